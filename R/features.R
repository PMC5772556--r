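# The 380-feature binding-site descriptor: k-mer composition (256 + 64),
# location-dependent promoter-window overlaps (17), physicochemical scalars
# (3) and global sequence features (40).

#' Default location windows L1..L17
#'
#' Seventeen TSS-relative promoter windows whose overlap length with the
#' binding-site interval forms the location-dependent descriptor. Four
#' windows are fixed at their published definitions: L3 = \[-35, -10\] (the
#' RNA-polymerase -35/-10 region), L6 = \[-10, 2\], L12 = \[-60, 60\] and
#' L15 = \[-95, -35\]. The remaining thirteen tile \[-120, 60\] over
#' canonical promoter elements (distal upstream/UP element region, the
#' Class I and Class II activation-site spans around -61.5 and -41.5, the
#' -35 and -10 hexamer neighbourhoods, and downstream blocks); they can be
#' overridden wholesale via [descriptorSpec()].
#'
#' @return data.frame with columns `name`, `start`, `end`.
#' @export
defaultWindows <- function() {
  data.frame(
    name = paste0("L", 1:17),
    start = c(-120, -95, -35, -60, -72, -10, -52, -40, -15, 2, 20, -60, 40,
              -120, -95, 0, -120),
    end = c(-95, -60, -10, -35, -51, 2, -31, -30, -5, 20, 40, 60, 60,
            -60, -35, 60, 60),
    stringsAsFactors = FALSE)
}

#' Build a descriptor layout
#'
#' @param windows data.frame of location windows (`name`, `start`, `end`);
#'   defaults to [defaultWindows()].
#' @param kmerSizes k values of the composition blocks, default `c(4, 3)`.
#' @param motifSequence `"extended"` (default) or `"core"`: which sequence
#'   the composition, physicochemical and global blocks are computed on.
#' @return a [DescriptorSpec-class].
#' @export
descriptorSpec <- function(windows = defaultWindows(), kmerSizes = c(4L, 3L),
                           motifSequence = "extended") {
  new("DescriptorSpec", kmerSizes = as.integer(kmerSizes), windows = windows,
      physchem = c("gc_content", "purine_fraction", "tm_wallace"),
      motifSequence = motifSequence)
}

allKmers <- function(k) {
  bases <- c("A", "C", "G", "T")
  if (k == 0) return("")
  grid <- do.call(expand.grid,
                  c(rep(list(bases), k), stringsAsFactors = FALSE))
  # lexicographic order: leftmost position most significant
  apply(grid[rev(seq_len(k))], 1, paste, collapse = "")
}

globalFeatureNames <- function() {
  bases <- c("A", "C", "G", "T")
  c(paste0("frac_", bases),
    paste0("dinuc_", allKmers(2)),
    as.vector(t(outer(bases, c("first", "q25", "q50", "q75", "last"),
                      function(b, q) paste0("dist_", b, "_", q)))))
}

#' Feature names of a descriptor layout
#'
#' Stable, unique names in extraction order:
#' `kmer4_*` (256), `kmer3_*` (64), window names (17), physicochemical (3),
#' global block (40).
#'
#' @param spec a [DescriptorSpec-class].
#' @return character vector of length [descriptorDimension()].
#' @export
descriptorNames <- function(spec = descriptorSpec()) {
  c(unlist(lapply(spec@kmerSizes,
                  function(k) paste0("kmer", k, "_", allKmers(k)))),
    spec@windows$name, spec@physchem, globalFeatureNames())
}

#' Overlapping k-mer composition of a DNA sequence
#'
#' Counts every length-k window in lexicographic k-mer order over
#' \{A, C, G, T\}; windows containing N contribute nothing. For an N-free
#' sequence of length L the counts sum to `L - k + 1`.
#'
#' @param seq DNA string (character or `DNAString`).
#' @param k word size (>= 1).
#' @return named integer vector of length `4^k`; all zero when
#'   `k > nchar(seq)`.
#' @export
kmerComposition <- function(seq, k) {
  stopifnot(k >= 1)
  s <- Biostrings::DNAString(as.character(seq))
  if (k > length(s)) {
    return(stats::setNames(integer(4^k), allKmers(k)))
  }
  Biostrings::oligonucleotideFrequency(s, width = k)
}

#' Overlap length between a site interval and a location window
#'
#' The number of integer nucleotide positions lying in both the closed site
#' interval `[left, right]` and the (real-bounded) window `[start, end]`;
#' 0 when disjoint. Vectorized over sites.
#'
#' @param left,right integer site bounds (TSS-relative).
#' @param start,end window bounds.
#' @return non-negative integer overlap length(s).
#' @export
windowOverlap <- function(left, right, start, end) {
  lo <- ceiling(pmax(left, start))
  hi <- floor(pmin(right, end))
  as.integer(pmax(0, hi - lo + 1))
}

#' Physicochemical descriptor (3 scalars)
#'
#' GC fraction, purine (A+G) fraction, and a Wallace-rule melting-temperature
#' estimate `2(A+T) + 4(G+C)` in degrees C. N bases are excluded from the
#' fractions; an all-N sequence yields zeros with a warning.
#'
#' @param seq DNA string.
#' @return named numeric vector of length 3.
#' @export
physicochemicalDescriptor <- function(seq) {
  chars <- strsplit(toupper(as.character(seq)), "")[[1]]
  cnt <- vapply(c("A", "C", "G", "T"), function(b) sum(chars == b), numeric(1))
  tot <- sum(cnt)
  if (tot == 0) {
    warning("sequence has no unambiguous bases; physicochemical features are 0")
    return(c(gc_content = 0, purine_fraction = 0, tm_wallace = 0))
  }
  c(gc_content = unname((cnt["G"] + cnt["C"]) / tot),
    purine_fraction = unname((cnt["A"] + cnt["G"]) / tot),
    tm_wallace = unname(2 * (cnt["A"] + cnt["T"]) + 4 * (cnt["G"] + cnt["C"])))
}

#' Global sequence descriptor (40 features)
#'
#' Three blocks: 4 mononucleotide fractions (over unambiguous bases, summing
#' to 1 for N-free input); 16 dinucleotide transition frequencies (counts of
#' adjacent unambiguous pairs, normalized by the total number of such pairs);
#' and 20 distribution features — for each base, the positions of its first,
#' 25%, 50%, 75% and last occurrence, normalized by sequence length, 0 when
#' the base is absent.
#'
#' @param seq DNA string.
#' @return named numeric vector of length 40.
#' @export
globalDescriptor <- function(seq) {
  s <- toupper(as.character(seq))
  chars <- strsplit(s, "")[[1]]
  L <- length(chars)
  bases <- c("A", "C", "G", "T")
  cnt <- vapply(bases, function(b) sum(chars == b), numeric(1))
  tot <- sum(cnt)
  fr <- if (tot > 0) cnt / tot else rep(0, 4)
  names(fr) <- paste0("frac_", bases)

  di <- stats::setNames(numeric(16), paste0("dinuc_", allKmers(2)))
  if (L >= 2) {
    a <- chars[-L]; b <- chars[-1]
    ok <- a %in% bases & b %in% bases
    if (any(ok)) {
      tabs <- table(paste0(a[ok], b[ok]))
      di[paste0("dinuc_", names(tabs))] <- as.numeric(tabs) / sum(ok)
    }
  }

  dist <- numeric(0)
  for (b in bases) {
    pos <- which(chars == b)
    m <- length(pos)
    vals <- if (m == 0) rep(0, 5) else {
      pos[c(1L, ceiling(0.25 * m), ceiling(0.5 * m), ceiling(0.75 * m), m)] / L
    }
    names(vals) <- paste0("dist_", b, "_", c("first", "q25", "q50", "q75", "last"))
    dist <- c(dist, vals)
  }
  c(fr, di, dist)
}

#' Extract the full descriptor for every site
#'
#' Concatenates the blocks `[4-mer (256) | 3-mer (64) | location (17) |`
#' `physicochemical (3) | global (40)]` into a 380-column feature matrix.
#' Composition, physicochemical and global blocks are computed on the
#' extended sequence (or the core when the spec says so); location features
#' use the TSS-relative core interval.
#'
#' @param sites a [SiteSet-class] with extended sequences (see
#'   [extendSites()]) unless `spec@motifSequence == "core"`.
#' @param spec a [DescriptorSpec-class].
#' @return numeric matrix, one row per site (rownames = site ids), columns
#'   named by [descriptorNames()].
#' @export
extractFeatures <- function(sites, spec = descriptorSpec()) {
  stopifnot(is(sites, "SiteSet"), is(spec, "DescriptorSpec"))
  if (spec@motifSequence == "extended") {
    if (!length(sites@extendedSeqs)) {
      stop("sites have no extended sequences; run extendSites() first")
    }
    seqs <- as.character(sites@extendedSeqs)
  } else {
    seqs <- as.character(sites@coreSeqs)
  }
  info <- sites@info
  nm <- descriptorNames(spec)
  out <- matrix(0, nrow = length(seqs), ncol = length(nm),
                dimnames = list(info$site_id, nm))
  for (i in seq_along(seqs)) {
    km <- unlist(lapply(spec@kmerSizes, function(k) {
      v <- kmerComposition(seqs[i], k)
      stats::setNames(v, paste0("kmer", k, "_", names(v)))
    }))
    loc <- stats::setNames(
      windowOverlap(info$left[i], info$right[i],
                    spec@windows$start, spec@windows$end),
      spec@windows$name)
    out[i, ] <- c(km, loc, physicochemicalDescriptor(seqs[i]),
                  globalDescriptor(seqs[i]))[nm]
  }
  out
}

#' Region and informative-motif features for the rule classifier
#'
#' Computes the scalar the rules call "Region" (site centre by default;
#' leftmost/rightmost semantics available) plus overlapping occurrence
#' counts of the rules' 4-mer motifs, counted on the extended sequence by
#' default.
#'
#' @param sites a [SiteSet-class].
#' @param motifs 4-mers to count; defaults to the four used by the canonical
#'   rules.
#' @param sequence `"extended"` (default; requires [extendSites()]) or
#'   `"core"`.
#' @param semantics Region semantics: `"center"` (default), `"leftmost"` or
#'   `"rightmost"`.
#' @return data.frame with columns `region` and one count column per motif,
#'   rownames = site ids.
#' @export
ruleFeatures <- function(sites, motifs = c("TTTT", "AACG", "TTAC", "GAGC"),
                         sequence = c("extended", "core"),
                         semantics = c("center", "leftmost", "rightmost")) {
  sequence <- match.arg(sequence)
  semantics <- match.arg(semantics)
  stopifnot(is(sites, "SiteSet"))
  if (sequence == "extended") {
    if (!length(sites@extendedSeqs)) {
      stop("sites have no extended sequences; run extendSites() first")
    }
    seqs <- sites@extendedSeqs
  } else {
    seqs <- sites@coreSeqs
  }
  info <- sites@info
  region <- switch(semantics,
                   center = (info$left + info$right) / 2,
                   leftmost = info$left,
                   rightmost = info$right)
  out <- data.frame(region = region, row.names = info$site_id)
  for (m in motifs) {
    out[[m]] <- Biostrings::vcountPattern(m, seqs)
  }
  out
}

#' Write a feature matrix with a sidecar layout file
#'
#' @param features matrix from [extractFeatures()].
#' @param path output TSV path (rows = sites, header = feature names); a
#'   `<path>.spec.json` sidecar records the block layout.
#' @param spec the [DescriptorSpec-class] used.
#' @return invisibly, `path`.
#' @export
writeFeatureTable <- function(features, path, spec = descriptorSpec()) {
  df <- data.frame(site_id = rownames(features), features,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(
    kmerSizes = spec@kmerSizes,
    windows = spec@windows,
    physchem = spec@physchem,
    motifSequence = spec@motifSequence,
    dimension = descriptorDimension(spec))
  jsonlite::write_json(sidecar, paste0(path, ".spec.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a feature matrix written by [writeFeatureTable()]
#'
#' @param path TSV path.
#' @return numeric matrix with site ids as rownames.
#' @export
readFeatureTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
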