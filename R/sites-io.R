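# Parsing, curation, coordinate transforms and splitting of binding-site
# tables in a RegulonDB-export-like tab-separated dialect.

#' Column-map dialect for RegulonDB-style site tables
#'
#' Describes how to read a tab-separated binding-site table: which column
#' holds each mandatory field, how role and evidence tokens map onto the
#' package vocabulary, and whether coordinates are absolute genome positions
#' (transformed to TSS-relative at parse time) or already TSS-relative.
#'
#' @param columns named character vector mapping canonical field names
#'   (`tf_name`, `left`, `right`, `tss`, `strand`, `sequence`, `evidence`,
#'   `role`, optionally `site_id`, `gene`, `left_flank`, `right_flank`) to
#'   column headers in the file.
#' @param role_map named character vector translating role tokens
#'   (e.g. `"+"`, `"-"`) to `activator`/`repressor`/`unknown`.
#' @param evidence_map named character vector translating evidence tokens to
#'   `strong`/`weak`.
#' @param coordinates `"absolute"` (genome coordinates; converted strand-aware
#'   so downstream of the TSS is positive) or `"relative"` (already on the
#'   TSS axis).
#' @return a list usable as the `dialect` argument of [parseSiteTable()] and
#'   [writeSiteTable()].
#' @export
regulondbDialect <- function(columns = NULL, role_map = NULL,
                             evidence_map = NULL, coordinates = "absolute") {
  defCols <- c(site_id = "site_id", tf_name = "tf_name", gene = "gene",
               left = "left", right = "right", tss = "tss", strand = "strand",
               sequence = "sequence", evidence = "evidence", role = "role",
               left_flank = "left_flank", right_flank = "right_flank")
  if (!is.null(columns)) defCols[names(columns)] <- columns
  defRole <- c(activator = "activator", repressor = "repressor",
               "+" = "activator", "-" = "repressor",
               unknown = "unknown", "?" = "unknown")
  if (!is.null(role_map)) defRole[names(role_map)] <- role_map
  defEv <- c(strong = "strong", weak = "weak",
             Strong = "strong", Weak = "weak")
  if (!is.null(evidence_map)) defEv[names(evidence_map)] <- evidence_map
  stopifnot(coordinates %in% c("absolute", "relative"))
  list(columns = defCols, role_map = defRole, evidence_map = defEv,
       coordinates = coordinates)
}

#' Parse a binding-site table
#'
#' Reads a tab-separated table of TF binding sites and returns a [SiteSet-class]
#' on the TSS-relative axis (TSS at 0). For minus-strand sites the genomic
#' interval is reflected about the TSS so that positive coordinates are always
#' downstream of the start site, and the stored `[left, right]` interval stays
#' `left <= right`. Malformed rows are not silently dropped: they are collected
#' in `metadata(x)$rejects` with a per-row reason.
#'
#' @param path path to a tab-separated file with a header row.
#' @param dialect column map, see [regulondbDialect()].
#' @param name dataset label.
#' @return a `SiteSet`; rejected rows (with reasons) are recorded in the
#'   object's metadata.
#' @export
parseSiteTable <- function(path, dialect = regulondbDialect(),
                           name = basename(path)) {
  if (!file.exists(path)) stop("site table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  mandatory <- c("tf_name", "left", "right", "tss", "strand",
                 "sequence", "evidence", "role")
  cols <- dialect$columns
  missing <- mandatory[!cols[mandatory] %in% colnames(tab)]
  if (length(missing)) {
    stop("dialect maps mandatory field(s) to absent column(s): ",
         paste(sprintf("%s -> '%s'", missing, cols[missing]), collapse = ", "))
  }
  getcol <- function(field) {
    if (field %in% names(cols) && cols[[field]] %in% colnames(tab)) {
      tab[[cols[[field]]]]
    } else NULL
  }

  n <- nrow(tab)
  reasons <- character(n)
  num <- function(x) suppressWarnings(as.numeric(x))
  left <- num(getcol("left")); right <- num(getcol("right"))
  tss <- num(getcol("tss"))
  strand <- getcol("strand")
  seqs <- toupper(getcol("sequence"))
  role_raw <- getcol("role"); ev_raw <- getcol("evidence")

  bad <- is.na(left) | is.na(right) | is.na(tss)
  reasons[bad & !nzchar(reasons)] <- "unparseable coordinate"
  bad2 <- !strand %in% c("+", "-")
  reasons[bad2 & !nzchar(reasons)] <- "invalid strand"
  bad3 <- !isDnaString(seqs) | !nzchar(seqs)
  reasons[bad3 & !nzchar(reasons)] <- "invalid sequence"
  role <- unname(dialect$role_map[role_raw])
  reasons[is.na(role) & !nzchar(reasons)] <- "unknown role token"
  evidence <- unname(dialect$evidence_map[ev_raw])
  reasons[is.na(evidence) & !nzchar(reasons)] <- "unknown evidence token"
  ok <- !nzchar(reasons)
  lenMismatch <- ok & (right - left + 1) != nchar(seqs)
  reasons[lenMismatch] <- "interval length does not match sequence length"
  ok <- !nzchar(reasons)

  # strand-aware TSS-relative transform: minus-strand sites are reflected so
  # downstream of the TSS maps to the positive half-axis
  if (dialect$coordinates == "absolute") {
    relLeft <- ifelse(strand == "+", left - tss, tss - right)
    relRight <- ifelse(strand == "+", right - tss, tss - left)
  } else {
    relLeft <- left
    relRight <- right
  }

  ids <- getcol("site_id") %||% sprintf("site%04d", seq_len(n))
  gene <- getcol("gene") %||% rep(NA_character_, n)
  info <- data.frame(
    site_id = ids, tf_name = getcol("tf_name"), gene = gene,
    left = relLeft, right = relRight, tss = tss, strand = strand,
    evidence = evidence, role = role,
    stringsAsFactors = FALSE)
  lf <- getcol("left_flank"); rf <- getcol("right_flank")
  if (!is.null(lf)) info$left_flank <- toupper(lf)
  if (!is.null(rf)) info$right_flank <- toupper(rf)

  rejects <- cbind(row = which(!ok), reason = reasons[!ok],
                   tab[!ok, , drop = FALSE])
  info <- info[ok, , drop = FALSE]
  rownames(info) <- NULL
  new("SiteSet",
      info = info,
      coreSeqs = Biostrings::DNAStringSet(
        stats::setNames(seqs[ok], info$site_id)),
      extendedSeqs = Biostrings::DNAStringSet(),
      name = name, provenance = paste("parsed from", path),
      curationLog = character(),
      metadata = list(rejects = as.data.frame(rejects)))
}

#' Curate a binding-site dataset
#'
#' Applies, in order: (1) TF-name filter, (2) evidence-level filter,
#' (3) removal of redundant sites sharing a TSS with identical leftmost and
#' rightmost positions (first occurrence kept), and (4) a core-length filter.
#' Counts removed at each step are recorded in the curation log.
#'
#' @param sites a [SiteSet-class].
#' @param tf TF name to retain (default `"CRP"`).
#' @param evidence evidence tier to retain (`"strong"` by default; `NULL`
#'   keeps all).
#' @param coreLength required site length in nucleotides (default 22).
#' @return the curated `SiteSet` with an updated curation log.
#' @export
curateSites <- function(sites, tf = "CRP", evidence = "strong",
                        coreLength = 22L) {
  stopifnot(is(sites, "SiteSet"))
  log <- character()
  cur <- sites
  keep <- cur@info$tf_name == tf
  log <- c(log, sprintf("tf-name filter ('%s'): removed %d", tf, sum(!keep)))
  cur <- cur[keep]
  if (!is.null(evidence)) {
    keep <- cur@info$evidence == evidence
    log <- c(log, sprintf("evidence filter ('%s'): removed %d",
                          evidence, sum(!keep)))
    cur <- cur[keep]
  }
  key <- paste(cur@info$tss, cur@info$left, cur@info$right, sep = "/")
  keep <- !duplicated(key)
  log <- c(log, sprintf("TSS-redundancy removal: removed %d", sum(!keep)))
  cur <- cur[keep]
  keep <- (cur@info$right - cur@info$left + 1) == coreLength
  log <- c(log, sprintf("length != %d filter: removed %d",
                        coreLength, sum(!keep)))
  cur <- cur[keep]
  cur@curationLog <- log
  cur@name <- sites@name
  cur
}

#' Extend site cores with flanking sequence
#'
#' Adds `k` nucleotides of flanking sequence on each side of the 22-nt core,
#' producing the 42-nt extended sequence the descriptor is computed on (with
#' the default `k = 10`). Flanks come from a provider function, or from
#' `left_flank`/`right_flank` columns recorded in the site table (the
#' synthetic generator stores them); where fewer than `k` bases are available
#' the sequence is N-padded to exactly `core + 2k` with a warning. N
#' contributes to no k-mer count downstream. Core interval coordinates are
#' unchanged.
#'
#' @param sites a [SiteSet-class].
#' @param k flank length per side (default 10).
#' @param flankSource optional `function(siteId, side)` returning the flanking
#'   sequence 5' (`side = "left"`) or 3' (`side = "right"`) of the core,
#'   innermost base adjacent to the core. Defaults to the stored flank
#'   columns.
#' @return the `SiteSet` with `extendedSeqs` populated.
#' @export
extendSites <- function(sites, k = 10L, flankSource = NULL) {
  stopifnot(is(sites, "SiteSet"))
  if (k < 0) stop("flank length k must be >= 0")
  k <- as.integer(k)
  info <- sites@info
  getFlank <- function(i, side) {
    if (!is.null(flankSource)) {
      flankSource(info$site_id[i], side) %||% ""
    } else {
      col <- paste0(side, "_flank")
      if (col %in% colnames(info) && !is.na(info[[col]][i])) info[[col]][i]
      else ""
    }
  }
  core <- as.character(sites@coreSeqs)
  ext <- character(length(core))
  padded <- FALSE
  for (i in seq_along(core)) {
    lf <- getFlank(i, "left")
    rf <- getFlank(i, "right")
    # keep the k bases adjacent to the core on each side
    lf <- if (nchar(lf) >= k) substr(lf, nchar(lf) - k + 1, nchar(lf)) else lf
    rf <- if (nchar(rf) >= k) substr(rf, 1, k) else rf
    if (nchar(lf) < k || nchar(rf) < k) padded <- TRUE
    lf <- paste0(strrep("N", k - nchar(lf)), lf)
    rf <- paste0(rf, strrep("N", k - nchar(rf)))
    ext[i] <- paste0(lf, core[i], rf)
  }
  if (padded) {
    warning("flank shorter than k for some sites; N-padded to full length")
  }
  sites@extendedSeqs <- Biostrings::DNAStringSet(
    stats::setNames(ext, info$site_id))
  sites
}

#' Stratified train/test split of a site dataset
#'
#' Splits a labeled dataset by role at a given ratio. Per class the test set
#' receives `floor(n_class * test / (train + test))` sites and the training
#' set the remainder, so per-class counts deviate from the exact ratio by at
#' most one site; the partition is deterministic under the seed.
#'
#' @param sites a [SiteSet-class] where every site has a known role.
#' @param ratio length-2 numeric `(train, test)` proportions, default `c(2, 1)`.
#' @param seed integer seed.
#' @return list with elements `train` and `test` (both `SiteSet`).
#' @export
splitDataset <- function(sites, ratio = c(2, 1), seed = 1L) {
  stopifnot(is(sites, "SiteSet"), length(ratio) == 2, all(ratio >= 0))
  role <- sites@info$role
  if (any(role == "unknown")) {
    stop("splitDataset requires every site to have a known role")
  }
  classes <- c("activator", "repressor")
  if (any(!classes %in% role)) {
    warning("a role class has 0 members; split proceeds")
  }
  testIdx <- withSeed(seed, {
    unlist(lapply(classes, function(cl) {
      idx <- which(role == cl)
      nTest <- floor(length(idx) * ratio[2] / sum(ratio))
      if (nTest == 0) integer() else sample(idx, nTest)
    }), use.names = FALSE)
  })
  trainIdx <- setdiff(seq_along(role), testIdx)
  train <- sites[trainIdx]; test <- sites[sort(testIdx)]
  train@name <- paste0(sites@name, "-TRN")
  test@name <- paste0(sites@name, "-TST")
  list(train = train, test = test)
}

#' Write a SiteSet back to the tab-separated dialect
#'
#' Inverse of [parseSiteTable()]: TSS-relative coordinates are mapped back to
#' absolute genome coordinates (strand-aware) when the dialect uses absolute
#' coordinates, so write-then-parse is lossless.
#'
#' @param sites a [SiteSet-class].
#' @param path output file path.
#' @param dialect see [regulondbDialect()].
#' @return invisibly, the path.
#' @export
writeSiteTable <- function(sites, path, dialect = regulondbDialect()) {
  info <- sites@info
  if (dialect$coordinates == "absolute") {
    absLeft <- ifelse(info$strand == "+", info$left + info$tss,
                      info$tss - info$right)
    absRight <- ifelse(info$strand == "+", info$right + info$tss,
                       info$tss - info$left)
  } else {
    absLeft <- info$left; absRight <- info$right
  }
  out <- data.frame(
    site_id = info$site_id, tf_name = info$tf_name, gene = info$gene,
    left = absLeft, right = absRight, tss = info$tss, strand = info$strand,
    sequence = as.character(sites@coreSeqs),
    evidence = info$evidence, role = info$role,
    stringsAsFactors = FALSE)
  for (col in c("left_flank", "right_flank")) {
    if (col %in% colnames(info)) out[[col]] <- info[[col]]
  }
  colnames(out) <- unname(dialect$columns[colnames(out)])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
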