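# Synthetic CRP-like binding-site generator. Sites are built on the
# palindromic consensus backbone, placed at TSS-relative positions drawn
# from the four interpretable rules' region intervals (plus an optional
# uncovered tail), with motif contents planted or suppressed so that the
# canonical first-match ruleset reproduces every noise-free label exactly.

consensusTemplate <- function() "NNNTGTGANNNNNNTCACANNN"

# attainable Region values (site centres) are half-integers for 22-nt sites;
# these grids enumerate each rule's admissible centres within a bounded
# promoter span, and the boundary sets hold the closed endpoints used for
# endpoint stress placement
ruleRegionGrid <- function(rule) {
  switch(rule,
    A1 = list(grids = list(seq(-110.5, -49.5, by = 1),
                           seq(49.5, 80.5, by = 1)),
              weights = c(87, 1),       # the left branch dominates
              boundary = c(-49.5, 49.5)),
    A2 = list(grids = list(seq(-70.5, -28.5, by = 1)), weights = 1,
              boundary = c(-70.5, -28.5)),
    R1 = list(grids = list(seq(-49.5, -10.5, by = 1),
                           seq(2.5, 69.5, by = 1)),
              weights = c(9, 5),
              boundary = c(-49.5, -10.5, 2.5, 69.5)),
    R2 = list(grids = list(seq(-30.5, 22.5, by = 1)), weights = 1,
              boundary = c(-30.5, 22.5)),
    uncovered = list(grids = list(seq(-115.5, -80.5, by = 1)), weights = 1,
                     boundary = c(-80.5)),
    stop("unknown rule: ", rule))
}

ruleConsequent <- c(A1 = "activator", A2 = "activator",
                    R1 = "repressor", R2 = "repressor")

# motif constraints given a target rule and a centre, such that under
# first-match evaluation (A1, A2, R1, R2) the site's observed consequent is
# the target rule's: earlier activation rules are blocked by planting the
# motifs they forbid (or exceeding A1's TTTT cap)
siteConstraints <- function(rule, center) {
  inA1 <- center <= -49.5 || center >= 49.5
  inA2 <- center >= -70.5 && center <= -28.5
  forbid <- character(); need <- list(); capTTTT <- Inf
  if (rule == "A1") {
    capTTTT <- 2
  } else if (rule == "A2") {
    forbid <- "AACG"
    if (inA1) need <- c(need, list(list(motif = "TTTT", min = 3)))
  } else if (rule == "R1") {
    forbid <- "TTAC"
    if (inA1) need <- c(need, list(list(motif = "TTTT", min = 3)))
    if (inA2) need <- c(need, list(list(motif = "AACG", min = 1)))
  } else if (rule == "R2") {
    forbid <- c("TTAC", "GAGC")
    if (inA2) need <- c(need, list(list(motif = "AACG", min = 1)))
  } else if (rule == "uncovered") {
    need <- list(list(motif = "TTTT", min = 3))
  }
  list(forbid = forbid, need = need, capTTTT = capTTTT)
}

countMotif <- function(seq, motif) {
  Biostrings::countPattern(motif, Biostrings::DNAString(seq))
}

randomBases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

fillTemplate <- function() {
  chars <- strsplit(consensusTemplate(), "")[[1]]
  ns <- chars == "N"
  chars[ns] <- sample(c("A", "C", "G", "T"), sum(ns), replace = TRUE)
  paste(chars, collapse = "")
}

# synthesize core + flanks meeting the motif constraints by targeted
# planting plus rejection; the consensus G/G/C/C backbone is always intact
synthesizeSite <- function(rule, center, k) {
  cst <- siteConstraints(rule, center)
  needTTTT <- any(vapply(cst$need, function(x) x$motif == "TTTT", logical(1)))
  needAACG <- any(vapply(cst$need, function(x) x$motif == "AACG", logical(1)))
  if ((needTTTT && k < 6) || (needAACG && k < 4)) {
    stop("unsatisfiable config: flank length k = ", k,
         " too short to plant required motifs for rule ", rule,
         " at Region ", center)
  }
  for (attempt in 1:400) {
    core <- fillTemplate()
    lf <- randomBases(k)
    rf <- randomBases(k)
    if (needTTTT) substr(lf, 1, 6) <- "TTTTTT"  # 3 overlapping TTTT
    if (needAACG) substr(rf, k - 3, k) <- "AACG"
    ext <- paste0(lf, core, rf)
    ok <- TRUE
    for (m in cst$forbid) if (countMotif(ext, m) > 0) { ok <- FALSE; break }
    if (ok && is.finite(cst$capTTTT) &&
        countMotif(ext, "TTTT") > cst$capTTTT) ok <- FALSE
    if (ok && needTTTT && countMotif(ext, "TTTT") < 3) ok <- FALSE
    if (ok && needAACG && countMotif(ext, "AACG") < 1) ok <- FALSE
    if (ok) return(list(core = core, left_flank = lf, right_flank = rf))
  }
  stop("unsatisfiable config: could not synthesize a site for rule ", rule,
       " at Region ", center, " after 400 attempts")
}

#' Configuration for the synthetic CRP-site generator
#'
#' Defaults emulate the curated strong-evidence CRP dataset: 169 sites with
#' a 36/169 repressor fraction, rule mixture proportional to the published
#' per-rule cover counts (88:31 activators via A1:A2, 14:7 repressors via
#' R1:R2) plus an uncovered tail sized so roughly 5/6 of sites are covered
#' by the ruleset, 10-nt recorded flanks, no label noise, and 5% of sites
#' placed exactly on rule-threshold boundaries to stress endpoint
#' conventions.
#'
#' @param nSites number of sites (default 169).
#' @param repressorFraction probability a covered site comes from a
#'   repression rule (default 36/169); within each role the rules keep their
#'   published ratios.
#' @param labelNoise probability each observed role is flipped (default 0).
#' @param uncoveredFraction probability of an uncovered-tail site (Region
#'   below -80 with the activation rules blocked), default 29/169.
#' @param boundaryFraction probability a site is placed exactly on one of
#'   its rule's attainable region boundaries (default 0.05).
#' @param flank recorded flank length per side (default 10).
#' @param seed integer seed.
#' @return list of class `synthConfig`.
#' @export
synthConfig <- function(nSites = 169L, repressorFraction = 36 / 169,
                        labelNoise = 0, uncoveredFraction = 29 / 169,
                        boundaryFraction = 0.05, flank = 10L, seed = 1L) {
  stopifnot(nSites >= 1, repressorFraction >= 0, repressorFraction <= 1,
            labelNoise >= 0, labelNoise <= 1,
            uncoveredFraction >= 0, uncoveredFraction < 1, flank >= 0)
  structure(list(nSites = as.integer(nSites),
                 repressorFraction = repressorFraction,
                 labelNoise = labelNoise,
                 uncoveredFraction = uncoveredFraction,
                 boundaryFraction = boundaryFraction,
                 flank = as.integer(flank), seed = as.integer(seed)),
            class = "synthConfig")
}

#' Generate a labeled synthetic CRP-site dataset
#'
#' Each site draws a target rule (A1/A2/R1/R2 or the uncovered tail), a
#' 22-nt TSS-relative interval whose centre satisfies that rule's region
#' predicate, and a core sequence on the palindromic consensus backbone
#' (G at positions 5 and 7, C at 16 and 18). Motifs are planted or
#' suppressed so that first-match evaluation of [canonicalRuleset()] on the
#' extended sequence yields exactly the target rule's consequent; the
#' observed role is then flipped with probability `labelNoise`. Flanks are
#' generated and recorded so [extendSites()] is exact. Uncovered-tail sites
#' get a random role and match no rule. Output is byte-stable under a fixed
#' seed.
#'
#' @param cfg a [synthConfig()].
#' @return a [SiteSet-class]; ground truth per site (assigned rule, true
#'   role, noise flip) is in the `rule`, `role_true` and `flipped` columns
#'   of `siteInfo()`.
#' @export
generateSites <- function(cfg = synthConfig()) {
  stopifnot(inherits(cfg, "synthConfig"))
  rules <- c("A1", "A2", "R1", "R2")
  actW <- c(88, 31) / 119
  repW <- c(14, 7) / 21
  withSeed(deriveSeed(cfg$seed, "generator"), {
    n <- cfg$nSites
    rows <- vector("list", n)
    cores <- character(n)
    for (i in seq_len(n)) {
      rule <- if (stats::runif(1) < cfg$uncoveredFraction) "uncovered"
      else if (stats::runif(1) < cfg$repressorFraction) {
        sample(c("R1", "R2"), 1, prob = repW)
      } else {
        sample(c("A1", "A2"), 1, prob = actW)
      }
      rr <- ruleRegionGrid(rule)
      center <- if (stats::runif(1) < cfg$boundaryFraction) {
        rr$boundary[sample(length(rr$boundary), 1)]
      } else {
        g <- rr$grids[[sample(length(rr$grids), 1,
                              prob = rr$weights / sum(rr$weights))]]
        g[sample(length(g), 1)]
      }
      left <- as.integer(center - 10.5)
      seqs <- synthesizeSite(rule, center, cfg$flank)
      roleTrue <- if (rule == "uncovered") {
        sample(c("activator", "repressor"), 1,
               prob = c(1 - cfg$repressorFraction, cfg$repressorFraction))
      } else ruleConsequent[[rule]]
      flip <- stats::runif(1) < cfg$labelNoise
      role <- if (flip) {
        setdiff(c("activator", "repressor"), roleTrue)
      } else roleTrue
      rows[[i]] <- data.frame(
        site_id = sprintf("syn%04d", i), tf_name = "CRP",
        gene = sprintf("gene%04d", i),
        left = left, right = left + 21L,
        tss = 10000L + i * 300L,
        strand = c("+", "-")[1 + (stats::runif(1) < 0.5)],
        evidence = "strong", role = role,
        rule = rule, role_true = roleTrue, flipped = flip,
        left_flank = seqs$left_flank, right_flank = seqs$right_flank,
        stringsAsFactors = FALSE)
      cores[i] <- seqs$core
    }
    info <- do.call(rbind, rows)
    new("SiteSet", info = info,
        coreSeqs = Biostrings::DNAStringSet(
          stats::setNames(cores, info$site_id)),
        extendedSeqs = Biostrings::DNAStringSet(),
        name = "synthetic-CRP",
        provenance = sprintf("generateSites(seed = %d)", cfg$seed),
        curationLog = character(),
        metadata = list(config = unclass(cfg)))
  })
}

#' Write a generated dataset as plain-text fixtures
#'
#' Emits the RegulonDB-dialect TSV (absolute coordinates, recorded flanks),
#' a FASTA of core sequences and a ground-truth sidecar TSV (site id,
#' assigned rule, true role, noise flip). The TSV round-trips losslessly
#' through [parseSiteTable()].
#'
#' @param sites a [SiteSet-class] from [generateSites()].
#' @param dir output directory (created if absent).
#' @param prefix file name prefix, default `"sites"`.
#' @return invisibly, named character vector of the written paths.
#' @export
writeFixture <- function(sites, dir, prefix = "sites") {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create fixture directory: ", dir)
  }
  paths <- c(table = file.path(dir, paste0(prefix, ".tsv")),
             fasta = file.path(dir, paste0(prefix, ".fasta")),
             truth = file.path(dir, paste0(prefix, "_truth.tsv")))
  writeSiteTable(sites, paths[["table"]])
  Biostrings::writeXStringSet(coreSeqs(sites), paths[["fasta"]])
  info <- siteInfo(sites)
  truthCols <- intersect(c("site_id", "rule", "role_true", "flipped"),
                         colnames(info))
  utils::write.table(info[, truthCols, drop = FALSE], paths[["truth"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
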