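# The canonical four-rule activation/repression classifier, first-match rule
# application, coverage statistics and JSON serialization.

makeRule <- function(name, consequent, region, motifs) {
  new("Rule", name = name, consequent = consequent,
      region = region, motifs = motifs, stats = list())
}

interval <- function(lo, hi, loOpen = FALSE, hiOpen = FALSE) {
  data.frame(lo = lo, hi = hi, loOpen = loOpen, hiOpen = hiOpen)
}

#' The canonical four-rule CRP classifier
#'
#' Returns the published interpretable ruleset, evaluated first-match in the
#' order A1, A2, R1, R2:
#'
#' * **A1** (activation): Region <= -49.5 or Region >= 49.5, and at most two
#'   TTTT motifs. The paired location conditions are a union of intervals —
#'   read as a conjunction they would be unsatisfiable, and the two branches
#'   carry separate cover counts (the left branch dominates).
#' * **A2** (activation): Region in \[-70.5, -28.5\] and no AACG motif.
#' * **R1** (repression): Region in (2, 70.5) or \[-49.5, -10), and no TTAC
#'   motif; endpoint openness follows the printed thresholds.
#' * **R2** (repression): Region in \[-31, 23\] and neither TTAC nor GAGC.
#'
#' The two activation regions contain the classic Class I (-61.5) and
#' Class II (-41.5) activation-site anchors; the repression regions overlap
#' the RNA-polymerase binding region and the immediate downstream of the
#' TSS, where a bound CRP dimer can obstruct transcription.
#'
#' @param fallback policy for uncovered sites: `"uncovered"` (default) or
#'   `"majority"`.
#' @return a [RuleSet-class] with rules A1, A2, R1, R2.
#' @export
canonicalRuleset <- function(fallback = "uncovered") {
  a1 <- makeRule("A1", "activator",
                 rbind(interval(-Inf, -49.5), interval(49.5, Inf)),
                 data.frame(feature = "TTTT", op = "le", value = 2))
  a2 <- makeRule("A2", "activator",
                 interval(-70.5, -28.5),
                 data.frame(feature = "AACG", op = "absent", value = 0))
  r1 <- makeRule("R1", "repressor",
                 rbind(interval(2, 70.5, loOpen = TRUE, hiOpen = TRUE),
                       interval(-49.5, -10, loOpen = FALSE, hiOpen = TRUE)),
                 data.frame(feature = "TTAC", op = "absent", value = 0))
  r2 <- makeRule("R2", "repressor",
                 interval(-31, 23),
                 data.frame(feature = c("TTAC", "GAGC"),
                            op = c("absent", "absent"), value = c(0, 0)))
  new("RuleSet", rules = list(a1, a2, r1, r2), fallback = fallback)
}

regionMatches <- function(regionDf, x) {
  if (nrow(regionDf) == 0) return(rep(TRUE, length(x)))
  hit <- rep(FALSE, length(x))
  for (i in seq_len(nrow(regionDf))) {
    lo <- regionDf$lo[i]; hi <- regionDf$hi[i]
    okLo <- if (regionDf$loOpen[i]) x > lo else x >= lo
    okHi <- if (regionDf$hiOpen[i]) x < hi else x <= hi
    hit <- hit | (okLo & okHi)
  }
  hit
}

# Antecedent truth of one rule over a feature data.frame (column `region`
# plus motif-count columns).
matchesRule <- function(rule, features, regionFeature = "region",
                        rawClass = FALSE) {
  x <- if (regionFeature %in% colnames(features)) features[[regionFeature]]
       else if (nrow(rule@region) == 0) rep(0, nrow(features))
       else stop("features lack the required column '", regionFeature, "'")
  ok <- regionMatches(rule@region, x)
  if (nrow(rule@motifs)) {
    for (i in seq_len(nrow(rule@motifs))) {
      f <- rule@motifs$feature[i]
      if (!f %in% colnames(features)) {
        stop("features lack the required column '", f, "'")
      }
      v <- features[[f]]
      ok <- ok & switch(rule@motifs$op[i],
                        le = v <= rule@motifs$value[i],
                        ge = v >= rule@motifs$value[i],
                        gt = v > rule@motifs$value[i],
                        absent = v == 0)
    }
  }
  ok
}

#' Classify sites with a rule set
#'
#' First-match classification in rule order; all matching rules are reported
#' so conflicts are visible rather than suppressed. Sites matching no rule
#' receive the fallback: `"uncovered"` (the default, reported as such) or the
#' majority consequent of the ruleset.
#'
#' @param features data.frame from [ruleFeatures()]: a `region` column plus
#'   one count column per motif the rules test; missing columns raise an
#'   error naming the feature.
#' @param ruleset a [RuleSet-class], default [canonicalRuleset()].
#' @return data.frame with columns `role` (`activator`/`repressor`/
#'   `uncovered`), `matched` (comma-joined matching rule names), `first_rule`
#'   and `n_matched`, rownames preserved from `features`.
#' @export
applyRuleset <- function(features, ruleset = canonicalRuleset()) {
  stopifnot(is(ruleset, "RuleSet"))
  n <- nrow(features)
  hits <- vapply(ruleset@rules, matchesRule, logical(n), features = features)
  if (n == 1) hits <- matrix(hits, nrow = 1)
  rn <- ruleNames(ruleset)
  firstIdx <- apply(hits, 1, function(h) if (any(h)) which(h)[1] else NA_integer_)
  cons <- vapply(ruleset@rules, function(r) r@consequent, character(1))
  fallbackRole <- if (ruleset@fallback == "majority") {
    names(sort(table(cons), decreasing = TRUE))[1]
  } else "uncovered"
  role <- ifelse(is.na(firstIdx), fallbackRole, cons[firstIdx])
  data.frame(
    role = role,
    matched = apply(hits, 1, function(h) paste(rn[h], collapse = ",")),
    first_rule = ifelse(is.na(firstIdx), NA_character_, rn[firstIdx]),
    n_matched = rowSums(hits),
    row.names = rownames(features),
    stringsAsFactors = FALSE)
}

#' Per-rule coverage and accuracy on a labeled dataset
#'
#' For each rule, `covered` counts sites of the rule's consequent class whose
#' antecedent matches; `coverage` divides by the class total (e.g. "covers
#' 88 of 133 activators"); `accuracy` divides by all antecedent matches
#' regardless of class (NA when the rule matches nothing). Antecedents are
#' evaluated independently here, not first-match, mirroring how per-rule
#' cover ratios are reported.
#'
#' @param ruleset a [RuleSet-class].
#' @param features data.frame as for [applyRuleset()].
#' @param truth true roles, same order as `features` rows.
#' @return list with `perRule` (data.frame: rule, consequent, n_matched,
#'   covered, class_total, coverage, accuracy) and `coveredFraction` (the
#'   fraction of sites matched by at least one rule).
#' @export
ruleCoverage <- function(ruleset, features, truth) {
  truth <- as.character(truth)
  n <- nrow(features)
  if (n == 0) {
    return(list(perRule = data.frame(), coveredFraction = NA_real_))
  }
  hits <- vapply(ruleset@rules, matchesRule, logical(n), features = features)
  if (n == 1) hits <- matrix(hits, nrow = 1)
  rows <- lapply(seq_along(ruleset@rules), function(i) {
    r <- ruleset@rules[[i]]
    m <- hits[, i]
    classTotal <- sum(truth == r@consequent)
    covered <- sum(m & truth == r@consequent)
    data.frame(rule = r@name, consequent = r@consequent,
               n_matched = sum(m), covered = covered,
               class_total = classTotal,
               coverage = if (classTotal > 0) covered / classTotal else NA_real_,
               accuracy = if (sum(m) > 0) covered / sum(m) else NA_real_,
               stringsAsFactors = FALSE)
  })
  list(perRule = do.call(rbind, rows),
       coveredFraction = mean(rowSums(hits) > 0))
}

ruleToList <- function(rule) {
  enc <- function(v) ifelse(is.finite(v), v, ifelse(v > 0, "Inf", "-Inf"))
  list(name = rule@name, consequent = rule@consequent,
       region = if (nrow(rule@region)) list(
         lo = as.list(enc(rule@region$lo)),
         hi = as.list(enc(rule@region$hi)),
         loOpen = rule@region$loOpen, hiOpen = rule@region$hiOpen)
       else NULL,
       motifs = if (nrow(rule@motifs)) rule@motifs else NULL)
}

ruleFromList <- function(x) {
  dec <- function(v) vapply(v, function(e) {
    if (is.character(e)) as.numeric(e) else as.numeric(e)
  }, numeric(1))
  region <- if (is.null(x$region)) {
    data.frame(lo = numeric(), hi = numeric(),
               loOpen = logical(), hiOpen = logical())
  } else {
    data.frame(lo = dec(x$region$lo), hi = dec(x$region$hi),
               loOpen = unlist(x$region$loOpen),
               hiOpen = unlist(x$region$hiOpen))
  }
  motifs <- if (is.null(x$motifs)) {
    data.frame(feature = character(), op = character(), value = numeric(),
               stringsAsFactors = FALSE)
  } else {
    data.frame(feature = unlist(x$motifs$feature),
               op = unlist(x$motifs$op),
               value = unlist(x$motifs$value), stringsAsFactors = FALSE)
  }
  makeRule(x$name, x$consequent, region, motifs)
}

#' Serialize a RuleSet to JSON
#'
#' Intervals, endpoint openness, motif predicates and evaluation order are
#' all preserved; infinite bounds are encoded as strings. [readRuleset()]
#' restores an identical classifier.
#'
#' @param ruleset a [RuleSet-class].
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
writeRuleset <- function(ruleset, path) {
  obj <- list(fallback = ruleset@fallback,
              rules = lapply(ruleset@rules, ruleToList))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname writeRuleset
#' @export
readRuleset <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  new("RuleSet",
      rules = lapply(obj$rules, ruleFromList),
      fallback = obj$fallback)
}
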