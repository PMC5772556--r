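#' @import methods
#' @importFrom Biostrings DNAStringSet DNAString oligonucleotideFrequency
#'   vcountPattern countPattern writeXStringSet subseq width
#' @importFrom stats predict qbeta quantile runif
#' @importFrom utils read.delim write.table packageVersion head tail
NULL

#' SiteSet: a collection of TSS-anchored transcription-factor binding sites
#'
#' The central container of the package. Each site carries a 22-nt core
#' sequence, an optional 42-nt extended sequence, and a closed TSS-relative
#' interval `[left, right]` with the transcription start site at 0 and
#' downstream positions positive (minus-strand sites are reflected at parse
#' time so the axis is always promoter-oriented). The site centre
#' `(left + right) / 2` is the "Region" scalar used by the interpretable
#' rules; for the standard even-length 22-nt sites it is a half-integer.
#'
#' @slot info data.frame with one row per site: `site_id`, `tf_name`, `gene`,
#'   `left`, `right`, `tss`, `strand`, `evidence`, `role`, and optionally
#'   `rule`, `role_true`, `left_flank`, `right_flank`.
#' @slot coreSeqs [Biostrings::DNAStringSet] of core site sequences, named by
#'   `site_id`; width matches `right - left + 1`.
#' @slot extendedSeqs [Biostrings::DNAStringSet] of flank-extended sequences
#'   (empty until [extendSites()] is called); the core is its central block.
#' @slot name,provenance free-text dataset labels.
#' @slot curationLog character vector of curation step summaries.
#' @slot metadata list for auxiliary records (parse rejects, generator config).
#'
#' @seealso [parseSiteTable()], [curateSites()], [extendSites()],
#'   [generateSites()]
#' @export
setClass("SiteSet", representation(
  info = "data.frame",
  coreSeqs = "DNAStringSet",
  extendedSeqs = "DNAStringSet",
  name = "character",
  provenance = "character",
  curationLog = "character",
  metadata = "list"
))

setValidity("SiteSet", function(object) {
  msgs <- character()
  n <- nrow(object@info)
  required <- c("site_id", "tf_name", "gene", "left", "right", "tss",
                "strand", "evidence", "role")
  miss <- setdiff(required, colnames(object@info))
  if (length(miss)) {
    msgs <- c(msgs, paste("missing info columns:", paste(miss, collapse = ", ")))
  }
  if (length(object@coreSeqs) != n) {
    msgs <- c(msgs, "length(coreSeqs) must equal nrow(info)")
  }
  if (n > 0 && !length(msgs)) {
    if (anyDuplicated(object@info$site_id)) {
      msgs <- c(msgs, "site_ids must be unique")
    }
    span <- object@info$right - object@info$left + 1
    if (any(span != Biostrings::width(object@coreSeqs))) {
      msgs <- c(msgs, "right - left + 1 must equal core sequence length")
    }
    ne <- length(object@extendedSeqs)
    if (ne != 0 && ne != n) {
      msgs <- c(msgs, "extendedSeqs must be empty or match the number of sites")
    }
    if (ne == n && n > 0) {
      k2 <- Biostrings::width(object@extendedSeqs) - Biostrings::width(object@coreSeqs)
      if (any(k2 < 0) || any(k2 %% 2 != 0)) {
        msgs <- c(msgs, "extended sequences must add equal flanks on both sides")
      } else {
        k <- k2 %/% 2
        central <- as.character(Biostrings::subseq(
          object@extendedSeqs, start = k + 1,
          width = Biostrings::width(object@coreSeqs)))
        if (any(central != as.character(object@coreSeqs))) {
          msgs <- c(msgs, "extended sequences must contain the core as their central block")
        }
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' DescriptorSpec: layout of the 380-feature binding-site descriptor
#'
#' Describes the fixed feature blocks extracted from an extended binding
#' site: 256 4-mer counts, 64 3-mer counts, 17 promoter-window overlap
#' lengths, 3 physicochemical scalars and 40 global sequence features
#' (256 + 64 + 17 + 3 + 40 = 380).
#'
#' @slot kmerSizes integer k values of the composition blocks (4 then 3).
#' @slot windows data.frame of location windows: `name`, `start`, `end`
#'   (TSS-relative, closed real intervals).
#' @slot physchem names of the three physicochemical scalars.
#' @slot motifSequence which sequence motif counts and composition are
#'   computed on: `"extended"` (default) or `"core"`.
#' @seealso [descriptorSpec()], [extractFeatures()]
#' @export
setClass("DescriptorSpec", representation(
  kmerSizes = "integer",
  windows = "data.frame",
  physchem = "character",
  motifSequence = "character"
))

setValidity("DescriptorSpec", function(object) {
  msgs <- character()
  if (!all(c("name", "start", "end") %in% colnames(object@windows))) {
    msgs <- c(msgs, "windows needs columns name, start, end")
  } else {
    if (any(object@windows$start >= object@windows$end)) {
      msgs <- c(msgs, "window start must be < end")
    }
    if (anyDuplicated(object@windows$name)) {
      msgs <- c(msgs, "window names must be unique")
    }
  }
  if (!object@motifSequence %in% c("extended", "core")) {
    msgs <- c(msgs, "motifSequence must be 'extended' or 'core'")
  }
  if (length(msgs)) msgs else TRUE
})

#' Rule: one interpretable activation/repression rule
#'
#' An antecedent over the Region scalar (a union of intervals with explicit
#' endpoint openness) and motif-count predicates, with a role consequent.
#'
#' @slot name rule label (e.g. "A1").
#' @slot consequent `"activator"` or `"repressor"`.
#' @slot region data.frame of interval rows `lo`, `hi`, `loOpen`, `hiOpen`;
#'   a site's Region must fall in at least one row (zero rows = no region
#'   constraint).
#' @slot motifs data.frame of predicates `feature`, `op`, `value` with
#'   `op` one of `"le"`, `"ge"`, `"gt"`, `"absent"` (count == 0).
#' @slot stats list of coverage statistics filled by [ruleCoverage()].
#' @export
setClass("Rule", representation(
  name = "character",
  consequent = "character",
  region = "data.frame",
  motifs = "data.frame",
  stats = "list"
))

setValidity("Rule", function(object) {
  msgs <- character()
  if (!object@consequent %in% c("activator", "repressor")) {
    msgs <- c(msgs, "consequent must be activator or repressor")
  }
  if (nrow(object@region) == 0 && nrow(object@motifs) == 0) {
    msgs <- c(msgs, "a rule needs at least one predicate")
  }
  if (nrow(object@motifs) && !all(object@motifs$op %in% c("le", "ge", "gt", "absent"))) {
    msgs <- c(msgs, "motif op must be le, ge, gt or absent")
  }
  if (length(msgs)) msgs else TRUE
})

#' RuleSet: an ordered first-match rule classifier
#'
#' @slot rules list of [Rule-class] objects, evaluated in order.
#' @slot fallback policy for sites matching no rule: `"uncovered"` (default)
#'   or `"majority"`.
#' @export
setClass("RuleSet", representation(
  rules = "list",
  fallback = "character"
))

setValidity("RuleSet", function(object) {
  if (!all(vapply(object@rules, is, logical(1), class2 = "Rule"))) {
    return("rules must all be Rule objects")
  }
  if (!object@fallback %in% c("uncovered", "majority")) {
    return("fallback must be 'uncovered' or 'majority'")
  }
  TRUE
})

#' DecisionTree: a C4.5-style gain-ratio decision tree
#'
#' Binary tree over numeric features with axis-parallel splits `x <= t`;
#' thresholds are midpoints between adjacent observed values, so integer
#' features split at half-integers.
#'
#' @slot root recursive node list (split nodes: `feature`, `threshold`,
#'   `left`, `right`; leaves: `class`, `counts`).
#' @slot features feature names seen at fitting time.
#' @slot classes class labels (factor levels of the response).
#' @export
setClass("DecisionTree", representation(
  root = "list",
  features = "character",
  classes = "character"
))

#' ConfusionMetrics: binary confusion counts and derived scores
#'
#' Repressor is the positive class throughout: sensitivity is the fraction
#' of repressor sites recovered, specificity the fraction of activator sites.
#'
#' @slot tp,fp,tn,fn confusion counts.
#' @slot acc,sen,spe,mcc accuracy, sensitivity, specificity and Matthews
#'   correlation coefficient (0 when its denominator vanishes).
#' @slot positive the positive class label.
#' @export
setClass("ConfusionMetrics", representation(
  tp = "numeric", fp = "numeric", tn = "numeric", fn = "numeric",
  acc = "numeric", sen = "numeric", spe = "numeric", mcc = "numeric",
  positive = "character"
))

#' CrpModel: a fitted RBF-SVM role predictor
#'
#' Wraps an [e1071::svm] fit together with the selected feature mask and the
#' training-set standardization, so prediction on new feature matrices is
#' self-contained and reproducible.
#'
#' @slot fit the underlying svm object.
#' @slot featureNames selected feature columns, in training order.
#' @slot center,scaleSd per-feature standardization parameters.
#' @slot gamma,cost RBF kernel width and soft-margin cost.
#' @slot levels class labels, `c("activator", "repressor")`.
#' @export
setClass("CrpModel", representation(
  fit = "ANY",
  featureNames = "character",
  center = "numeric",
  scaleSd = "numeric",
  gamma = "numeric",
  cost = "numeric",
  levels = "character"
))

#' SelectionResult: the IBCGA feature-subset sweep
#'
#' @slot perR list indexed by subset size r: each element has `mask`
#'   (selected column indices), `fitness` (cross-validation accuracy).
#' @slot bestR the chosen subset size m (highest fitness, ties to smaller r).
#' @slot bestMask selected feature indices of the winning subset S_m.
#' @slot bestFeatures names of the winning features.
#' @slot svmParams named numeric `gamma`, `cost` re-tuned on S_m.
#' @slot history data.frame of per-(r, generation) best fitness.
#' @slot config the GA configuration used.
#' @export
setClass("SelectionResult", representation(
  perR = "list",
  bestR = "integer",
  bestMask = "integer",
  bestFeatures = "character",
  svmParams = "numeric",
  history = "data.frame",
  config = "list"
))
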