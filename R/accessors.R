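# Accessors and show methods for the S4 containers.

#' @rdname SiteSet-class
#' @param object,x a `SiteSet`.
#' @export
setGeneric("siteInfo", function(object) standardGeneric("siteInfo"))

#' @rdname SiteSet-class
#' @export
setMethod("siteInfo", "SiteSet", function(object) object@info)

#' @rdname SiteSet-class
#' @export
setGeneric("siteIds", function(object) standardGeneric("siteIds"))

#' @rdname SiteSet-class
#' @export
setMethod("siteIds", "SiteSet", function(object) object@info$site_id)

#' @rdname SiteSet-class
#' @export
setGeneric("coreSeqs", function(object) standardGeneric("coreSeqs"))

#' @rdname SiteSet-class
#' @export
setMethod("coreSeqs", "SiteSet", function(object) object@coreSeqs)

#' @rdname SiteSet-class
#' @export
setGeneric("extendedSeqs", function(object) standardGeneric("extendedSeqs"))

#' @rdname SiteSet-class
#' @export
setMethod("extendedSeqs", "SiteSet", function(object) object@extendedSeqs)

#' @rdname SiteSet-class
#' @export
setGeneric("roles", function(object) standardGeneric("roles"))

#' @rdname SiteSet-class
#' @export
setMethod("roles", "SiteSet", function(object) object@info$role)

#' Site centres on the TSS-relative axis
#'
#' The "Region" scalar of the interpretable rules under its default
#' (centre) semantics: `(left + right) / 2`, a half-integer for the
#' standard even-length 22-nt sites.
#'
#' @param object a `SiteSet`.
#' @return numeric vector of centres, named by site id.
#' @export
setGeneric("siteCenters", function(object) standardGeneric("siteCenters"))

#' @rdname siteCenters
#' @export
setMethod("siteCenters", "SiteSet", function(object) {
  stats::setNames((object@info$left + object@info$right) / 2,
                  object@info$site_id)
})

#' @rdname SiteSet-class
#' @export
setGeneric("curationLog", function(object) standardGeneric("curationLog"))

#' @rdname SiteSet-class
#' @export
setMethod("curationLog", "SiteSet", function(object) object@curationLog)

#' @rdname SiteSet-class
#' @export
setMethod("length", "SiteSet", function(x) nrow(x@info))

#' Subset a SiteSet
#'
#' @param x a `SiteSet`.
#' @param i logical, integer or character (site id) index.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "SiteSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@info$site_id)
  info <- x@info[i, , drop = FALSE]
  rownames(info) <- NULL
  new("SiteSet",
      info = info,
      coreSeqs = x@coreSeqs[i],
      extendedSeqs = if (length(x@extendedSeqs)) x@extendedSeqs[i]
                     else x@extendedSeqs,
      name = x@name, provenance = x@provenance,
      curationLog = x@curationLog, metadata = x@metadata)
})

setMethod("show", "SiteSet", function(object) {
  n <- length(object)
  tab <- table(factor(object@info$role,
                      levels = c("activator", "repressor", "unknown")))
  cat(sprintf("SiteSet '%s': %d site(s) (%d activator, %d repressor, %d unknown)\n",
              object@name, n, tab[["activator"]], tab[["repressor"]],
              tab[["unknown"]]))
  cat(sprintf("  extended sequences: %s\n",
              if (length(object@extendedSeqs)) "present" else "absent"))
  if (length(object@curationLog)) {
    cat("  curation:", paste(object@curationLog, collapse = "; "), "\n")
  }
})

#' Total dimension of a descriptor layout
#'
#' @param object a `DescriptorSpec`.
#' @return integer, 380 for the default layout.
#' @export
setGeneric("descriptorDimension", function(object) standardGeneric("descriptorDimension"))

#' @rdname descriptorDimension
#' @export
setMethod("descriptorDimension", "DescriptorSpec", function(object) {
  as.integer(sum(4^object@kmerSizes) + nrow(object@windows) +
             length(object@physchem) + 40L)
})

setMethod("show", "DescriptorSpec", function(object) {
  cat(sprintf(
    "DescriptorSpec: %d features (%s k-mer composition + %d windows + %d physicochemical + 40 global)\n",
    descriptorDimension(object),
    paste(4^object@kmerSizes, collapse = " + "),
    nrow(object@windows), length(object@physchem)))
  cat(sprintf("  motif/composition sequence: %s\n", object@motifSequence))
})

setMethod("show", "Rule", function(object) {
  reg <- if (nrow(object@region) == 0) "any Region" else {
    paste(apply(object@region, 1, function(r) {
      sprintf("%s%s, %s%s",
              if (as.logical(r[["loOpen"]])) "(" else "[",
              format(as.numeric(r[["lo"]])),
              format(as.numeric(r[["hi"]])),
              if (as.logical(r[["hiOpen"]])) ")" else "]")
    }), collapse = " U ")
  }
  mot <- if (nrow(object@motifs) == 0) "" else {
    paste(" & ", paste(mapply(function(f, op, v) {
      switch(op,
             absent = sprintf("no %s", f),
             le = sprintf("%s <= %g", f, v),
             ge = sprintf("%s >= %g", f, v),
             gt = sprintf("%s > %g", f, v))
    }, object@motifs$feature, object@motifs$op, object@motifs$value),
    collapse = " & "), sep = "")
  }
  cat(sprintf("Rule %s: Region in %s%s => %s\n",
              object@name, reg, mot, object@consequent))
})

setMethod("show", "RuleSet", function(object) {
  cat(sprintf("RuleSet of %d rule(s), first-match, fallback = '%s'\n",
              length(object@rules), object@fallback))
  for (r in object@rules) show(r)
})

#' @rdname RuleSet-class
#' @param x a `RuleSet`.
#' @export
setMethod("length", "RuleSet", function(x) length(x@rules))

#' @rdname RuleSet-class
#' @export
setGeneric("ruleNames", function(object) standardGeneric("ruleNames"))

#' @rdname RuleSet-class
#' @param object a `RuleSet`.
#' @export
setMethod("ruleNames", "RuleSet", function(object) {
  vapply(object@rules, function(r) r@name, character(1))
})

setMethod("show", "ConfusionMetrics", function(object) {
  cat(sprintf("ConfusionMetrics (positive class: %s)\n", object@positive))
  cat(sprintf("  TP=%d FP=%d TN=%d FN=%d\n",
              object@tp, object@fp, object@tn, object@fn))
  cat(sprintf("  ACC=%.2f SEN=%.2f SPE=%.2f MCC=%.2f\n",
              object@acc, object@sen, object@spe, object@mcc))
})

#' Metrics as a one-row data.frame
#'
#' Counts plus ACC/SEN/SPE/MCC at full precision; printing rounds to two
#' decimals, matching the field's reporting convention.
#'
#' @param object a `ConfusionMetrics`.
#' @return data.frame with columns TP, FP, TN, FN, ACC, SEN, SPE, MCC.
#' @export
setGeneric("metricsTable", function(object) standardGeneric("metricsTable"))

#' @rdname metricsTable
#' @export
setMethod("metricsTable", "ConfusionMetrics", function(object) {
  data.frame(TP = object@tp, FP = object@fp, TN = object@tn, FN = object@fn,
             ACC = object@acc, SEN = object@sen, SPE = object@spe,
             MCC = object@mcc)
})

setMethod("show", "CrpModel", function(object) {
  cat(sprintf("CrpModel: RBF SVM on %d feature(s), gamma=%g, cost=%g\n",
              length(object@featureNames), object@gamma, object@cost))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: r swept %s..%s; best r = %d (CV accuracy %.3f)\n",
              min(as.integer(names(object@perR))),
              max(as.integer(names(object@perR))),
              object@bestR, object@perR[[as.character(object@bestR)]]$fitness))
  cat("  features:", paste(object@bestFeatures, collapse = ", "), "\n")
})

setMethod("show", "DecisionTree", function(object) {
  printNode <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (isTRUE(node$leaf)) {
      cat(sprintf("%s=> %s (%s)\n", pad, node$class,
                  paste(sprintf("%s:%d", names(node$counts), node$counts),
                        collapse = ", ")))
    } else {
      cat(sprintf("%s%s <= %g\n", pad, node$feature, node$threshold))
      printNode(node$left, indent + 1)
      cat(sprintf("%s%s > %g\n", pad, node$feature, node$threshold))
      printNode(node$right, indent + 1)
    }
  }
  cat("C4.5-style DecisionTree\n")
  printNode(object@root, 0)
})
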