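# C4.5-style decision-tree induction: gain-ratio splits on numeric features
# with midpoint thresholds, minimum-leaf-size stopping and pessimistic
# (confidence-bound) subtree-replacement pruning, plus root-to-leaf rule
# extraction.

entropyOf <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# binomial upper confidence limit on the error rate, the C4.5 pessimistic
# error estimate (Clopper-Pearson upper bound at confidence cf)
pessimisticErrors <- function(n, e, cf = 0.25) {
  if (n == 0) return(0)
  n * stats::qbeta(1 - cf, e + 1, n - e)
}

bestSplit <- function(X, y, minLeaf) {
  n <- length(y)
  baseH <- entropyOf(table(y))
  best <- NULL
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    ux <- sort(unique(x))
    if (length(ux) < 2) next
    thr <- (ux[-1] + ux[-length(ux)]) / 2  # midpoints
    for (t in thr) {
      leftIdx <- x <= t
      nl <- sum(leftIdx)
      if (nl < minLeaf || n - nl < minLeaf) next
      hl <- entropyOf(table(y[leftIdx]))
      hr <- entropyOf(table(y[!leftIdx]))
      gain <- baseH - (nl / n) * hl - ((n - nl) / n) * hr
      if (gain <= 1e-12) next
      pl <- nl / n
      splitInfo <- -(pl * log2(pl) + (1 - pl) * log2(1 - pl))
      ratio <- gain / splitInfo
      if (is.null(best) || ratio > best$ratio + 1e-12) {
        best <- list(feature = j, threshold = t, ratio = ratio)
      }
    }
  }
  best
}

growTree <- function(X, y, minLeaf, minSplit) {
  counts <- table(y)
  leaf <- function() {
    cls <- names(counts)[which.max(counts)]
    list(leaf = TRUE, class = cls,
         counts = stats::setNames(as.integer(counts), names(counts)),
         n = length(y), errors = length(y) - max(counts))
  }
  if (length(y) < minSplit || sum(counts > 0) < 2) return(leaf())
  split <- bestSplit(X, y, minLeaf)
  if (is.null(split)) return(leaf())
  idx <- X[, split$feature] <= split$threshold
  list(leaf = FALSE,
       feature = colnames(X)[split$feature], featureIdx = split$feature,
       threshold = split$threshold,
       counts = stats::setNames(as.integer(counts), names(counts)),
       n = length(y),
       left = growTree(X[idx, , drop = FALSE], y[idx], minLeaf, minSplit),
       right = growTree(X[!idx, , drop = FALSE], y[!idx], minLeaf, minSplit))
}

pruneNode <- function(node, cf) {
  if (isTRUE(node$leaf)) return(node)
  node$left <- pruneNode(node$left, cf)
  node$right <- pruneNode(node$right, cf)
  subtreeErr <- function(nd) {
    if (isTRUE(nd$leaf)) pessimisticErrors(nd$n, nd$errors, cf)
    else subtreeErr(nd$left) + subtreeErr(nd$right)
  }
  leafErrHere <- pessimisticErrors(node$n, node$n - max(node$counts), cf)
  if (leafErrHere <= subtreeErr(node) + 1e-9) {
    cls <- names(node$counts)[which.max(node$counts)]
    return(list(leaf = TRUE, class = cls, counts = node$counts,
                n = node$n, errors = node$n - max(node$counts)))
  }
  node
}

#' Fit a C4.5-style decision tree
#'
#' Binary splits on numeric features chosen by information gain ratio, with
#' thresholds at midpoints between adjacent observed values (so integer
#' features split at half-integers). Stopping uses a minimum node/leaf size;
#' optional pruning replaces subtrees whose pessimistic (upper-confidence)
#' error is no better than a single leaf's. Fitting is deterministic given
#' input order; no randomness is used.
#'
#' @param X data.frame or matrix of numeric features.
#' @param y class labels (factor or character); a single-class `y` yields a
#'   one-leaf tree.
#' @param minLeaf minimum observations per leaf (default 2).
#' @param minSplit minimum observations to attempt a split (default 4).
#' @param prune apply pessimistic-error pruning (default TRUE).
#' @param cf pruning confidence level (default 0.25, the C4.5 convention).
#' @return a [DecisionTree-class].
#' @export
fitC45 <- function(X, y, minLeaf = 2L, minSplit = 4L, prune = TRUE,
                   cf = 0.25) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- factor(y)
  root <- growTree(X, y, minLeaf, minSplit)
  if (prune) root <- pruneNode(root, cf)
  new("DecisionTree", root = root, features = colnames(X),
      classes = levels(y))
}

#' Predict classes with a decision tree
#'
#' @param tree a [DecisionTree-class].
#' @param X data.frame or matrix containing the tree's feature columns.
#' @return character vector of predicted classes.
#' @export
predictC45 <- function(tree, X) {
  X <- as.matrix(X)
  one <- function(node, row) {
    while (!isTRUE(node$leaf)) {
      node <- if (row[[node$feature]] <= node$threshold) node$left
              else node$right
    }
    node$class
  }
  vapply(seq_len(nrow(X)), function(i) one(tree@root, X[i, ]), character(1))
}

#' Extract root-to-leaf rules from a decision tree
#'
#' One rule per leaf: the conjunction of split conditions along the path,
#' with redundant bounds on the same feature collapsed into a single
#' interval. Conditions on a `region` feature populate the rule's region
#' slot; all other features become threshold predicates. Stats are computed
#' on the supplied dataset. The leaves partition the feature space, so the
#' extracted rules classify identically to the tree.
#'
#' @param tree a [DecisionTree-class].
#' @param X feature data used for coverage statistics.
#' @param y labels for the same rows.
#' @param regionFeature name of the feature to treat as the Region scalar
#'   (default `"region"`).
#' @return list of [Rule-class] objects, one per leaf.
#' @export
extractRules <- function(tree, X, y, regionFeature = "region") {
  X <- as.data.frame(X)
  y <- as.character(y)
  rules <- list()
  walk <- function(node, bounds) {
    if (isTRUE(node$leaf)) {
      region <- data.frame(lo = numeric(), hi = numeric(),
                           loOpen = logical(), hiOpen = logical())
      motifs <- data.frame(feature = character(), op = character(),
                           value = numeric(), stringsAsFactors = FALSE)
      for (f in names(bounds)) {
        b <- bounds[[f]]
        if (f == regionFeature) {
          region <- data.frame(lo = b["lo"], hi = b["hi"],
                               loOpen = TRUE, hiOpen = FALSE,
                               row.names = NULL)
        } else {
          if (is.finite(b["hi"])) {
            motifs <- rbind(motifs, data.frame(
              feature = f, op = "le", value = unname(b["hi"])))
          }
          if (is.finite(b["lo"])) {
            motifs <- rbind(motifs, data.frame(
              feature = f, op = "gt", value = unname(b["lo"])))
          }
        }
      }
      cls <- node$class
      rules[[length(rules) + 1L]] <<- new(
        "Rule", name = sprintf("path%02d", length(rules) + 1L),
        consequent = if (cls %in% c("activator", "repressor")) cls
                     else "activator",
        region = region, motifs = motifs,
        stats = list(leafCounts = node$counts, leafClass = cls))
      return(invisible())
    }
    f <- node$feature
    b <- bounds[[f]] %||% c(lo = -Inf, hi = Inf)
    bl <- b; bl["hi"] <- min(b["hi"], node$threshold)
    br <- b; br["lo"] <- max(b["lo"], node$threshold)
    boundsL <- bounds; boundsL[[f]] <- bl
    boundsR <- bounds; boundsR[[f]] <- br
    walk(node$left, boundsL)
    walk(node$right, boundsR)
  }
  walk(tree@root, list())
  # leaf class may be outside the role vocabulary for generic trees; keep the
  # raw class in stats and compute per-rule counts on the dataset
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    matched <- matchesRule(r, X, regionFeature = regionFeature,
                           rawClass = TRUE)
    cls <- r@stats$leafClass
    r@stats$covered_total <- sum(matched)
    r@stats$correct <- sum(matched & y == cls)
    rules[[i]] <- r
  }
  rules
}
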