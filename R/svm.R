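# RBF-SVM training, prediction and cross-validated fitness. The SVM is the
# inner classifier of the wrapper feature selection; repressor is the
# positive class everywhere.

roleFactor <- function(y) {
  y <- as.character(y)
  bad <- !y %in% c("activator", "repressor")
  if (any(bad)) stop("labels must be 'activator' or 'repressor'")
  factor(y, levels = c("activator", "repressor"))
}

standardizeTrain <- function(X) {
  ctr <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  list(X = scale(X, center = ctr, scale = sd), center = ctr, scale = sd)
}

standardizeApply <- function(X, ctr, sd) {
  scale(X, center = ctr, scale = sd)
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# round-robin so fold sizes differ by at most one per class.
stratifiedFolds <- function(y, folds, seed) {
  y <- roleFactor(y)
  minClass <- min(table(y))
  if (minClass < folds) {
    warning(sprintf("smallest class has %d members; reducing folds from %d to %d",
                    minClass, folds, minClass))
    folds <- minClass
  }
  assign <- integer(length(y))
  withSeed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

svmFit <- function(X, y, gamma, cost) {
  e1071::svm(x = X, y = y, kernel = "radial", gamma = gamma, cost = cost,
             scale = FALSE)
}

# Decision scores oriented so that larger means more repressor-like.
svmScores <- function(fit, X) {
  pr <- stats::predict(fit, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  lab <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
  s <- as.numeric(dv[, 1])
  if (lab[1] != "repressor") s <- -s
  list(labels = as.character(pr), scores = s)
}

cvAccuracyFolds <- function(X, y, foldAssign, gamma, cost) {
  y <- roleFactor(y)
  correct <- 0L
  for (f in sort(unique(foldAssign))) {
    tr <- foldAssign != f
    st <- standardizeTrain(X[tr, , drop = FALSE])
    fit <- svmFit(st$X, y[tr], gamma, cost)
    Xte <- standardizeApply(X[!tr, , drop = FALSE], st$center, st$scale)
    pred <- stats::predict(fit, Xte)
    correct <- correct + sum(as.character(pred) == as.character(y[!tr]))
  }
  correct / length(y)
}

#' Cross-validated SVM accuracy of a feature subset
#'
#' The fitness function of the wrapper selection: stratified k-fold
#' cross-validation accuracy of an RBF-kernel SVM restricted to the masked
#' feature columns. With 24 repressors and `folds = 24`, each fold holds
#' exactly one repressor, maximizing the number of repressors available for
#' training. Deterministic under the seed; if the smallest class has fewer
#' than `folds` members the fold count is reduced with a warning.
#'
#' @param X numeric feature matrix (rows = sites).
#' @param y roles (`"activator"`/`"repressor"`).
#' @param mask logical vector over columns, or integer column indices; must
#'   select at least one feature.
#' @param folds number of CV folds (default 24).
#' @param gamma,cost RBF SVM parameters.
#' @param seed integer seed for the fold assignment.
#' @return accuracy in \[0, 1\].
#' @export
cvFitness <- function(X, y, mask = rep(TRUE, ncol(X)), folds = 24L,
                      gamma = 0.05, cost = 8, seed = 1L) {
  if (is.logical(mask)) mask <- which(mask)
  if (length(mask) == 0) stop("mask must select at least one feature")
  foldAssign <- stratifiedFolds(y, folds, seed)
  cvAccuracyFolds(X[, mask, drop = FALSE], y, foldAssign, gamma, cost)
}

#' Grid search for SVM parameters
#'
#' Returns the `(gamma, cost)` grid point maximizing cross-validated
#' accuracy; ties are broken toward the smallest cost, then the smallest
#' gamma.
#'
#' @param X,y feature matrix and roles.
#' @param grid list with numeric elements `gamma` and `cost`.
#' @param folds CV folds.
#' @param seed integer seed.
#' @return named numeric vector `c(gamma=, cost=, accuracy=)`.
#' @export
gridSearchSvm <- function(X, y,
                          grid = list(gamma = 2^seq(-7, 1, by = 2),
                                      cost = 2^seq(-1, 7, by = 2)),
                          folds = 5L, seed = 1L) {
  if (!length(grid$gamma) || !length(grid$cost)) {
    stop("svm grid must contain gamma and cost candidates")
  }
  foldAssign <- stratifiedFolds(y, folds, seed)
  best <- NULL
  # iterate cost outer-descending? no: scan in increasing cost then gamma so
  # the first strict improvement wins and ties keep the smallest values
  for (cost in sort(grid$cost)) {
    for (gamma in sort(grid$gamma)) {
      acc <- cvAccuracyFolds(X, y, foldAssign, gamma, cost)
      if (is.null(best) || acc > best[["accuracy"]] + 1e-12) {
        best <- c(gamma = gamma, cost = cost, accuracy = acc)
      }
    }
  }
  best
}

#' Train the role-prediction SVM on selected features
#'
#' Fits an RBF SVM on the masked, standardized feature columns. The returned
#' model stores the feature names, standardization and kernel parameters, so
#' it survives serialization (`saveRDS`/`readRDS`) and refuses feature
#' matrices whose columns do not match.
#'
#' @param X numeric feature matrix with column names.
#' @param y roles.
#' @param mask logical/integer column selection (default: all columns).
#' @param gamma,cost RBF SVM parameters.
#' @return a [CrpModel-class].
#' @export
trainModel <- function(X, y, mask = rep(TRUE, ncol(X)), gamma = 0.05,
                       cost = 8) {
  if (is.logical(mask)) mask <- which(mask)
  if (length(mask) == 0) stop("mask must select at least one feature")
  Xm <- X[, mask, drop = FALSE]
  st <- standardizeTrain(Xm)
  fit <- svmFit(st$X, roleFactor(y), gamma, cost)
  new("CrpModel", fit = fit,
      featureNames = colnames(Xm) %||% as.character(mask),
      center = st$center, scaleSd = st$scale,
      gamma = gamma, cost = cost,
      levels = c("activator", "repressor"))
}

#' Predict roles with a trained model
#'
#' @param model a [CrpModel-class].
#' @param X feature matrix containing (at least) the model's feature columns.
#' @return list with `labels` (character roles) and `scores` (decision
#'   values, larger = more repressor-like, usable for ROC curves), both named
#'   by rownames of `X`.
#' @export
predictRoles <- function(model, X) {
  stopifnot(is(model, "CrpModel"))
  missing <- setdiff(model@featureNames, colnames(X))
  if (length(missing)) {
    stop("feature matrix lacks model columns: ",
         paste(missing, collapse = ", "))
  }
  Xm <- standardizeApply(X[, model@featureNames, drop = FALSE],
                         model@center, model@scaleSd)
  out <- svmScores(model@fit, Xm)
  names(out$labels) <- rownames(X)
  names(out$scores) <- rownames(X)
  out
}
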