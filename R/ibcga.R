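# Inheritable bi-objective combinatorial GA for wrapper feature selection:
# solve C(n, r) for r = rStart..rEnd in one run, inheriting each size-r
# population into size r+1, and report the sweep plus the best subset S_m.

#' GA configuration for [ibcgaSelect()]
#'
#' @param rStart,rEnd subset-size sweep bounds (default 5..30).
#' @param populationSize individuals per generation (default 50).
#' @param generationsPerR generations evolved at each subset size (default 30).
#' @param mutationRate per-offspring probability of a swap mutation
#'   (one selected index exchanged with one unselected), default 0.05.
#' @param crossover `"uniform"` (uniform crossover followed by repair to
#'   exactly r selected features). An orthogonal-array "intelligent"
#'   crossover can be plugged in via `crossoverFun(parentA, parentB, r, n)`.
#' @param eliteCount individuals carried over unchanged (default 1).
#' @param cvFolds folds of the cross-validated fitness (default 24).
#' @param svmGrid list of `gamma` and `cost` candidates; the grid is searched
#'   once on the full matrix to fix the kernel parameters used during the
#'   sweep, and again on the winning subset.
#' @param seed integer master seed (folds and evolution both derive from it).
#' @param crossoverFun optional custom crossover function.
#' @return list of class `gaConfig`.
#' @export
gaConfig <- function(rStart = 5L, rEnd = 30L, populationSize = 50L,
                     generationsPerR = 30L, mutationRate = 0.05,
                     crossover = c("uniform", "intelligent"),
                     eliteCount = 1L, cvFolds = 24L,
                     svmGrid = list(gamma = 2^seq(-7, 1, by = 2),
                                    cost = 2^seq(-1, 7, by = 2)),
                     seed = 1L, crossoverFun = NULL) {
  crossover <- match.arg(crossover)
  stopifnot(rStart >= 1, rEnd >= rStart, populationSize >= 2,
            mutationRate >= 0, mutationRate <= 1)
  structure(list(rStart = as.integer(rStart), rEnd = as.integer(rEnd),
                 populationSize = as.integer(populationSize),
                 generationsPerR = as.integer(generationsPerR),
                 mutationRate = mutationRate, crossover = crossover,
                 eliteCount = as.integer(eliteCount),
                 cvFolds = as.integer(cvFolds), svmGrid = svmGrid,
                 seed = as.integer(seed), crossoverFun = crossoverFun),
            class = "gaConfig")
}

# uniform crossover of two index sets, repaired to exactly r indices:
# shared indices are kept, the remainder is filled from the symmetric
# difference at random, topped up from outside if the union is too small.
uniformCrossover <- function(a, b, r, n) {
  common <- intersect(a, b)
  pool <- setdiff(union(a, b), common)
  child <- common
  if (length(child) > r) {
    child <- sample(child, r)
  } else if (length(pool) > 0) {
    take <- min(r - length(child), length(pool))
    if (take > 0) child <- c(child, sample(pool, take))
  }
  if (length(child) < r) {
    outside <- setdiff(seq_len(n), child)
    child <- c(child, sample(outside, r - length(child)))
  }
  sort(child)
}

swapMutation <- function(mask, n) {
  out <- setdiff(seq_len(n), mask)
  if (!length(out) || !length(mask)) return(mask)
  drop <- sample(length(mask), 1L)
  add <- out[sample(length(out), 1L)]
  sort(c(mask[-drop], add))
}

maskKey <- function(mask) paste(mask, collapse = ",")

#' Inheritable bi-objective combinatorial feature selection
#'
#' Sweeps subset sizes r from `rStart` to `rEnd`. At each r a population of
#' exactly-r-feature masks is evolved with tournament selection, crossover
#' with repair (offspring always have exactly r features), swap mutation and
#' elitism, under the cross-validated SVM accuracy fitness. The best mask of
#' size r seeds size r+1: every individual inherits its mask plus one random
#' unselected feature. The sweep's best solution S_m (highest fitness, ties
#' broken toward fewer features) is re-tuned with a fresh SVM grid search.
#'
#' @param X numeric feature matrix with >= `rEnd` columns.
#' @param y roles.
#' @param cfg a [gaConfig()].
#' @return a [SelectionResult-class].
#' @export
ibcgaSelect <- function(X, y, cfg = gaConfig()) {
  n <- ncol(X)
  if (cfg$rEnd > n) stop("rEnd exceeds the number of features")
  y <- roleFactor(y)
  foldAssign <- stratifiedFolds(y, cfg$cvFolds, deriveSeed(cfg$seed, "cv-folds"))

  params <- withSeed(deriveSeed(cfg$seed, "grid"), {
    gridSearchSvm(X, y, grid = cfg$svmGrid,
                  folds = min(cfg$cvFolds, min(table(y))),
                  seed = deriveSeed(cfg$seed, "grid-folds"))
  })
  gamma <- params[["gamma"]]; cost <- params[["cost"]]

  cache <- new.env(parent = emptyenv())
  evalMask <- function(mask) {
    key <- maskKey(mask)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    fit <- cvAccuracyFolds(X[, mask, drop = FALSE], y, foldAssign, gamma, cost)
    cache[[key]] <- fit
    fit
  }
  xover <- cfg$crossoverFun %||% uniformCrossover

  perR <- list()
  hist <- list()
  withSeed(deriveSeed(cfg$seed, "evolution"), {
    pop <- replicate(cfg$populationSize,
                     sort(sample(n, cfg$rStart)), simplify = FALSE)
    for (r in seq(cfg$rStart, cfg$rEnd)) {
      fitness <- vapply(pop, evalMask, numeric(1))
      for (g in seq_len(cfg$generationsPerR)) {
        ord <- order(fitness, decreasing = TRUE)
        newPop <- pop[ord[seq_len(min(cfg$eliteCount, length(pop)))]]
        while (length(newPop) < cfg$populationSize) {
          pick <- function() {
            cand <- sample(length(pop), 2L)
            if (fitness[cand[1]] >= fitness[cand[2]]) cand[1] else cand[2]
          }
          child <- xover(pop[[pick()]], pop[[pick()]], r, n)
          if (stats::runif(1) < cfg$mutationRate) {
            child <- swapMutation(child, n)
          }
          # duplicate replacement: a child identical to one already in the
          # offspring pool is forced through a swap mutation, keeping the
          # population diverse without raising the mutation rate
          key <- maskKey(child)
          if (any(vapply(newPop, maskKey, character(1)) == key)) {
            child <- swapMutation(child, n)
          }
          newPop[[length(newPop) + 1L]] <- child
        }
        pop <- newPop
        fitness <- vapply(pop, evalMask, numeric(1))
        hist[[length(hist) + 1L]] <- data.frame(
          r = r, generation = g, best = max(fitness))
      }
      bestIdx <- which.max(fitness)
      perR[[as.character(r)]] <- list(mask = pop[[bestIdx]],
                                       fitness = fitness[bestIdx])
      if (r < cfg$rEnd) {
        # inheritance: grow every individual by one random unselected feature
        pop <- lapply(pop, function(mask) {
          outside <- setdiff(seq_len(n), mask)
          sort(c(mask, outside[sample(length(outside), 1L)]))
        })
      }
    }
  })

  fitnesses <- vapply(perR, function(x) x$fitness, numeric(1))
  rs <- as.integer(names(perR))
  bestR <- rs[order(-fitnesses, rs)][1]  # ties -> smaller r (parsimony)
  bestMask <- perR[[as.character(bestR)]]$mask

  finalParams <- withSeed(deriveSeed(cfg$seed, "regrid"), {
    gridSearchSvm(X[, bestMask, drop = FALSE], y, grid = cfg$svmGrid,
                  folds = min(cfg$cvFolds, min(table(y))),
                  seed = deriveSeed(cfg$seed, "regrid-folds"))
  })

  new("SelectionResult",
      perR = perR, bestR = bestR, bestMask = as.integer(bestMask),
      bestFeatures = (colnames(X) %||% as.character(seq_len(n)))[bestMask],
      svmParams = c(gamma = finalParams[["gamma"]],
                    cost = finalParams[["cost"]]),
      history = do.call(rbind, hist),
      config = unclass(cfg)[setdiff(names(cfg), "crossoverFun")])
}

#' Serialize a SelectionResult to JSON
#'
#' @param result a [SelectionResult-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeSelectionResult <- function(result, path) {
  obj <- list(
    bestR = result@bestR,
    bestMask = result@bestMask,
    bestFeatures = result@bestFeatures,
    svmParams = as.list(result@svmParams),
    perR = lapply(result@perR, function(x)
      list(mask = x$mask, fitness = x$fitness)),
    config = result@config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
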