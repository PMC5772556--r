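# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed, runs `code`, and restores the caller's `.Random.seed`, so
#' seeded package operations never perturb the global RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage-specific seed from a global seed
#'
#' One user-facing seed fans out to independent per-stage streams (generator,
#' split, GA, cross-validation) so each stage is reproducible in isolation.
#' The derivation is a fixed integer hash of the stage name; results stay
#' within the 32-bit signed range.
#'
#' @param seed Integer master seed.
#' @param stage Character stage label.
#' @return An integer seed.
#' @export
deriveSeed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (v in utf8ToInt(stage)) h <- (h * 131 + v) %% 1999999973
  as.integer(((as.numeric(seed) %% 65011 + 1) * 32609 + h) %% 2147483629)
}

# Vectorized check that strings are DNA over an allowed alphabet.
isDnaString <- function(x, allowN = TRUE) {
  pat <- if (allowN) "^[ACGTNacgtn]*$" else "^[ACGTacgt]*$"
  grepl(pat, x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
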