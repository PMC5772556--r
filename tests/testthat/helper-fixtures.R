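# In-code fixtures shared across test files.

# A labeled feature table with two planted informative columns (x1 + x2
# determines the class with a clean margin) among noise columns.
makePlantedTable <- function(n = 60, p = 50, seed = 1) {
  crproles:::withSeed(seed, {
    X <- matrix(stats::runif(n * p, -1, 1), n, p)
    keep <- abs(X[, 1] + X[, 2]) > 0.4
    while (sum(keep) < n) {
      X[!keep, 1:2] <- stats::runif(2 * sum(!keep), -1, 1)
      keep <- abs(X[, 1] + X[, 2]) > 0.4
    }
    colnames(X) <- paste0("f", seq_len(p))
    list(X = X, y = ifelse(X[, 1] + X[, 2] > 0, "repressor", "activator"))
  })
}

# Hand-written six-row site table covering each curation filter:
# one non-CRP TF, one weak-evidence, two exact duplicates at one TSS,
# one 21-nt site, one clean site.
writeCurationFixture <- function(path) {
  seq22 <- "AAATGTGATCTAGATCACATTT"
  seq21 <- "AAATGTGATCTAGATCACATT"
  tab <- data.frame(
    site_id = paste0("s", 1:6),
    tf_name = c("FNR", "CRP", "CRP", "CRP", "CRP", "CRP"),
    gene = paste0("g", 1:6),
    left = c(1001, 1001, 2001, 2001, 3001, 4001),
    right = c(1022, 1022, 2022, 2022, 3021, 4022),
    tss = c(1060, 1060, 2060, 2060, 3060, 4060),
    strand = "+",
    sequence = c(seq22, seq22, seq22, seq22, seq21, seq22),
    evidence = c("strong", "weak", "strong", "strong", "strong", "strong"),
    role = c("activator", "activator", "repressor", "repressor",
             "activator", "activator"),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# SiteSet with exact class sizes (roles overwritten on a generated set).
makeSitesWithRoles <- function(nRep, nAct, seed = 1) {
  s <- generateSites(synthConfig(nSites = nRep + nAct, seed = seed))
  s@info$role <- c(rep("repressor", nRep), rep("activator", nAct))
  s
}

# Independent transcription of the four published rules, used as the
# enumeration oracle for the canonical ruleset.
oracleRole <- function(R, TTTT, AACG, TTAC, GAGC) {
  a1 <- (R <= -49.5 | R >= 49.5) & TTTT <= 2
  a2 <- (R >= -70.5 & R <= -28.5) & AACG == 0
  r1 <- ((R > 2 & R < 70.5) | (R >= -49.5 & R < -10)) & TTAC == 0
  r2 <- (R >= -31 & R <= 23) & TTAC == 0 & GAGC == 0
  ifelse(a1, "activator",
         ifelse(a2, "activator",
                ifelse(r1, "repressor",
                       ifelse(r2, "repressor", "uncovered"))))
}
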