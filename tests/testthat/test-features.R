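test_that("k-mer composition counts overlapping words in lexicographic order", {
  v <- kmerComposition("TTTTT", 4)
  expect_length(v, 256L)
  expect_equal(unname(v[["TTTT"]]), 2L)
  expect_equal(sum(v), 2L)

  v2 <- kmerComposition("ACGT", 4)
  expect_equal(unname(v2[["ACGT"]]), 1L)
  expect_equal(sum(v2), 1L)
  expect_equal(names(v2)[1], "AAAA")
  expect_equal(names(v2)[256], "TTTT")

  # conservation: counts over an N-free sequence of length L sum to L - k + 1
  crproles:::withSeed(5, {
    for (i in 1:20) {
      L <- sample(10:60, 1)
      s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
      expect_equal(sum(kmerComposition(s, 3)), L - 2)
    }
  })

  # windows containing N contribute nothing
  expect_equal(sum(kmerComposition("AANAA", 3)), 0L)
  # k longer than the sequence: all-zero vector, not an error
  expect_equal(sum(kmerComposition("ACG", 4)), 0L)
})

test_that("hand-counted oracle agrees with the k-mer block", {
  countOracle <- function(s, word) {
    k <- nchar(word)
    sum(vapply(seq_len(nchar(s) - k + 1),
               function(i) substr(s, i, i + k - 1) == word, logical(1)))
  }
  crproles:::withSeed(11, {
    for (i in 1:10) {
      s <- paste(sample(c("A", "C", "G", "T"), 42, replace = TRUE),
                 collapse = "")
      v <- kmerComposition(s, 4)
      for (w in sample(names(v), 8)) {
        expect_equal(unname(v[[w]]), countOracle(s, w))
      }
    }
  })
})

test_that("window overlap equals integer-position enumeration", {
  expect_equal(windowOverlap(-52, -31, -35, -10), 5L)
  expect_equal(windowOverlap(-80, -59, -35, -10), 0L)
  expect_equal(windowOverlap(-30, -9, -35, -10), 21L)
  expect_equal(windowOverlap(-52, -31, -95, -35), 18L)

  enumerate <- function(l, r, a, b) sum(seq(l, r) >= a & seq(l, r) <= b)
  crproles:::withSeed(21, {
    for (i in 1:1000) {
      l <- sample(-120:90, 1); r <- l + sample(0:40, 1)
      a <- stats::runif(1, -130, 90); b <- a + stats::runif(1, 0, 80)
      got <- windowOverlap(l, r, a, b)
      expect_identical(got, as.integer(enumerate(l, r, a, b)))
      # bounded by both lengths
      expect_lte(got, r - l + 1)
    }
  })
})

test_that("physicochemical block behaves as composition-only scalars", {
  expect_equal(physicochemicalDescriptor("GGCC")[["gc_content"]], 1.0)
  expect_equal(physicochemicalDescriptor("ATAT")[["gc_content"]], 0.0)
  # reverse complement preserves GC fraction
  s <- "ATGGCATTAC"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(physicochemicalDescriptor(s)[["gc_content"]],
               physicochemicalDescriptor(rc)[["gc_content"]])
  expect_equal(physicochemicalDescriptor("ATGC")[["tm_wallace"]], 12)
  expect_warning(z <- physicochemicalDescriptor("NNNN"), "no unambiguous")
  expect_equal(unname(z), c(0, 0, 0))
})

test_that("global descriptor has 40 features with the documented structure", {
  g <- globalDescriptor("AAAAAAAA")
  expect_length(g, 40L)
  expect_equal(g[["frac_A"]], 1.0)
  expect_equal(g[["dinuc_AA"]], 1.0)
  expect_equal(g[["dist_A_first"]], 1 / 8)
  expect_equal(g[["dist_A_last"]], 1.0)
  expect_equal(g[["dist_C_first"]], 0)  # absent base -> zeros

  crproles:::withSeed(31, {
    for (i in 1:10) {
      s <- paste(sample(c("A", "C", "G", "T"), 42, replace = TRUE),
                 collapse = "")
      g <- globalDescriptor(s)
      expect_length(g, 40L)
      expect_equal(sum(g[paste0("frac_", c("A", "C", "G", "T"))]), 1.0)
      expect_equal(sum(g[grep("^dinuc_", names(g))]), 1.0)
    }
  })
})

test_that("the full descriptor is 380-dimensional with stable block layout", {
  spec <- descriptorSpec()
  expect_equal(descriptorDimension(spec), 380L)
  nm <- descriptorNames(spec)
  expect_length(nm, 380L)
  expect_false(anyDuplicated(nm) > 0)
  expect_equal(sum(startsWith(nm, "kmer4_")), 256L)
  expect_equal(sum(startsWith(nm, "kmer3_")), 64L)
  expect_equal(sum(grepl("^L\\d+$", nm)), 17L)

  # published windows are fixed exactly
  w <- spec@windows
  expect_equal(unlist(w[w$name == "L3", c("start", "end")],
                      use.names = FALSE), c(-35, -10))
  expect_equal(unlist(w[w$name == "L6", c("start", "end")],
                      use.names = FALSE), c(-10, 2))
  expect_equal(unlist(w[w$name == "L12", c("start", "end")],
                      use.names = FALSE), c(-60, 60))
  expect_equal(unlist(w[w$name == "L15", c("start", "end")],
                      use.names = FALSE), c(-95, -35))

  sites <- extendSites(generateSites(synthConfig(nSites = 5, seed = 13)))
  X <- extractFeatures(sites, spec)
  expect_equal(dim(X), c(5L, 380L))
  expect_equal(colnames(X), nm)
  # k-mer counts are non-negative integers
  km <- X[, startsWith(nm, "kmer4_") | startsWith(nm, "kmer3_")]
  expect_true(all(km >= 0 & km == floor(km)))
  # determinism: identical sequence and interval give identical vectors
  expect_identical(extractFeatures(sites, spec), X)
  # extraction requires extension
  expect_error(extractFeatures(generateSites(synthConfig(nSites = 2, seed = 1))),
               "extendSites")
})

test_that("a site centred at the Class II anchor has the published overlaps", {
  # site [-52, -31] (centre -41.5): overlap 5 with [-35, -10], 18 with
  # [-95, -35], verified by enumeration above
  sites <- extendSites(generateSites(synthConfig(nSites = 3, seed = 2)))
  sites@info$left <- c(-52L, -52L, -52L)
  sites@info$right <- c(-31L, -31L, -31L)
  X <- extractFeatures(sites)
  expect_equal(unname(X[1, "L3"]), 5)
  expect_equal(unname(X[1, "L15"]), 18)
  expect_equal(unname(X[1, "L12"]), 22)
})

test_that("feature names round-trip through the on-disk table", {
  sites <- extendSites(generateSites(synthConfig(nSites = 4, seed = 3)))
  X <- extractFeatures(sites)
  path <- tempfile(fileext = ".tsv")
  writeFeatureTable(X, path)
  X2 <- readFeatureTable(path)
  expect_equal(colnames(X2), colnames(X))
  expect_equal(rownames(X2), rownames(X))
  expect_equal(X2, X, tolerance = 1e-12)
  expect_true(file.exists(paste0(path, ".spec.json")))
})

test_that("rule features expose Region and motif counts under both scopes", {
  sites <- extendSites(generateSites(synthConfig(nSites = 10, seed = 8)))
  rf <- ruleFeatures(sites)
  expect_equal(colnames(rf), c("region", "TTTT", "AACG", "TTAC", "GAGC"))
  expect_equal(rf$region, unname(siteCenters(sites)))
  # motif counts agree with direct pattern counting on the extension
  expect_equal(rf$TTTT,
               Biostrings::vcountPattern("TTTT", extendedSeqs(sites)))
  rfCore <- ruleFeatures(sites, sequence = "core")
  expect_true(all(rfCore$TTTT <= rf$TTTT))
  rfLeft <- ruleFeatures(sites, semantics = "leftmost")
  expect_equal(rfLeft$region, siteInfo(sites)$left)
})
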