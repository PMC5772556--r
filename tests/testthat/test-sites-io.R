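test_that("parsing a site table populates every field and rejects bad rows", {
  path <- writeCurationFixture(tempfile(fileext = ".tsv"))
  sites <- parseSiteTable(path)
  expect_s4_class(sites, "SiteSet")
  expect_length(sites, 6L)
  info <- siteInfo(sites)
  expect_equal(info$site_id, paste0("s", 1:6))
  # plus strand: TSS-relative = absolute - tss
  expect_equal(info$left[1], 1001 - 1060)
  expect_equal(info$right[1], 1022 - 1060)
  expect_equal(nrow(sites@metadata$rejects), 0L)

  # malformed rows go to the reject report, not silently dropped
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$left[2] <- "not-a-number"
  tab$role[3] <- "mystery"
  path2 <- tempfile(fileext = ".tsv")
  utils::write.table(tab, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  sites2 <- parseSiteTable(path2)
  expect_length(sites2, 4L)
  expect_setequal(sites2@metadata$rejects$reason,
                  c("unparseable coordinate", "unknown role token"))
})

test_that("a missing mandatory column is a configuration error", {
  path <- writeCurationFixture(tempfile(fileext = ".tsv"))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$strand <- NULL
  path2 <- tempfile(fileext = ".tsv")
  utils::write.table(tab, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(parseSiteTable(path2), "strand")
})

test_that("a header-only file yields an empty SiteSet", {
  path <- writeCurationFixture(tempfile(fileext = ".tsv"))
  writeLines(readLines(path)[1], path)
  sites <- parseSiteTable(path)
  expect_length(sites, 0L)
})

test_that("minus-strand sites are reflected so downstream of TSS is positive", {
  tab <- data.frame(
    site_id = "m1", tf_name = "CRP", gene = "g",
    left = 5019, right = 5040, tss = 5000, strand = "-",
    sequence = "AAATGTGATCTAGATCACATTT",
    evidence = "strong", role = "activator", stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sites <- parseSiteTable(path)
  info <- siteInfo(sites)
  # genomically downstream-of-TSS (higher coordinate) on the minus strand is
  # biologically upstream: the interval lands on the negative half-axis
  expect_equal(info$left, -40)
  expect_equal(info$right, -19)
  # reflection is an involution: writing and re-parsing restores coordinates
  path2 <- tempfile(fileext = ".tsv")
  writeSiteTable(sites, path2)
  info2 <- siteInfo(parseSiteTable(path2))
  expect_equal(info2$left, info$left)
  expect_equal(info2$right, info$right)
})

test_that("curation applies the four filters in order and logs counts", {
  sites <- parseSiteTable(writeCurationFixture(tempfile(fileext = ".tsv")))
  cur <- curateSites(sites, tf = "CRP", evidence = "strong")
  expect_length(cur, 2L)
  # the first duplicate survives; the clean site survives
  expect_equal(siteIds(cur), c("s3", "s6"))
  expect_length(curationLog(cur), 4L)
  expect_match(curationLog(cur)[1], "removed 1")
  expect_match(curationLog(cur)[3], "removed 1")  # one duplicate dropped

  # idempotence
  cur2 <- curateSites(cur)
  expect_equal(siteIds(cur2), siteIds(cur))

  # an all-clean input passes through unchanged
  clean <- generateSites(synthConfig(nSites = 12, seed = 4))
  expect_equal(siteIds(curateSites(clean)), siteIds(clean))
})

test_that("flank extension produces 22 + 2k sequences and N-pads shortfalls", {
  sites <- generateSites(synthConfig(nSites = 8, seed = 9))
  ext <- extendSites(sites, k = 10)
  expect_true(all(Biostrings::width(extendedSeqs(ext)) == 42))
  # core is the central 22-mer
  expect_equal(
    as.character(Biostrings::subseq(extendedSeqs(ext), 11, width = 22)),
    as.character(coreSeqs(ext)))
  # coordinates unchanged
  expect_equal(siteInfo(ext)$left, siteInfo(sites)$left)

  # k = 0 leaves the core untouched
  ext0 <- extendSites(sites, k = 0)
  expect_equal(as.character(extendedSeqs(ext0)), as.character(coreSeqs(sites)))

  # short flanks are N-padded to exactly 22 + 2k with a warning
  short <- sites
  short@info$left_flank <- substr(short@info$left_flank, 7, 10)
  expect_warning(extS <- extendSites(short, k = 10), "N-padded")
  expect_true(all(Biostrings::width(extendedSeqs(extS)) == 42))
  expect_true(all(startsWith(as.character(extendedSeqs(extS)), "NNNNNN")))

  expect_error(extendSites(sites, k = -1), "k")
})

test_that("the stratified 2:1 split reproduces per-class counts exactly", {
  sites <- makeSitesWithRoles(nRep = 36, nAct = 133, seed = 2)
  sp <- splitDataset(sites, ratio = c(2, 1), seed = 7)
  expect_length(sp$train, 113L)
  expect_length(sp$test, 56L)
  expect_equal(sum(roles(sp$train) == "repressor"), 24L)
  expect_equal(sum(roles(sp$train) == "activator"), 89L)
  expect_equal(sum(roles(sp$test) == "repressor"), 12L)
  expect_equal(sum(roles(sp$test) == "activator"), 44L)

  # partition: disjoint and exhaustive
  expect_length(intersect(siteIds(sp$train), siteIds(sp$test)), 0L)
  expect_setequal(c(siteIds(sp$train), siteIds(sp$test)), siteIds(sites))

  # deterministic under seed
  sp2 <- splitDataset(sites, ratio = c(2, 1), seed = 7)
  expect_identical(siteIds(sp2$train), siteIds(sp$train))

  # degenerate ratio: everything in train
  spAll <- splitDataset(sites, ratio = c(1, 0), seed = 7)
  expect_length(spAll$train, 169L)
  expect_length(spAll$test, 0L)
})

test_that("per-class split counts deviate from the exact ratio by at most one", {
  for (seed in 1:5) {
    nRep <- 10 + seed; nAct <- 40 + 3 * seed
    sp <- splitDataset(makeSitesWithRoles(nRep, nAct, seed = seed),
                       ratio = c(2, 1), seed = seed)
    for (cl in c("repressor", "activator")) {
      nCl <- if (cl == "repressor") nRep else nAct
      got <- sum(roles(sp$test) == cl)
      expect_lte(abs(got - nCl / 3), 1)
    }
  }
})
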