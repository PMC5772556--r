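test_that("the canonical ruleset carries the published predicates", {
  rs <- canonicalRuleset()
  expect_length(rs, 4L)
  expect_equal(ruleNames(rs), c("A1", "A2", "R1", "R2"))
  cons <- vapply(rs@rules, function(r) r@consequent, character(1))
  expect_equal(unname(cons),
               c("activator", "activator", "repressor", "repressor"))

  a1 <- rs@rules[[1]]
  expect_equal(a1@region$lo, c(-Inf, 49.5))
  expect_equal(a1@region$hi, c(-49.5, Inf))
  expect_false(any(a1@region$hiOpen[1], a1@region$loOpen[2]))
  expect_equal(a1@motifs$feature, "TTTT")
  expect_equal(a1@motifs$value, 2)

  r1 <- rs@rules[[3]]
  expect_equal(r1@region$lo, c(2, -49.5))
  expect_equal(r1@region$hi, c(70.5, -10))
  expect_true(r1@region$loOpen[1] && r1@region$hiOpen[1])   # 2 < R < 70.5
  expect_false(r1@region$loOpen[2]); expect_true(r1@region$hiOpen[2])
})

test_that("boundary truth table matches the enumeration oracle exactly", {
  regions <- c(-80, -70.5, -55, -49.5, -49.4, -31, -28.5, -10, 0, 2, 2.1,
               23, 49.5, 70.4, 70.5)
  combos <- expand.grid(TTTT = c(0, 3), AACG = c(0, 1),
                        TTAC = c(0, 1), GAGC = c(0, 1))
  grid <- merge(data.frame(region = regions), combos)
  expected <- oracleRole(grid$region, grid$TTTT, grid$AACG,
                         grid$TTAC, grid$GAGC)
  got <- applyRuleset(grid, canonicalRuleset())
  expect_identical(got$role, unname(expected))

  # hand-frozen endpoint checks
  one <- function(R, TTTT = 0, AACG = 0, TTAC = 0, GAGC = 0) {
    applyRuleset(data.frame(region = R, TTTT = TTTT, AACG = AACG,
                            TTAC = TTAC, GAGC = GAGC))
  }
  expect_equal(one(-49.5)$role, "activator")        # A1 closed at -49.5
  expect_equal(one(-49.5)$first_rule, "A1")
  expect_equal(one(-49.4)$first_rule, "A2")         # just inside A2 only
  expect_equal(one(-55, TTTT = 3)$first_rule, "A2") # A1 blocked by motif cap
  expect_equal(one(10)$role, "repressor")
  expect_equal(one(10)$matched, "R1,R2")            # both match, R1 first
  expect_equal(one(70.5)$first_rule, "A1")          # R1 open at 70.5
  expect_equal(one(2)$first_rule, "R2")             # R1 open at 2, R2 covers
  expect_equal(one(-80, TTTT = 3, AACG = 1)$role, "uncovered")
})

test_that("first-match order is respected and fallback policies work", {
  f <- data.frame(region = -80, TTTT = 3, AACG = 1, TTAC = 0, GAGC = 0)
  expect_equal(applyRuleset(f, canonicalRuleset())$role, "uncovered")
  expect_equal(applyRuleset(f, canonicalRuleset(fallback = "majority"))$role,
               "activator")
  # missing required feature errors by name
  expect_error(applyRuleset(data.frame(region = 0, TTTT = 0, AACG = 0,
                                       TTAC = 0)), "GAGC")
})

test_that("rule coverage and accuracy follow the published counting scheme", {
  sites <- extendSites(generateSites(
    synthConfig(nSites = 250, uncoveredFraction = 0, seed = 31)))
  rf <- ruleFeatures(sites)
  cov <- ruleCoverage(canonicalRuleset(), rf, roles(sites))
  tab <- cov$perRule
  expect_equal(tab$rule, c("A1", "A2", "R1", "R2"))
  # noise-free rule-generated data: a matching antecedent can still cover a
  # site of the other class only if an earlier rule claimed it; coverage
  # numerators never exceed the class totals and accuracies are in (0, 1]
  expect_true(all(tab$covered <= tab$class_total))
  expect_true(all(tab$covered <= tab$n_matched))
  expect_equal(tab$coverage, tab$covered / tab$class_total)
  expect_equal(tab$accuracy, tab$covered / tab$n_matched)
  expect_equal(cov$coveredFraction, 1.0)

  # with the uncovered tail present the covered fraction drops below 1
  sites2 <- extendSites(generateSites(synthConfig(nSites = 250, seed = 32)))
  cov2 <- ruleCoverage(canonicalRuleset(), ruleFeatures(sites2),
                       roles(sites2))
  expect_lt(cov2$coveredFraction, 1.0)
  expect_gt(cov2$coveredFraction, 0.6)

  # rule matching nothing reports NA accuracy
  never <- new("RuleSet", rules = list(crproles:::makeRule(
    "X", "repressor", crproles:::interval(900, 901),
    data.frame(feature = character(), op = character(), value = numeric()))),
    fallback = "uncovered")
  cov3 <- ruleCoverage(never, rf, roles(sites))
  expect_equal(cov3$perRule$covered, 0)
  expect_true(is.na(cov3$perRule$accuracy))

  # empty dataset -> empty table
  cov4 <- ruleCoverage(canonicalRuleset(), rf[0, ], character())
  expect_equal(nrow(cov4$perRule), 0L)
})

test_that("rulesets survive JSON serialization with identical predicates", {
  rs <- canonicalRuleset()
  path <- tempfile(fileext = ".json")
  writeRuleset(rs, path)
  rs2 <- readRuleset(path)
  expect_equal(ruleNames(rs2), ruleNames(rs))
  expect_equal(rs2@fallback, rs@fallback)
  for (i in seq_along(rs@rules)) {
    expect_equal(rs2@rules[[i]]@region, rs@rules[[i]]@region)
    expect_equal(rs2@rules[[i]]@motifs, rs@rules[[i]]@motifs)
    expect_equal(rs2@rules[[i]]@consequent, rs@rules[[i]]@consequent)
  }
  # identical classifications after the round trip
  grid <- data.frame(region = seq(-90, 80, by = 1.5), TTTT = 1, AACG = 0,
                     TTAC = 0, GAGC = 0)
  expect_identical(applyRuleset(grid, rs2)$role, applyRuleset(grid, rs)$role)
})
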