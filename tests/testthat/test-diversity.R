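test_that("rarefaction conserves depth, is seeded, and signals exclusion", {
  counts <- c(a = 500L, b = 300L, c = 150L, d = 50L)
  r <- rarefyCounts(counts, 200, seed = 5)
  expect_equal(sum(r), 200)
  expect_true(all(r <= counts))
  expect_identical(r, rarefyCounts(counts, 200, seed = 5))
  # depth equal to the total leaves the sample unchanged
  expect_identical(rarefyCounts(counts, 1000L, seed = 1), counts)
  # too-shallow samples raise an explicit exclusion condition
  expect_error(rarefyCounts(counts, 2000, seed = 1),
               class = "darkbinRarefactionExclusion")
})

test_that("rarefied richness matches the hypergeometric expectation", {
  counts <- c(40L, 12L, 6L, 3L, 1L, 1L)
  depth <- 20
  rich <- vapply(1:400, function(s)
    sum(rarefyCounts(counts, depth, seed = s) > 0), 0)
  analytic <- expectedRarefiedRichness(counts, depth)
  expect_lt(abs(mean(rich) - analytic) / analytic, 0.03)
  # cross-check the closed form itself against the field's standard tool
  expect_equal(analytic,
               unname(vegan::rarefy(matrix(counts, 1), depth)[1]),
               tolerance = 1e-8)
})

test_that("alpha diversity matches closed forms and the direct oracle", {
  one <- alphaDiversity(c(x = 10))
  expect_equal(one$richness, 1L)
  expect_equal(one$gini_simpson, 0)

  four <- alphaDiversity(c(5, 5, 5, 5))
  expect_equal(four$gini_simpson, 0.75)       # 1 - 4 * (1/4)^2

  set.seed(161)
  for (rep in 1:10) {
    v <- rpois(8, 20) + 1
    p <- v / sum(v)
    expect_equal(alphaDiversity(v)$gini_simpson, 1 - sum(p * p))
    expect_equal(alphaDiversity(v)$gini_simpson,
                 unname(vegan::diversity(v, index = "simpson")))
  }
  # bounded by 1 - 1/richness, attained only at uniformity
  v <- c(10, 10, 10)
  expect_equal(alphaDiversity(v)$gini_simpson, 1 - 1 / 3)
  expect_lt(alphaDiversity(c(20, 5, 5))$gini_simpson, 1 - 1 / 3)
  expect_error(alphaDiversity(c(0, 0)), "empty")
})

test_that("Bray-Curtis matches closed forms and vegan", {
  p <- c(0.5, 0.5, 0)
  expect_equal(brayCurtis(p, p), 0)
  expect_equal(brayCurtis(c(1, 0, 0), c(0, 0.4, 0.6)), 1)  # disjoint
  expect_equal(brayCurtis(p, c(1, 0, 0)), 0.5)
  set.seed(171)
  for (rep in 1:10) {
    a <- rexp(6); a <- a / sum(a)
    b <- rexp(6); b <- b / sum(b)
    expect_equal(brayCurtis(a, b), brayCurtis(b, a))
    expect_equal(brayCurtis(a, b),
                 unname(as.numeric(vegan::vegdist(rbind(a, b), "bray"))))
    expect_gte(brayCurtis(a, b), 0)
    expect_lte(brayCurtis(a, b), 1)
  }
})

test_that("intra/inter partition covers each unordered pair once", {
  counts <- matrix(rep(c(10L, 20L, 30L), 4), nrow = 3)
  meta <- data.frame(sample_id = paste0("s", 1:4),
                     patient = c("P1", "P1", "P2", "P2"),
                     site = "ear", side = c("left", "right"),
                     disease_state = "unaffected")
  se <- abundanceTable(counts, meta)
  b <- intraInterBeta(se)
  # all samples identical -> all distances zero
  expect_true(all(c(b$intra, b$inter) == 0))
  expect_equal(length(b$intra) + length(b$inter), choose(4, 2))
  expect_equal(length(b$intra), 2)
})

test_that("Welch's t matches the textbook formula and the pooled limit", {
  a <- c(4.1, 5.2, 6.3, 5.8, 4.9)
  b <- c(7.0, 8.1, 6.5, 7.7, 8.4, 7.9)
  got <- welchT(a, b)
  want <- welchOracle(a, b)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
  expect_equal(got$df, want$df, tolerance = 1e-12)
  expect_equal(got$p_value, want$p_value, tolerance = 1e-12)

  # identical groups: statistic 0, p = 1
  same <- welchT(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # equal n and equal variance: agrees with the pooled t within 1e-6
  x <- c(1, 2, 3, 4, 5)
  y <- x + 2
  pooled <- t.test(x, y, var.equal = TRUE)
  wt <- welchT(x, y)
  expect_equal(wt$statistic, unname(pooled$statistic), tolerance = 1e-6)
  expect_equal(wt$p_value, pooled$p.value, tolerance = 1e-6)

  expect_error(welchT(rep(1, 3), rep(2, 3)), "zero variance")
})

test_that("the paired test handles degenerate pairings", {
  mkSe <- function(dCounts, uCounts, nPat) {
    rows <- list(); cols <- list(); k <- 0
    for (p in seq_len(nPat)) for (st in c("diseased", "unaffected")) {
      k <- k + 1
      rows[[k]] <- data.frame(
        sample_id = sprintf("P%d_%s", p, st), patient = sprintf("P%d", p),
        site = "ear", side = if (st == "diseased") "left" else "right",
        disease_state = st)
      cols[[k]] <- if (st == "diseased") dCounts else uCounts
    }
    m <- do.call(cbind, cols)
    rownames(m) <- paste0("t", seq_along(dCounts))
    abundanceTable(m, do.call(rbind, rows))
  }

  # all pairs identical -> every p = 1
  se <- mkSe(c(100L, 200L, 300L), c(100L, 200L, 300L), 8)
  pt <- pairedSiteTest(se, seed = 1)
  expect_true(all(pt$p_raw == 1))
  expect_true(all(pt$direction == "none"))

  # a single pair is flagged as underpowered and returns p = 1
  se1 <- mkSe(c(100L, 200L, 300L), c(150L, 180L, 270L), 1)
  expect_warning(pt1 <- pairedSiteTest(se1, seed = 1), "pairs")
  expect_true(all(pt1$p_raw == 1))

  # no eligible pairs at all is an error
  bad <- mkSe(c(1L, 2L, 3L), c(1L, 2L, 3L), 2)
  SummarizedExperiment::colData(bad)$disease_state <- "unaffected"
  expect_error(pairedSiteTest(bad, seed = 1), "no eligible")
})

test_that("a planted disease effect is recovered with correct direction", {
  hits <- vapply(1:3, function(s) {
    se <- simulateCohort(cohortSpec(20, effectMultiplier = 2,
                                    depthPerSample = 20000, seed = s))
    pt <- pairedSiteTest(se, seed = 100 + s)
    row <- pt[pt$taxon == "Staphylococcus", ]
    row$p_adjusted < 0.05 && row$direction == "diseased_up"
  }, TRUE)
  expect_true(all(hits))
})
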