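# Identity fractions, pair validation, stratification metrics.

test_that("identity fraction follows the shared-variant formula", {
  a <- makeCallSet("A", c(100, 200, 300))
  b <- SampleCallSet("B", makeCalls(c(200, 300, 400)))
  expect_equal(identityFraction(a, a), 1)
  expect_equal(identityFraction(a, b), 2 * 2 / 6)
  d <- makeCallSet("D", c(700, 800))
  expect_equal(identityFraction(a, d), 0)
  expect_error(identityFraction(SampleCallSet("E", data.frame()),
                                SampleCallSet("F", data.frame())),
               "undefined")
})

test_that("identity keys on the full variant, not the position", {
  a <- makeCallSet("A", c(100, 200), alt = "G")
  b <- makeCallSet("B", c(100, 200), alt = "T")
  expect_equal(identityFraction(a, b), 0)
})

test_that("identity matrix is symmetric with unit diagonal", {
  m <- identityMatrix(list(makeCallSet("A", c(100, 200, 300)),
                           makeCallSet("B", c(200, 300, 400)),
                           makeCallSet("C", c(700, 800))))
  expect_equal(diag(m), c(A = 1, B = 1, C = 1))
  expect_equal(m, t(m))
  expect_equal(m["A", "C"], 0)
  expect_equal(m["A", "B"], 2 / 3)
})

test_that("declared pairs are mutual best matches on simulated cohorts", {
  sim <- smallSim(2)
  m <- identityMatrix(sim$cohort)
  rep <- validatePairs(m, sim$design)
  paired <- rep[!is.na(rep$declared_kin), ]
  expect_true(all(paired$is_declared_kin))
  # a sib pair is a strictly better match than any unrelated sample
  p <- designPairs(sim$design)
  for (i in seq_len(nrow(p))) {
    s1 <- p$sample1[i]; s2 <- p$sample2[i]
    others <- setdiff(rownames(m), c(s1, s2))
    expect_gt(m[s1, s2], max(m[s1, others]))
    expect_gt(m[s1, s2], max(m[s2, others]))
  }
})

test_that("the box-whisker outlier rule flags only strong best matches", {
  set.seed(31)
  ids <- c(sprintf("U%02d", 1:18), "K1", "K2")
  nn <- length(ids)
  m <- matrix(0.30 + runif(nn * nn, -0.02, 0.02), nn, nn,
              dimnames = list(ids, ids))
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  diag(m) <- 1
  m["K1", "K2"] <- m["K2", "K1"] <- 0.8
  design <- CohortDesign(
    samples = data.frame(sample_id = ids),
    pairs = data.frame(sample1 = "K1", sample2 = "K2",
                       relationship = "brothers"),
    sporadic = ids[1:18])
  rep <- validatePairs(m, design)
  expect_true(all(rep$is_outlier[rep$sample %in% c("K1", "K2")]))
  expect_false(any(rep$is_outlier[!(rep$sample %in% c("K1", "K2"))]))
  expect_true(all(rep$is_declared_kin[rep$sample %in% c("K1", "K2")]))
})

test_that("swapped design labels are flagged inconsistent", {
  sim <- smallSim(2)
  d <- sim$design
  p <- designPairs(d)
  # swap one member of pair 1 with one member of pair 2
  p$sample2[1:2] <- p$sample2[2:1]
  bad <- CohortDesign(designSamples(d), p, designSporadic(d))
  rep <- validatePairs(identityMatrix(sim$cohort), bad)
  swapped <- rep$sample %in% c(p$sample1[1:2], p$sample2[1:2])
  expect_false(any(rep$is_declared_kin[swapped]))
})

test_that("stratification metrics: degenerate and constant cases", {
  cs <- lapply(c("A", "B", "C"), function(id) makeCallSet(id, c(100, 200)))
  panel <- ReferencePanel(data.frame(
    chrom = "X", pos = c(100, 200), ref = "A", alt = "G",
    maf = 0.3, freq_popA = 0.5, freq_popB = 0.1))
  sm <- stratificationMetrics(cs, panel)
  expect_equal(sm$rss_sd, rep(0, 3))   # identical samples, zero RSS spread
  expect_equal(sm$ea_metric, rep(0.5, 3))
  expect_equal(sm$aa_metric, rep(0.1, 3))
  expect_false(any(sm$flagged))
})

test_that("a population-B sample maximizes aa metric and RSS deviation", {
  set.seed(9)
  n <- 1200
  pos <- sort(sample.int(1e8, n))
  fA <- rbeta(n, 1, 6)
  fB <- rbeta(n, 1, 6)  # population B has its own variant spectrum
  panel <- ReferencePanel(data.frame(
    chrom = "X", pos = pos, ref = "A", alt = "G", maf = fA,
    freq_popA = fA, freq_popB = fB))
  draw <- function(id, f) {
    g <- runif(n) < f
    makeCallSet(id, pos[g])
  }
  cohort <- c(lapply(sprintf("A%02d", 1:19), draw, f = fA),
              list(draw("B01", fB)))
  sm <- stratificationMetrics(cohort, panel)
  expect_equal(sm$sample[which.max(sm$aa_metric)], "B01")
  expect_equal(sm$sample[which.max(sm$rss_sd)], "B01")
})
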