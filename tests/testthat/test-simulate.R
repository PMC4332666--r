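# Synthetic cohort generator: determinism, constructed truth, and
# statistical structure.

test_that("identical seeds give identical panels and cohorts", {
  cfg <- simulationConfig(nSporadic = 4L,
                          pairRelationships = rep("brothers", 2),
                          nPanelVariants = 400L)
  p1 <- simulateReferencePanel(cfg, 11)
  p2 <- simulateReferencePanel(cfg, 11)
  expect_identical(panelRecords(p1), panelRecords(p2))
  s1 <- simulateCohort(cfg, p1, 11)
  s2 <- simulateCohort(cfg, p2, 11)
  for (s in names(s1$cohort))
    expect_identical(calls(s1$cohort[[s]]), calls(s2$cohort[[s]]))
  expect_identical(s1$truth$causal, s2$truth$causal)
  sc1 <- simulateRecurrentPathogenicScenario(11)
  sc2 <- simulateRecurrentPathogenicScenario(11)
  expect_identical(sc1$key, sc2$key)
  expect_identical(calls(sc1$cohort[[sc1$carriers[1]]]),
                   calls(sc2$cohort[[sc2$carriers[1]]]))
})

test_that("panel pathogenic flags and carrier counts track frequency", {
  cfg <- simulationConfig(nPanelVariants = 4000L, pathogenicFrac = 0)
  p <- simulateReferencePanel(cfg, 12)
  rec <- panelRecords(p)
  expect_true(all(rec$clin_sig == "none"))
  # E[male_carrier_count] = 525 * maf, site by site
  resid <- rec$male_carrier_count - 525 * rec$maf
  se <- sqrt(sum(525 * rec$maf * (1 - rec$maf))) / nrow(rec)
  expect_lt(abs(mean(resid)), 3 * se)
  expect_true(all(rec$allele_count >= rec$male_carrier_count))
  # no panel site inside the pseudoautosomal mask
  expect_false(any((rec$pos - 1 >= parMaskHg19$start[1] &
                      rec$pos - 1 < parMaskHg19$end[1]) |
                     (rec$pos - 1 >= parMaskHg19$start[2] &
                        rec$pos - 1 < parMaskHg19$end[2])))
})

test_that("with all error rates zero, discordance is confined outside
           true shared segments", {
  sim <- smallSim(15, strandBiasRate = 0, clusterRate = 0,
                  batchSystematicPerBatch = 0L, discordanceNoiseRate = 0)
  expect_equal(nrow(sim$truth$errors), 0L)
  p <- designPairs(sim$design)
  for (i in seq_len(nrow(p))) {
    tr <- discordanceTrack(sim$cohort[[p$sample1[i]]],
                           sim$cohort[[p$sample2[i]]])
    segs <- sim$truth$segments[[p$sample1[i]]]
    ar <- tr[tr$status == "AR", , drop = FALSE]
    expect_length(pointsInside(ar, segs$start, segs$end), 0L)
  }
})

test_that("constructed truth keeps causal, panel and error keys disjoint", {
  sim <- smallSim(16)
  ck <- causalKey(sim$truth$causal)
  expect_false(any(ck %in% panelKeys(sim$panel)))
  for (nm in c("dbsnp", "evs", "male1000g"))
    expect_false(any(ck %in% panelKeys(sim$panels[[nm]])))
  ek <- causalKey(sim$truth$errors)
  expect_false(any(ck %in% ek))
  # each pair's causal key lies inside one of its true shared segments
  ca <- sim$truth$causal
  pairCa <- ca[grepl(",", ca$sample_ids), ]
  for (i in seq_len(nrow(pairCa))) {
    s1 <- strsplit(pairCa$sample_ids[i], ",")[[1]][1]
    segs <- sim$truth$segments[[s1]]
    expect_true(any(pairCa$pos[i] - 1 >= segs$start &
                      pairCa$pos[i] - 1 < segs$end))
  }
})

test_that("batch-systematic keys recur in unrelated same-batch samples", {
  sim <- smallSim(17)
  be <- sim$truth$errors[sim$truth$errors$class == "batch", ]
  kin <- kinOf(sim$design)
  for (k in unique(causalKey(be))) {
    carriers <- be$sample_id[causalKey(be) == k]
    expect_gte(length(carriers), 2L)
    unrelatedPair <- FALSE
    for (a in carriers) for (b in setdiff(carriers, a))
      if (is.na(kin[a]) || kin[[a]] != b) unrelatedPair <- TRUE
    expect_true(unrelatedPair)
  }
})

test_that("noise-free pair identity exceeds any sporadic identity", {
  sim <- smallSim(18, strandBiasRate = 0, clusterRate = 0,
                  batchSystematicPerBatch = 0L, discordanceNoiseRate = 0)
  m <- identityMatrix(sim$cohort)
  p <- designPairs(sim$design)
  pairIdent <- min(vapply(seq_len(nrow(p)), function(i)
    m[p$sample1[i], p$sample2[i]], numeric(1)))
  for (s in designSporadic(sim$design)) {
    others <- setdiff(rownames(m), s)
    expect_gt(pairIdent, max(m[s, others]))
  }
})

test_that("the recurrent-pathogenic fixture plants one rare annotated key
           in two sporadic samples and one pair", {
  sc <- simulateRecurrentPathogenicScenario(19)
  expect_length(sc$carriers, 4L)
  kin <- kinOf(sc$design)
  expect_true(all(is.na(kin[sc$carriers[1:2]])))
  expect_equal(kin[[sc$carriers[3]]], sc$carriers[4])
  for (s in sc$carriers)
    expect_true(sc$key %in% variantKeys(sc$cohort[[s]]))
  crec <- panelRecords(sc$panels$clinical)
  hit <- variantKey(crec) == sc$key
  expect_true(any(hit))
  expect_equal(crec$clin_sig[hit], "pathogenic")
  expect_lt(crec$maf[hit], 0.01)
})
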