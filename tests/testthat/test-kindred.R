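# The affected-kindred/cross-cohort filter and clinical rescue.

# cohort: one brother pair (K1, K2) and two sporadic samples (U1, U2)
kindredFixture <- function(callsOf) {
  cohort <- lapply(names(callsOf), function(s)
    SampleCallSet(s, makeCalls(callsOf[[s]])))
  names(cohort) <- names(callsOf)
  design <- CohortDesign(
    samples = data.frame(sample_id = names(callsOf)),
    pairs = data.frame(sample1 = "K1", sample2 = "K2",
                       relationship = "brothers"),
    sporadic = setdiff(names(callsOf), c("K1", "K2")))
  list(cohort = cohort, design = design)
}

test_that("the cross-cohort and kindred rules follow the truth table", {
  # keys: 1e6 private to K1 (kin has it) / 2e6 in K1 only (kin ref)
  # 3e6 in K1+U1 (unrelated share) / 4e6 private to U2
  fx <- kindredFixture(list(K1 = c(1e6, 2e6, 3e6), K2 = 1e6,
                            U1 = 3e6, U2 = 4e6))
  r <- kindredCrossCohortFilter(fx$cohort, fx$design)
  expect_equal(calls(r$callsets$K1)$pos, 1e6)     # shared with kin only
  expect_equal(calls(r$callsets$K2)$pos, 1e6)
  expect_equal(nCalls(r$callsets$U1), 0L)          # shared with unrelated
  expect_equal(calls(r$callsets$U2)$pos, 4e6)      # sporadic private
  e <- r$entries
  reasonOf <- function(s, pos)
    e$reason[e$sample_id == s & e$pos == pos]
  expect_equal(reasonOf("K1", 1e6), "kindred-shared")
  expect_equal(reasonOf("K1", 2e6), "kindred-unshared")
  expect_equal(reasonOf("K1", 3e6), "cross-cohort")
  expect_equal(reasonOf("U1", 3e6), "cross-cohort")
  expect_equal(reasonOf("U2", 4e6), "sporadic")
})

test_that("low kin coverage rescinds the kindred-unshared rejection", {
  fx <- kindredFixture(list(K1 = c(2e6, 8e6), K2 = 1e6, U1 = 5e5,
                            U2 = 7e5))
  # K2 is under-covered around 2e6 but well covered at 8e6
  lowcov <- list(K2 = data.frame(start = 1.5e6, end = 2.5e6))
  r <- kindredCrossCohortFilter(fx$cohort, fx$design,
                                lowCoverage = lowcov)
  e <- r$entries
  expect_equal(e$reason[e$sample_id == "K1" & e$pos == 2e6],
               "kindred-lowcov-accommodation")
  expect_equal(e$decision[e$sample_id == "K1" & e$pos == 2e6], "retain")
  expect_equal(e$reason[e$sample_id == "K1" & e$pos == 8e6],
               "kindred-unshared")
  expect_equal(calls(r$callsets$K1)$pos, 2e6)
})

test_that("exhaustive truth table over presence, coverage and kinship", {
  # for a focal variant in K1 at 5e6: kin state in {present,
  # absent-lowcov, absent-highcov}, sharer in {none, unrelated}
  for (kinState in c("present", "absent-lowcov", "absent-highcov")) {
    for (sharer in c("none", "unrelated")) {
      callsOf <- list(K1 = 5e6,
                      K2 = if (kinState == "present") c(5e6, 9e6) else 9e6,
                      U1 = if (sharer == "unrelated") c(5e6, 1e6) else 1e6,
                      U2 = 2e6)
      fx <- kindredFixture(callsOf)
      lowcov <- if (kinState == "absent-lowcov")
        list(K2 = data.frame(start = 4e6, end = 6e6)) else NULL
      r <- kindredCrossCohortFilter(fx$cohort, fx$design,
                                    lowCoverage = lowcov)
      kept <- 5e6 %in% calls(r$callsets$K1)$pos
      expected <- sharer == "none" && kinState != "absent-highcov"
      expect_identical(kept, expected,
                       label = paste(kinState, sharer))
    }
  }
})

test_that("output is invariant to sample ordering", {
  fx <- kindredFixture(list(K1 = c(1e6, 3e6), K2 = 1e6,
                            U1 = 3e6, U2 = 4e6))
  r1 <- kindredCrossCohortFilter(fx$cohort, fx$design)
  r2 <- kindredCrossCohortFilter(rev(fx$cohort), fx$design)
  for (s in names(fx$cohort))
    expect_equal(calls(r1$callsets[[s]]), calls(r2$callsets[[s]]))
})

test_that("the filter never increases a sample's variant count", {
  sim <- smallSim(12)
  r <- kindredCrossCohortFilter(sim$cohort, sim$design)
  for (s in names(sim$cohort))
    expect_lte(nCalls(r$callsets[[s]]), nCalls(sim$cohort[[s]]))
  expect_error(kindredCrossCohortFilter(
    sim$cohort, CohortDesign(data.frame(sample_id = "zz"),
                             sporadic = "zz")), "missing from design")
})

test_that("clinical rescue restores pathogenic rare cross-cohort losses", {
  fx <- kindredFixture(list(K1 = c(1e6, 5e6), K2 = c(1e6, 5e6),
                            U1 = c(5e6, 2e6), U2 = c(5e6, 3e6)))
  r <- kindredCrossCohortFilter(fx$cohort, fx$design)
  ledger <- FilterLedger(r$entries)
  panelOf <- function(clin, maf) ReferencePanel(data.frame(
    chrom = "X", pos = 5e6, ref = "A", alt = "G", maf = maf,
    clin_sig = clin))
  # pathogenic nonsense at MAF 0.2%: rescued in all four carriers
  rs <- clinicalRescue(ledger, panelOf("pathogenic", 0.002))
  expect_equal(rs$rescuedKeys, "X:5000000:A:G")
  e <- ledgerEntries(rs$ledger)
  resc <- e[e$decision == "rescue", ]
  expect_setequal(resc$sample_id, c("K1", "K2", "U1", "U2"))
  expect_true(all(resc$reason == "clinical-rescue"))
  # no pathogenic annotation: stays rejected
  expect_length(clinicalRescue(ledger, panelOf("none", 0.002))$rescuedKeys,
                0L)
  # pathogenic but common (MAF 5%): stays rejected
  expect_length(clinicalRescue(ledger,
                               panelOf("pathogenic", 0.05))$rescuedKeys,
                0L)
})

test_that("batch-systematic keys are self-neutralized cohort-wide", {
  sim <- smallSim(13)
  pre <- lapply(sim$cohort, function(cs) preFilter(cs)$callset)
  names(pre) <- names(sim$cohort)
  r <- kindredCrossCohortFilter(pre, sim$design)
  be <- sim$truth$errors[sim$truth$errors$class == "batch", ]
  keys <- causalKey(be)
  for (i in seq_len(nrow(be)))
    expect_false(keys[i] %in% variantKeys(r$callsets[[be$sample_id[i]]]))
})
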