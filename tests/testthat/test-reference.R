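# Carrier-probability MAF cutoff model and the database subtraction
# filters.

test_that("carrier probability: boundary cases and the 12-copy bound", {
  expect_equal(carrierProbability(0), 1)
  expect_equal(carrierProbability(567 + 1), 0)   # pigeonhole: > F females
  p12 <- carrierProbability(12)
  expect_lte(p12, 0.01)
  expect_equal(p12, choose(567, 12) * 2^12 / choose(1659, 12),
               tolerance = 1e-12)
  # the unrestricted chromosome model is slightly larger at n = 12
  expect_gt(carrierProbability(12, model = "chromosome"), 0.01)
  expect_error(carrierProbability(-1), "must be")
})

test_that("carrier probability is strictly decreasing up to F", {
  p <- carrierProbability(0:567)
  expect_true(all(diff(p) < 0))
  p2 <- carrierProbability(0:600, model = "chromosome")
  expect_true(all(diff(p2) < 0))
})

test_that("the copy-count cutoff scan reproduces the 12-copy threshold", {
  expect_equal(minCountForCutoff(1), 0L)
  expect_equal(minCountForCutoff(0.01), 12L)
  # agreement with a brute-force scan on a probability grid
  for (pMax in c(0.25, 0.1, 0.05, 0.01, 0.001, 1e-6)) {
    scan <- which(carrierProbability(0:567) <= pMax)[1] - 1L
    expect_equal(minCountForCutoff(pMax), scan)
  }
  expect_warning(out <- minCountForCutoff(1e-300), "sentinel")
  expect_equal(out, 568L)
})

test_that("non-clinical panel drops pathogenic then rare records", {
  panel <- ReferencePanel(data.frame(
    chrom = "X", pos = c(1e6, 2e6, 3e6, 4e6), ref = "A", alt = "G",
    maf = c(0.3, 0.001, 0.007, 0.3),
    allele_count = c(500L, 3L, 12L, 100L),
    clin_sig = c("pathogenic", "none", "none", "none")))
  nc <- buildNonclinicalDbsnp(panel)
  expect_equal(panelRecords(nc)$pos, c(3e6, 4e6))
  # pathogenic records never survive, whatever their count
  expect_false(any(panelRecords(nc)$clin_sig %in%
                     c("pathogenic", "probable-pathogenic")))
  # counts derived from maf when allele_count is missing
  panel2 <- ReferencePanel(data.frame(
    chrom = "X", pos = c(1e6, 2e6), ref = "A", alt = "G",
    maf = c(0.001, 0.3)))
  expect_equal(panelRecords(buildNonclinicalDbsnp(panel2))$pos, 2e6)
})

test_that("male-only subset keeps records with male carriers", {
  panel <- ReferencePanel(data.frame(
    chrom = "X", pos = c(1e6, 2e6), ref = "A", alt = "G",
    maf = c(0.1, 0.05), allele_count = c(31L, 4L),
    male_carrier_count = c(1L, 0L), female_only = c(FALSE, TRUE)))
  expect_equal(panelRecords(maleOnlySubset(panel))$pos, 1e6)
  expect_equal(nrow(panelRecords(maleOnlySubset(
    ReferencePanel(data.frame())))), 0L)
  # a release failing the ploidy audit is refused
  badAudit <- auditGenotypePloidy(c(1, 1, 2, 3, 0.05, 3.95, 1, 2, 1, 1))
  expect_error(maleOnlySubset(panel, genotypeAudit = badAudit),
               "refusing")
  expect_silent(maleOnlySubset(panel, genotypeAudit = badAudit,
                               maxAmbiguous = 0.5))
})

test_that("EVS subset keeps hemizygous-annotated non-PAR records", {
  panel <- ReferencePanel(data.frame(
    chrom = "X", pos = c(1e6, 2e6, 9e6), ref = "A", alt = "G",
    maf = 0.1, hemizygous_annotated = c(TRUE, FALSE, TRUE)))
  out <- panelRecords(evsMaleSubset(panel))
  expect_equal(out$pos, 9e6)  # 1e6 is inside PAR1, 2e6 not annotated
  out2 <- panelRecords(evsMaleSubset(panel, parMask = NULL))
  expect_equal(out2$pos, c(1e6, 9e6))
})

test_that("panel subtraction rejects matches except rescued keys", {
  cs <- makeCallSet("A", c(1e7, 2e7, 3e7))
  panel <- ReferencePanel(data.frame(
    chrom = "X", pos = c(1e7, 2e7), ref = "A", alt = "G", maf = 0.1))
  r <- subtractPanel(cs, panel, "dbsnp")
  expect_equal(calls(r$callset)$pos, 3e7)
  expect_equal(sum(r$entries$decision == "reject"), 2L)
  r2 <- subtractPanel(cs, panel, "dbsnp", rescued = "X:10000000:A:G")
  expect_equal(calls(r2$callset)$pos, c(1e7, 3e7))
  # empty panel is the identity
  r3 <- subtractPanel(cs, ReferencePanel(data.frame()), "dbsnp")
  expect_equal(calls(r3$callset), calls(cs))
})

test_that("a planted pathogenic variant cannot be subtracted by the
           non-clinical panel", {
  sim <- smallSim(14)
  nc <- buildNonclinicalDbsnp(sim$panels$dbsnp)
  ca <- sim$truth$causal
  expect_false(any(causalKey(ca) %in% panelKeys(nc)))
})
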