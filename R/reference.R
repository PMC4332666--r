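# Database-derived subtraction filters and the minor-allele-frequency
# cutoff derived from the female-carrier probability model.

#' Probability that all variant copies sit in female carriers
#'
#' For a variant observed in \code{nCopies} of the M + 2F X chromosomes of
#' a sex-mixed reference panel (M male chromosomes, F female individuals
#' contributing two each), returns the probability that every copy lands
#' on a female chromosome with no female receiving two copies — i.e. all
#' carriers are heterozygous females, the configuration under which a
#' recessive pathogenic variant could hide from the male subset. Under the
#' default carrier model this is choose(F, n) * 2^n / choose(M + 2F, n),
#' and 0 once n exceeds F. The alternative "chromosome" model drops the
#' heterozygous-carrier restriction and allows female homozygotes:
#' choose(2F, n) / choose(M + 2F, n).
#'
#' @param nCopies observed copies of the variant allele (>= 0).
#' @param nMaleChr male X chromosomes in the panel (default 525).
#' @param nFemaleInd female individuals in the panel (default 567).
#' @param model "carrier" (default) or "chromosome".
#' @return probability in [0, 1]; strictly decreasing in nCopies.
#' @export
carrierProbability <- function(nCopies, nMaleChr = 525L,
                               nFemaleInd = 567L,
                               model = c("carrier", "chromosome")) {
  model <- match.arg(model)
  if (any(nCopies < 0) || nMaleChr <= 0 || nFemaleInd <= 0)
    stop("nCopies must be >= 0 and population counts positive")
  M <- nMaleChr; F <- nFemaleInd
  total <- M + 2 * F
  vapply(nCopies, function(n) {
    if (n == 0) return(1)
    if (model == "carrier") {
      if (n > F) return(0)
      exp(lchoose(F, n) + n * log(2) - lchoose(total, n))
    } else {
      if (n > 2 * F) return(0)
      exp(lchoose(2 * F, n) - lchoose(total, n))
    }
  }, numeric(1))
}

#' Smallest allele count meeting the carrier-probability bound
#'
#' Returns the smallest copy number n such that
#' \code{carrierProbability(n, ...)} is at most \code{pMax}. With the
#' default panel composition (525 male chromosomes, 567 females) and
#' pMax = 0.01 this is 12 copies — MAF 12/1659, about 0.72% — the cutoff
#' below which an unannotated variant could plausibly be hiding in female
#' carriers only and must not be used for subtraction.
#'
#' @inheritParams carrierProbability
#' @param pMax probability ceiling in (0, 1).
#' @return integer copy count; if even n = F (the maximum attainable
#'   carrier configuration) exceeds pMax, returns F + 1 with a warning.
#' @export
minCountForCutoff <- function(pMax = 0.01, nMaleChr = 525L,
                              nFemaleInd = 567L,
                              model = c("carrier", "chromosome")) {
  model <- match.arg(model)
  stopifnot(pMax > 0, pMax < 1 || pMax == 1)
  if (pMax >= 1) return(0L)
  nMax <- if (model == "carrier") nFemaleInd else 2L * nFemaleInd
  for (n in 0:nMax) {
    if (carrierProbability(n, nMaleChr, nFemaleInd, model) <= pMax)
      return(n)
  }
  warning("pMax not attainable below n = ", nMax, "; returning sentinel")
  nMax + 1L
}

#' Build a "non-clinical" dbSNP-like panel
#'
#' Removes (a) all records annotated probable-pathogenic or pathogenic,
#' then (b) all records observed in fewer than \code{minAlleleCount}
#' copies. The count threshold (default 12, from
#' \code{\link{minCountForCutoff}}) keeps rare variants out of the
#' subtraction panel because they could be unannotated pathogenic alleles
#' hiding in female carriers. When a record lacks allele_count, it is
#' derived from maf times the panel's chromosome total.
#'
#' @param panel a \code{ReferencePanel}.
#' @param minAlleleCount minimum copies for a record to stay (default 12).
#' @return a filtered \code{ReferencePanel}.
#' @export
buildNonclinicalDbsnp <- function(panel, minAlleleCount = 12L) {
  rec <- panelRecords(panel)
  rec <- rec[!(rec$clin_sig %in% c("probable-pathogenic", "pathogenic")), ,
             drop = FALSE]
  ac <- rec$allele_count
  if (any(is.na(ac))) {
    tot <- panel@nMaleChr + 2L * panel@nFemaleInd
    ac[is.na(ac)] <- round(rec$maf[is.na(ac)] * tot)
  }
  rec <- rec[ac >= minAlleleCount, , drop = FALSE]
  ReferencePanel(rec, source = paste0(panel@source, ".nonclinical"),
                 nMaleChr = panel@nMaleChr, nFemaleInd = panel@nFemaleInd)
}

#' Male-only subset of a population panel
#'
#' Retains records observed in at least one male carrier (equivalently,
#' drops records seen only in females). If a genotype-ploidy audit of the
#' panel's male calls is supplied and its ambiguous fraction exceeds
#' \code{maxAmbiguous}, the subset is refused: a release whose male
#' X-chromosome genotypes are substantially ambiguous cannot be trusted
#' as a subtraction filter and should be re-called from alignments.
#'
#' @param panel a \code{ReferencePanel} with male_carrier_count or
#'   female_only populated.
#' @param genotypeAudit optional result of
#'   \code{\link{auditGenotypePloidy}} on the panel's male genotypes.
#' @param maxAmbiguous tolerated ambiguous fraction (default 0).
#' @return a filtered \code{ReferencePanel}.
#' @export
maleOnlySubset <- function(panel, genotypeAudit = NULL, maxAmbiguous = 0) {
  if (!is.null(genotypeAudit) &&
      genotypeAudit$fracAmbiguous > maxAmbiguous)
    stop(sprintf(paste0("refusing to build male-only panel: %.1f%% of ",
                        "non-zero male genotypes are ambiguous ",
                        "(tolerance %.1f%%)"),
                 100 * genotypeAudit$fracAmbiguous, 100 * maxAmbiguous))
  rec <- panelRecords(panel)
  if (nrow(rec) == 0L) return(panel)
  hasMale <- if (!all(is.na(rec$male_carrier_count)))
    !is.na(rec$male_carrier_count) & rec$male_carrier_count >= 1L
  else if (!all(is.na(rec$female_only))) !rec$female_only
  else stop("panel lacks a sex partition (male_carrier_count or female_only)")
  ReferencePanel(rec[hasMale, , drop = FALSE],
                 source = paste0(panel@source, ".male"),
                 nMaleChr = panel@nMaleChr, nFemaleInd = panel@nFemaleInd)
}

#' Hemizygous-male subset of an EVS-like panel
#'
#' Retains records annotated as observed in hemizygous males and removes
#' records inside the pseudoautosomal mask.
#'
#' @param panel a \code{ReferencePanel} with hemizygous_annotated.
#' @param parMask data.frame of half-open intervals (default
#'   \code{parMaskHg19}); NULL disables masking.
#' @return a filtered \code{ReferencePanel}.
#' @export
evsMaleSubset <- function(panel, parMask = parMaskHg19) {
  rec <- panelRecords(panel)
  keep <- !is.na(rec$hemizygous_annotated) & rec$hemizygous_annotated
  if (!is.null(parMask))
    keep <- keep & !.inIntervals(rec$pos, parMask)
  ReferencePanel(rec[keep, , drop = FALSE],
                 source = paste0(panel@source, ".hemizygous"),
                 nMaleChr = panel@nMaleChr, nFemaleInd = panel@nFemaleInd)
}

#' Subtract a reference panel from a call set
#'
#' Rejects every call whose (chrom, pos, ref, alt) key appears in the
#' panel, except keys in the rescued set, which pass through all
#' database-subtraction stages untouched.
#'
#' @param callset a \code{SampleCallSet}.
#' @param panel a \code{ReferencePanel}.
#' @param stageName ledger stage label (also the rejection reason).
#' @param rescued character vector of variant keys immune to subtraction.
#' @return list with \code{callset} and \code{entries}.
#' @export
subtractPanel <- function(callset, panel, stageName,
                          rescued = character()) {
  cl <- calls(callset)
  k <- variantKey(cl)
  hit <- (k %in% panelKeys(panel)) & !(k %in% rescued)
  entries <- rbind(
    .ledgerRows(sampleID(callset), cl[!hit, , drop = FALSE],
                stageName, "retain", paste0(stageName, "-absent")),
    .ledgerRows(sampleID(callset), cl[hit, , drop = FALSE],
                stageName, "reject", stageName))
  list(callset = .withCalls(callset, cl[!hit, , drop = FALSE]),
       entries = entries)
}
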