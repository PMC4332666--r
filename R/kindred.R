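# The affected-kindred/cross-cohort filter: retain variants shared within
# declared kindred pairs, remove variants shared across unrelated samples,
# accommodate coverage-driven discordance within pairs, and rescue known
# pathogenic rare variants lost to cross-cohort removal.

# internal: is position p (1-based) inside any half-open interval?
.inIntervals <- function(pos, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L)
    return(rep(FALSE, length(pos)))
  ok <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(intervals)))
    ok <- ok | (pos - 1 >= intervals$start[i] & pos - 1 < intervals$end[i])
  ok
}

#' Affected-kindred/cross-cohort filter
#'
#' Applies the two relatedness rules in order. Cross-cohort rule: a
#' variant key carried by two or more samples that are not declared kin is
#' rejected in every carrier (including kindred pairs that share the key
#' with an unrelated sample) — causal mutations of a rare X-linked
#' disorder are expected to be private to families, while keys recurring
#' across unrelated samples are common polymorphisms or systematic
#' batch errors. Kindred concordance rule: for a paired sample, a
#' surviving variant absent in its kin is rejected unless the kin lacks
#' adequate coverage at the site, in which case the absence is
#' uninformative and the variant is retained. Sporadic samples keep every
#' variant that survives the cross-cohort rule.
#'
#' Coverage at non-variant sites is served by optional per-sample
#' low-coverage tracks (half-open intervals where depth < minDepth);
#' absent a track, absence of a call is treated as a confident
#' reference call.
#'
#' @param cohort named list of \code{SampleCallSet}s.
#' @param design a \code{CohortDesign} covering every cohort sample.
#' @param minDepth depth below which a kin's reference call is considered
#'   uninformative (default 4). Retained for metadata; the decision uses
#'   the low-coverage tracks.
#' @param lowCoverage optional named list (by sample id) of data.frames
#'   with start, end: intervals where that sample's depth < minDepth.
#' @param carrierCohort optional named list of \code{SampleCallSet}s used
#'   as the carrier evidence for the cross-cohort rule and the kin
#'   presence lookup (default: \code{cohort} itself). In a combined run
#'   this is the post-prefilter cohort, so that a variant's presence in
#'   an unrelated sample still counts against it even when that copy was
#'   already removed by the shared-segment filter.
#' @return list with \code{callsets} (named list of retained
#'   \code{SampleCallSet}s) and \code{entries} (ledger rows; stage
#'   "kindred-crosscohort", reasons "cross-cohort", "kindred-unshared",
#'   "kindred-lowcov-accommodation", "kindred-shared", "private",
#'   "sporadic").
#' @export
kindredCrossCohortFilter <- function(cohort, design, minDepth = 4L,
                                     lowCoverage = NULL,
                                     carrierCohort = NULL) {
  ids <- vapply(cohort, sampleID, character(1))
  names(cohort) <- ids
  roster <- designSamples(design)$sample_id
  if (!all(ids %in% roster))
    stop("cohort sample(s) missing from design: ",
         paste(setdiff(ids, roster), collapse = ", "))
  kin <- kinOf(design)

  keysBySample <- lapply(cohort, variantKeys)
  if (is.null(carrierCohort)) {
    carrierKeys <- keysBySample
  } else {
    cids <- vapply(carrierCohort, sampleID, character(1))
    names(carrierCohort) <- cids
    carrierKeys <- lapply(carrierCohort, variantKeys)
  }
  carrierTab <- data.frame(
    sample = rep(names(carrierKeys), lengths(carrierKeys)),
    key = unlist(carrierKeys, use.names = FALSE),
    stringsAsFactors = FALSE)

  # cross-cohort rule: key carried by >= 2 samples that are not declared
  # kin of one another. Carriers that are exactly one sample or exactly
  # one declared pair are exempt.
  carriersOf <- split(carrierTab$sample, carrierTab$key)
  crossKeys <- names(carriersOf)[vapply(carriersOf, function(cs) {
    cs <- unique(cs)
    if (length(cs) < 2L) return(FALSE)
    if (length(cs) == 2L) {
      k <- kin[cs[1]]
      return(!(!is.na(k) && identical(unname(k), cs[2])))
    }
    TRUE
  }, logical(1))]

  entries <- list()
  out <- list()
  for (s in ids) {
    cl <- calls(cohort[[s]])
    k <- keysBySample[[s]]
    isCross <- k %in% crossKeys
    entries[[length(entries) + 1L]] <-
      .ledgerRows(s, cl[isCross, , drop = FALSE],
                  "kindred-crosscohort", "reject", "cross-cohort")
    cl2 <- cl[!isCross, , drop = FALSE]
    k2 <- k[!isCross]
    mate <- if (s %in% names(kin)) kin[[s]] else NA_character_
    if (is.na(mate)) {
      entries[[length(entries) + 1L]] <-
        .ledgerRows(s, cl2, "kindred-crosscohort", "retain", "sporadic")
      out[[s]] <- .withCalls(cohort[[s]], cl2)
    } else {
      inMate <- k2 %in% carrierKeys[[mate]]
      lowcov <- .inIntervals(cl2$pos, lowCoverage[[mate]])
      keep <- inMate | lowcov
      reason <- ifelse(inMate, "kindred-shared",
                       ifelse(lowcov, "kindred-lowcov-accommodation",
                              "kindred-unshared"))
      entries[[length(entries) + 1L]] <-
        .ledgerRows(s, cl2, "kindred-crosscohort",
                    ifelse(keep, "retain", "reject"), reason)
      out[[s]] <- .withCalls(cohort[[s]], cl2[keep, , drop = FALSE])
    }
  }
  list(callsets = out, entries = do.call(rbind, entries))
}

#' Clinical rescue of cross-cohort rejections
#'
#' Re-marks as "rescue" every variant that was rejected under the
#' cross-cohort rule but is annotated probable-pathogenic or pathogenic in
#' the clinical panel with population MAF below \code{mafMax}. Recurrence
#' of a known rare pathogenic mutation across unrelated affected families
#' is plausible for a disease gene, so such losses are reversed; rescued
#' keys are also immune to the downstream database-subtraction filters.
#'
#' @param ledger a \code{FilterLedger} containing cross-cohort rejections.
#' @param clinicalPanel a \code{ReferencePanel} with clin_sig and maf.
#' @param mafMax MAF ceiling for rescue (default 0.01).
#' @return list with \code{ledger} (amended \code{FilterLedger}) and
#'   \code{rescuedKeys} (character vector of rescued variant keys).
#' @export
clinicalRescue <- function(ledger, clinicalPanel, mafMax = 0.01) {
  e <- ledgerEntries(ledger)
  rec <- panelRecords(clinicalPanel)
  pathKeys <- variantKey(
    rec[rec$clin_sig %in% c("probable-pathogenic", "pathogenic") &
        !is.na(rec$maf) & rec$maf < mafMax, , drop = FALSE])
  key <- paste(e$chrom, e$pos, e$ref, e$alt, sep = ":")
  hit <- e$stage == "kindred-crosscohort" & e$decision == "reject" &
    e$reason == "cross-cohort" & key %in% pathKeys
  e$decision[hit] <- "rescue"
  e$reason[hit] <- "clinical-rescue"
  list(ledger = FilterLedger(e), rescuedKeys = unique(key[hit]))
}
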