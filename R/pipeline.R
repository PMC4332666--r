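# End-to-end combined filter: universal pre-filters, shared-segment and
# kindred/cross-cohort filters, clinical rescue, sequential
# database-subtraction filters, then gene scoring and enrichment.

.STAGES <- c("shared-segment", "kindred-crosscohort",
             "dbsnp", "male-panel", "evs")

#' Parameters of the combined filter
#'
#' @param proximityBp proximity pre-filter distance (default 10).
#' @param windowBp,stepBp,maxDiscordant shared-segment detection
#'   parameters (defaults 5 Mb window, 1 Mb step, 0 discordant points).
#' @param minDepth kin coverage threshold for the accommodation rule.
#' @param rescueMaf MAF ceiling for clinical rescue (default 0.01).
#' @param minAlleleCount allele-count floor for the non-clinical dbSNP
#'   panel (default 12, from \code{\link{minCountForCutoff}}).
#' @param chromLength chromosome length in bp.
#' @param weights gene-score weights (\code{\link{defaultScoreWeights}}).
#' @param lowCoverage optional named list of low-coverage interval tables.
#' @return list of parameters.
#' @export
combinedParams <- function(proximityBp = 10L, windowBp = 5e6,
                           stepBp = 1e6, maxDiscordant = 0L,
                           minDepth = 4L, rescueMaf = 0.01,
                           minAlleleCount = 12L,
                           chromLength = 155270560,
                           weights = defaultScoreWeights(),
                           lowCoverage = NULL) {
  as.list(environment())
}

#' Run the combined filter end to end
#'
#' Stage order: (1) strand and proximity pre-filters on every sample;
#' (2) shared-segment filter for kindred pairs (sporadic samples bypass),
#' then the affected-kindred/cross-cohort filter cohort-wide; (3)
#' clinical rescue re-introduces cross-cohort rejections annotated
#' pathogenic with low MAF; (4) sequential panel subtractions —
#' non-clinical dbSNP, male-only population, hemizygous-male EVS —
#' skipping rescued keys; (5) gene scoring and known-gene enrichment.
#' Every decision is logged once per stage in the ledger.
#'
#' @param cohort named list of \code{SampleCallSet}s.
#' @param design a \code{CohortDesign}.
#' @param panels list with elements dbsnp, male1000g, evs, clinical
#'   (\code{ReferencePanel}s); missing elements skip their stage.
#' @param geneMap optional gene map for scoring (see
#'   \code{\link{scoreGenes}}).
#' @param knownGenes optional character vector of known disease genes.
#' @param nGenesTotal size of the full target gene set for enrichment.
#' @param params list from \code{\link{combinedParams}}.
#' @return list with callsets (final retained \code{SampleCallSet}s),
#'   ledger (\code{FilterLedger}), rescuedKeys, segments (per pair),
#'   baseline (post-prefilter callsets), report
#'   (\code{\link{reportReduction}}), geneScores, enrichment.
#' @export
runCombined <- function(cohort, design, panels = list(), geneMap = NULL,
                        knownGenes = NULL, nGenesTotal = NULL,
                        params = combinedParams()) {
  ids <- vapply(cohort, sampleID, character(1))
  names(cohort) <- ids
  if (!all(ids %in% designSamples(design)$sample_id))
    stop("cohort sample(s) missing from design: ",
         paste(setdiff(ids, designSamples(design)$sample_id),
               collapse = ", "))
  entries <- list()

  # (1) universal pre-filters
  current <- list()
  for (s in ids) {
    pf <- preFilter(cohort[[s]], windowBp = params$proximityBp)
    current[[s]] <- pf$callset
    entries[[length(entries) + 1L]] <- pf$entries
  }
  baseline <- current

  # (2a) shared-segment filter per declared pair
  segments <- list()
  p <- designPairs(design)
  for (i in seq_len(nrow(p))) {
    s1 <- p$sample1[i]; s2 <- p$sample2[i]
    track <- discordanceTrack(current[[s1]], current[[s2]])
    segs <- detectSharedSegments(track, windowBp = params$windowBp,
                                 stepBp = params$stepBp,
                                 maxDiscordant = params$maxDiscordant,
                                 chromLength = params$chromLength)
    segments[[paste(s1, s2, sep = "-")]] <- segs
    sf <- sharedSegmentFilter(current[[s1]], current[[s2]], segs)
    current[[s1]] <- sf$callsets[[1]]
    current[[s2]] <- sf$callsets[[2]]
    entries[[length(entries) + 1L]] <- sf$entries
  }
  for (s in designSporadic(design)) {
    if (!(s %in% ids)) next
    entries[[length(entries) + 1L]] <-
      .ledgerRows(s, calls(current[[s]]), "shared-segment", "retain",
                  "sporadic-bypass")
  }

  # (2b) kindred/cross-cohort filter
  kf <- kindredCrossCohortFilter(current, design,
                                 minDepth = params$minDepth,
                                 lowCoverage = params$lowCoverage,
                                 carrierCohort = baseline)
  current <- kf$callsets
  entries[[length(entries) + 1L]] <- kf$entries
  ledgerDf <- do.call(rbind, entries)

  # (3) clinical rescue of cross-cohort rejections
  rescuedKeys <- character(0)
  if (!is.null(panels$clinical)) {
    rs <- clinicalRescue(FilterLedger(ledgerDf), panels$clinical,
                         mafMax = params$rescueMaf)
    ledgerDf <- ledgerEntries(rs$ledger)
    rescuedKeys <- rs$rescuedKeys
    if (length(rescuedKeys)) {
      e <- ledgerDf
      resc <- e[e$decision == "rescue", , drop = FALSE]
      for (s in unique(resc$sample_id)) {
        keys <- paste(resc$chrom, resc$pos, resc$ref, resc$alt,
                      sep = ":")[resc$sample_id == s]
        bl <- calls(baseline[[s]])
        back <- bl[variantKey(bl) %in% keys, , drop = FALSE]
        cl <- unique(rbind(calls(current[[s]]), back))
        current[[s]] <- SampleCallSet(s, cl,
                                      batch = sampleBatch(current[[s]]))
      }
    }
  }

  # (4) sequential database subtractions, rescued keys immune
  dbStages <- list(
    dbsnp = if (!is.null(panels$dbsnp))
      buildNonclinicalDbsnp(panels$dbsnp,
                            minAlleleCount = params$minAlleleCount),
    `male-panel` = if (!is.null(panels$male1000g))
      maleOnlySubset(panels$male1000g),
    evs = if (!is.null(panels$evs)) evsMaleSubset(panels$evs))
  dbEntries <- list()
  for (stage in names(dbStages)) {
    pan <- dbStages[[stage]]
    if (is.null(pan)) next
    for (s in ids) {
      sp <- subtractPanel(current[[s]], pan, stage,
                          rescued = rescuedKeys)
      current[[s]] <- sp$callset
      dbEntries[[length(dbEntries) + 1L]] <- sp$entries
    }
  }
  ledger <- FilterLedger(rbind(ledgerDf, do.call(rbind, dbEntries)))

  # (5) gene scoring and enrichment
  geneScores <- NULL
  enrichment <- NULL
  if (!is.null(geneMap)) {
    geneScores <- scoreGenes(current, design, geneMap,
                             weights = params$weights)
    if (!is.null(knownGenes) && !is.null(nGenesTotal) &&
        nrow(geneScores) > 0L) {
      enrichment <- hypergeometricEnrichment(
        k = sum(geneScores$gene_id %in% knownGenes),
        n = nrow(geneScores), K = length(knownGenes), N = nGenesTotal)
    }
  }

  list(callsets = current, ledger = ledger, rescuedKeys = rescuedKeys,
       segments = segments, baseline = baseline,
       report = reportReduction(ledger, baseline),
       geneScores = geneScores, enrichment = enrichment)
}

#' Stage-by-stage reduction report
#'
#' Reconstructs, from the ledger, the variants each sample retains after
#' every stage and summarizes them in the conventional layout: mean and
#' standard deviation of variants per sample, split into
#' non-synonymous-or-splicing versus other calls, with percentages
#' relative to the post-prefilter baseline. Rescued variants re-enter at
#' the kindred/cross-cohort stage.
#'
#' @param ledger a \code{FilterLedger} from \code{\link{runCombined}}.
#' @param baseline named list of post-prefilter \code{SampleCallSet}s.
#' @return data.frame with stage, mean_total, sd_total, mean_nonsyn_splice,
#'   mean_other, pct_of_baseline.
#' @export
reportReduction <- function(ledger, baseline) {
  e <- ledgerEntries(ledger)
  ids <- names(baseline)
  nsspl <- c("nonsense", "frameshift", "splicing", "missense")
  classOf <- lapply(baseline, function(cs)
    stats::setNames(calls(cs)$funcClass %in% nsspl, variantKeys(cs)))
  stages <- intersect(.STAGES, unique(e$stage))
  perStage <- function(keysBySample) {
    tot <- vapply(keysBySample, length, integer(1))
    ns <- vapply(ids, function(s)
      sum(classOf[[s]][keysBySample[[s]]]), numeric(1))
    c(mean_total = mean(tot), sd_total = stats::sd(tot),
      mean_nonsyn_splice = mean(ns), mean_other = mean(tot - ns))
  }
  keys <- lapply(baseline, variantKeys)
  names(keys) <- ids
  rows <- list(data.frame(stage = "prefilter",
                          t(perStage(keys)), pct_of_baseline = 100))
  basMean <- mean(vapply(keys, length, integer(1)))
  eKey <- paste(e$chrom, e$pos, e$ref, e$alt, sep = ":")
  kept <- e$decision %in% c("retain", "rescue")
  for (st in stages) {
    sel <- e$stage == st & kept
    upd <- split(eKey[sel], factor(e$sample_id[sel], levels = ids))
    touched <- unique(e$sample_id[e$stage == st])
    # a sample with no rows at a stage had an empty call set already
    for (s in touched) keys[[s]] <- upd[[s]]
    row <- data.frame(stage = st, t(perStage(keys)),
                      pct_of_baseline = NA_real_)
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  out$pct_of_baseline <- 100 * out$mean_total / basMean
  rownames(out) <- NULL
  out
}

#' Run one filter in isolation on top of the pre-filters
#'
#' Applies the strand/proximity pre-filters and then a single named
#' filter, returning the mean per-sample retained count and the
#' percentage reduction relative to the post-prefilter baseline. Used to
#' compare individual filters the way sequential pipelines are usually
#' benchmarked stage by stage.
#'
#' @param cohort named list of \code{SampleCallSet}s.
#' @param design a \code{CohortDesign}.
#' @param which one of "shared-segment", "kindred", "dbsnp",
#'   "male-panel", "evs". "kindred" is the cross-cohort plus kindred
#'   concordance rules without the shared-segment component.
#' @param panels list of \code{ReferencePanel}s as in
#'   \code{\link{runCombined}}.
#' @param params list from \code{\link{combinedParams}}.
#' @return list with mean_retained, mean_baseline, pct_reduction.
#' @export
runSingleFilter <- function(cohort, design,
                            which = c("shared-segment", "kindred",
                                      "dbsnp", "male-panel", "evs"),
                            panels = list(), params = combinedParams()) {
  which <- match.arg(which)
  ids <- vapply(cohort, sampleID, character(1))
  names(cohort) <- ids
  current <- list()
  for (s in ids)
    current[[s]] <- preFilter(cohort[[s]],
                              windowBp = params$proximityBp)$callset
  basMean <- mean(vapply(current, nCalls, integer(1)))
  out <- current
  if (which == "shared-segment") {
    p <- designPairs(design)
    for (i in seq_len(nrow(p))) {
      s1 <- p$sample1[i]; s2 <- p$sample2[i]
      track <- discordanceTrack(current[[s1]], current[[s2]])
      segs <- detectSharedSegments(track, windowBp = params$windowBp,
                                   stepBp = params$stepBp,
                                   maxDiscordant = params$maxDiscordant,
                                   chromLength = params$chromLength)
      sf <- sharedSegmentFilter(current[[s1]], current[[s2]], segs)
      out[[s1]] <- sf$callsets[[1]]
      out[[s2]] <- sf$callsets[[2]]
    }
  } else if (which == "kindred") {
    out <- kindredCrossCohortFilter(current, design,
                                    minDepth = params$minDepth,
                                    lowCoverage =
                                      params$lowCoverage)$callsets
  } else {
    pan <- switch(which,
      dbsnp = buildNonclinicalDbsnp(panels$dbsnp,
                                    minAlleleCount =
                                      params$minAlleleCount),
      `male-panel` = maleOnlySubset(panels$male1000g),
      evs = evsMaleSubset(panels$evs))
    for (s in ids)
      out[[s]] <- subtractPanel(current[[s]], pan, which)$callset
  }
  m <- mean(vapply(out, nCalls, integer(1)))
  list(mean_retained = m, mean_baseline = basMean,
       pct_reduction = 100 * (1 - m / basMean))
}
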