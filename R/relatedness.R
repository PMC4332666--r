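# Pairwise relatedness by shared-variant identity, validation of declared
# kindred pairs, and population-stratification metrics.

#' Identity fraction between two call sets
#'
#' Identity = 2 * |A intersect B| / (|A| + |B|), with the intersection
#' keyed on the full (chrom, pos, ref, alt) variant key. Equals 1 iff the
#' keyed sets are equal and 0 for disjoint sets.
#'
#' @param callsA,callsB \code{SampleCallSet}s.
#' @return fraction in [0, 1].
#' @export
identityFraction <- function(callsA, callsB) {
  a <- variantKeys(callsA)
  b <- variantKeys(callsB)
  if (length(a) + length(b) == 0L)
    stop("identity undefined: both call sets are empty")
  2 * sum(a %in% b) / (length(a) + length(b))
}

#' Pairwise identity matrix for a cohort
#'
#' @param cohort named list of \code{SampleCallSet}s (>= 2 samples).
#' @return symmetric matrix of identity fractions with unit diagonal,
#'   dimnames = sample ids.
#' @export
identityMatrix <- function(cohort) {
  stopifnot(length(cohort) >= 2L)
  ids <- vapply(cohort, sampleID, character(1))
  names(cohort) <- ids
  keys <- lapply(cohort, variantKeys)
  n <- length(ids)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    v <- 2 * sum(keys[[i]] %in% keys[[j]]) /
      (length(keys[[i]]) + length(keys[[j]]))
    m[i, j] <- m[j, i] <- v
  }
  m
}

#' Validate declared kindred pairs against the identity matrix
#'
#' For each sample, finds the cohort member sharing the highest identity
#' and flags it as an outlier of the sample's identity distribution using
#' the box-whisker convention (best identity > Q3 + whisker * IQR). A
#' paired sample whose best match is not its declared kin, or a declared
#' pair that is not mutually best-matching, indicates a design error.
#'
#' @param m identity matrix from \code{\link{identityMatrix}}.
#' @param design a \code{CohortDesign}; its samples must be in \code{m}.
#' @param whisker Tukey multiplier for the outlier rule (default 1.5).
#' @return data.frame with sample, best_match, best_identity, declared_kin
#'   (NA for sporadic), is_declared_kin, is_outlier.
#' @export
validatePairs <- function(m, design, whisker = 1.5) {
  ids <- designSamples(design)$sample_id
  stopifnot(all(ids %in% rownames(m)))
  kin <- kinOf(design)
  out <- lapply(ids, function(s) {
    v <- m[s, setdiff(rownames(m), s)]
    best <- names(v)[which.max(v)]
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
    thr <- q[2] + whisker * (q[2] - q[1])
    dk <- if (s %in% names(kin)) kin[[s]] else NA_character_
    data.frame(sample = s, best_match = best, best_identity = max(v),
               declared_kin = dk,
               is_declared_kin = identical(best, dk),
               is_outlier = max(v) > thr,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Population-stratification metrics
#'
#' Computes, per sample: the deviation of its residual sum of squares from
#' the cohort mean genotype (in cohort standard-deviation units), and the
#' mean population-specific allele frequency of its panel-matched variants
#' for two reference populations. The cohort genotype mean at a site is
#' the fraction of samples carrying the alternate allele (samples are
#' haploid males, so presence is the genotype).
#'
#' @param cohort named list of \code{SampleCallSet}s.
#' @param panel a \code{ReferencePanel} whose records carry population
#'   frequency columns \code{freq_popA} and \code{freq_popB}.
#' @return data.frame with sample, rss, rss_sd, ea_metric, aa_metric,
#'   n_panel_matched, flagged (TRUE when a sample had no panel overlap and
#'   its frequency metrics are undefined).
#' @export
stratificationMetrics <- function(cohort, panel) {
  rec <- panelRecords(panel)
  stopifnot(all(c("freq_popA", "freq_popB") %in% names(rec)))
  ids <- vapply(cohort, sampleID, character(1))
  keys <- lapply(cohort, variantKeys)
  allKeys <- unique(unlist(keys))
  carrier <- vapply(keys, function(k) allKeys %in% k,
                    logical(length(allKeys)))
  meanFreq <- rowMeans(carrier)
  rss <- colSums((carrier - meanFreq)^2)
  sdRss <- stats::sd(rss)
  rssSd <- if (is.na(sdRss) || sdRss == 0) rep(0, length(rss))
           else (rss - mean(rss)) / sdRss
  pk <- variantKey(rec)
  ea <- aa <- nm <- numeric(length(ids))
  for (i in seq_along(ids)) {
    j <- match(keys[[i]], pk)
    j <- j[!is.na(j)]
    nm[i] <- length(j)
    ea[i] <- if (length(j)) mean(rec$freq_popA[j]) else NA_real_
    aa[i] <- if (length(j)) mean(rec$freq_popB[j]) else NA_real_
  }
  data.frame(sample = ids, rss = rss, rss_sd = rssSd,
             ea_metric = ea, aa_metric = aa,
             n_panel_matched = nm, flagged = nm == 0L,
             stringsAsFactors = FALSE, row.names = NULL)
}
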