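# Gene scoring by mutation burden over the filtered cohort and
# hypergeometric enrichment of known disease genes.

#' Default gene-score weights
#'
#' Loss-of-function and splice-site changes weigh twice a missense change;
#' synonymous and intronic changes carry no weight; a variant retained in
#' both members of a kindred pair is multiplied by the pair bonus.
#'
#' @return named list of weights.
#' @export
defaultScoreWeights <- function() {
  list(nonsense = 2, frameshift = 2, splicing = 2, missense = 1,
       synonymous = 0, intronic = 0, other = 0, pairBonus = 2)
}

#' Score genes by mutation burden
#'
#' Each distinct qualifying variant contributes its functional-class
#' weight; a variant retained in both members of a declared pair
#' contributes once, multiplied by the pair bonus, while a variant seen in
#' several unrelated carriers contributes once per carrier. Genes with
#' zero score (only synonymous/intronic/unweighted variants) are excluded.
#' Ties are broken by presence of a loss-of-function variant, then number
#' of qualifying variants, then gene id.
#'
#' @param cohort named list of filtered \code{SampleCallSet}s.
#' @param design a \code{CohortDesign}.
#' @param geneMap data.frame with columns chrom, pos, ref, alt, gene_id
#'   (and optionally func_class overriding the call's class).
#' @param weights named list as \code{\link{defaultScoreWeights}}.
#' @return data.frame of ranked gene scores: gene_id, score,
#'   n_qualifying, has_lof, kindred_supported.
#' @export
scoreGenes <- function(cohort, design, geneMap,
                       weights = defaultScoreWeights()) {
  ids <- vapply(cohort, sampleID, character(1))
  names(cohort) <- ids
  kin <- kinOf(design)
  mapKey <- variantKey(geneMap)
  rows <- list()
  for (s in ids) {
    cl <- calls(cohort[[s]])
    if (nrow(cl) == 0L) next
    k <- variantKey(cl)
    gi <- match(k, mapKey)
    unmapped <- is.na(gi)
    if (any(unmapped))
      message(sum(unmapped), " variant(s) in ", s,
              " have no gene mapping; not counted")
    if (all(unmapped)) next
    fc <- if (!is.null(geneMap$func_class))
      geneMap$func_class[gi[!unmapped]] else cl$funcClass[!unmapped]
    rows[[s]] <- data.frame(
      sample = s, key = k[!unmapped],
      gene_id = geneMap$gene_id[gi[!unmapped]],
      func = fc, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(gene_id = character(), score = numeric(),
                      n_qualifying = integer(), has_lof = logical(),
                      kindred_supported = logical()))
  tab <- do.call(rbind, rows)
  w <- unlist(weights[.FUNC_CLASSES])
  tab$w <- w[tab$func]
  tab$w[is.na(tab$w)] <- 0
  # collapse pair-shared occurrences: one contribution times the bonus
  tab$family <- ifelse(tab$sample %in% names(kin),
                       paste(pmin(tab$sample, kin[tab$sample]),
                             pmax(tab$sample, kin[tab$sample])),
                       tab$sample)
  grp <- paste(tab$family, tab$key)
  agg <- do.call(rbind, lapply(split(tab, grp), function(d) {
    shared <- length(unique(d$sample)) == 2L
    data.frame(gene_id = d$gene_id[1], func = d$func[1],
               contrib = d$w[1] * if (shared) weights$pairBonus else 1,
               qualifying = d$w[1] > 0, shared = shared & d$w[1] > 0,
               stringsAsFactors = FALSE)
  }))
  lofClasses <- c("nonsense", "frameshift", "splicing")
  res <- do.call(rbind, lapply(split(agg, agg$gene_id), function(d)
    data.frame(gene_id = d$gene_id[1],
               score = sum(d$contrib),
               n_qualifying = sum(d$qualifying),
               has_lof = any(d$qualifying & d$func %in% lofClasses),
               kindred_supported = any(d$shared),
               stringsAsFactors = FALSE)))
  res <- res[res$score > 0, , drop = FALSE]
  res <- res[order(-res$score, -res$has_lof, -res$n_qualifying,
                   res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Hypergeometric enrichment of known genes in a prioritized list
#'
#' Upper-tail probability of drawing at least k known genes when n genes
#' are drawn without replacement from a target set of N genes containing
#' K known genes: sum(dhyper(k:n, K, N-K, n)), equivalently
#' 1 - phyper(k-1, K, N-K, n). Fold enrichment is the observed fraction
#' k/n over the expected fraction K/N.
#'
#' @param k observed known genes in the list.
#' @param n prioritized list size.
#' @param K known genes in the target set.
#' @param N target-set size.
#' @return list with k, n, K, N, p_value, fold, observed_fraction,
#'   expected_fraction.
#' @export
hypergeometricEnrichment <- function(k, n, K, N) {
  if (k < 0 || k > n || n > N || K > N || K < 0)
    stop("need 0 <= k <= n <= N and 0 <= K <= N")
  p <- 1 - stats::phyper(k - 1, K, N - K, n)
  list(k = k, n = n, K = K, N = N,
       p_value = p,
       fold = (k / n) / (K / N),
       observed_fraction = k / n,
       expected_fraction = K / N)
}

#' Mutation-rate-weighted baseline probability
#'
#' Probability of selecting a known gene from the target set when genes
#' are weighted by their mutation counts in a control cohort: the sum of
#' counts over known genes divided by the total. With uniform counts this
#' reduces to K/N.
#'
#' @param geneMutationCounts named numeric vector of per-gene mutation
#'   counts from a control cohort.
#' @param knownGenes character vector of known gene ids.
#' @return probability in [0, 1].
#' @export
weightedBaseline <- function(geneMutationCounts, knownGenes) {
  if (any(geneMutationCounts < 0))
    stop("mutation counts must be non-negative")
  tot <- sum(geneMutationCounts)
  if (tot == 0) stop("total mutation count is zero")
  sum(geneMutationCounts[names(geneMutationCounts) %in% knownGenes]) / tot
}
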