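# Universal pre-filters applied before any other filtering: strand
# representation and inter-variant proximity. Both target signatures of
# false-positive calls — alternate reads confined to one sequencing strand,
# and calls aggregating in close proximity.

#' Strand-representation pre-filter
#'
#' Retains a call only if at least one alternate-allele read was observed
#' on each strand (altFwd >= 1 and altRev >= 1). An excess of alternate
#' calls from a single strand characterizes false positives.
#'
#' @param callset a \code{SampleCallSet} with altFwd/altRev populated.
#' @param permissive if TRUE, calls with missing strand counts pass
#'   through; if FALSE (default) they are a configuration error.
#' @return list with \code{callset} (retained calls) and \code{entries}
#'   (ledger rows, one per input call; rejects carry reason "strand").
#' @export
strandFilter <- function(callset, permissive = FALSE) {
  cl <- calls(callset)
  missing <- is.na(cl$altFwd) | is.na(cl$altRev)
  if (any(missing) && !permissive)
    stop("strand counts missing for ", sum(missing), " call(s) in sample '",
         sampleID(callset), "'; supply ADF/ADR or set permissive = TRUE")
  keep <- missing | (cl$altFwd >= 1L & cl$altRev >= 1L)
  entries <- rbind(
    .ledgerRows(sampleID(callset), cl[keep, , drop = FALSE],
                "prefilter-strand", "retain", "strand-ok"),
    .ledgerRows(sampleID(callset), cl[!keep, , drop = FALSE],
                "prefilter-strand", "reject", "strand"))
  list(callset = .withCalls(callset, cl[keep, , drop = FALSE]),
       entries = entries)
}

#' Inter-variant proximity pre-filter
#'
#' Rejects every call that lies within \code{windowBp} nucleotides
#' (inclusive) of another call of the same sample. Distances are computed
#' once on the original call set — removal is not re-applied iteratively —
#' so both members of a close pair are rejected and the result is
#' order-independent.
#'
#' @param callset a \code{SampleCallSet}.
#' @param windowBp rejection distance in bp (default 10).
#' @return list with \code{callset} and \code{entries} as in
#'   \code{\link{strandFilter}}; rejects carry reason "proximity".
#' @export
proximityFilter <- function(callset, windowBp = 10L) {
  cl <- calls(callset)
  n <- nrow(cl)
  if (n == 0L)
    return(list(callset = callset,
                entries = .ledgerRows(sampleID(callset), cl,
                                      "prefilter-proximity", "retain",
                                      "proximity-ok")))
  pos <- cl$pos  # sorted by class invariant
  tooClose <- rep(FALSE, n)
  if (n > 1L) {
    gap <- diff(pos)
    close <- gap <= windowBp
    tooClose[c(close, FALSE)] <- tooClose[c(close, FALSE)] | TRUE
    tooClose[c(FALSE, close)] <- tooClose[c(FALSE, close)] | TRUE
  }
  # two calls at the same position (different alleles) have distance 0
  entries <- rbind(
    .ledgerRows(sampleID(callset), cl[!tooClose, , drop = FALSE],
                "prefilter-proximity", "retain", "proximity-ok"),
    .ledgerRows(sampleID(callset), cl[tooClose, , drop = FALSE],
                "prefilter-proximity", "reject", "proximity"))
  list(callset = .withCalls(callset, cl[!tooClose, , drop = FALSE]),
       entries = entries)
}

#' Apply both universal pre-filters
#'
#' Strand filter first, then proximity filter on the survivors.
#'
#' @inheritParams strandFilter
#' @inheritParams proximityFilter
#' @return list with \code{callset} and \code{entries}.
#' @export
preFilter <- function(callset, windowBp = 10L, permissive = FALSE) {
  s <- strandFilter(callset, permissive = permissive)
  p <- proximityFilter(s$callset, windowBp = windowBp)
  list(callset = p$callset, entries = rbind(s$entries, p$entries))
}
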