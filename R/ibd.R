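# Pairwise discordance tracks, shared identical-by-descent segment
# detection by a sliding window with deterministic boundary refinement,
# the shared-segment filter, and the linkage-interval crossing check.
#
# Coordinates: variant positions are 1-based; segments and intervals are
# 0-based half-open [start, end), so a call at position p lies inside a
# segment iff start <= p - 1 < end.

#' Pairwise discordance track
#'
#' Every (chrom, pos, ref, alt) key present in either sample becomes one
#' point: "AA" when both samples carry the alternate allele (concordant),
#' "AR" when exactly one does (discordant). Within a true identical-by-
#' descent segment, discordant points arise only from calling errors or
#' de novo mutation.
#'
#' @param callsA,callsB \code{SampleCallSet}s from the same chromosome.
#' @return data.frame with columns pos, status, sorted by position.
#' @export
discordanceTrack <- function(callsA, callsB) {
  a <- variantKeys(callsA)
  b <- variantKeys(callsB)
  keys <- union(a, b)
  pos <- as.integer(vapply(strsplit(keys, ":", fixed = TRUE),
                           `[`, character(1), 2L))
  status <- ifelse(keys %in% a & keys %in% b, "AA", "AR")
  o <- order(pos)
  data.frame(pos = pos[o], status = status[o], stringsAsFactors = FALSE)
}

#' Detect shared identical-by-descent segments
#'
#' Slides a window of \code{windowBp} across [0, chromLength) at
#' \code{stepBp} increments; windows containing at most
#' \code{maxDiscordant} discordant (AR) points are flagged, and
#' overlapping or adjacent flagged windows are merged. Each merged region
#' is then refined deterministically: it is extended to the nearest
#' exterior AR point on each side, and the boundary is placed at the
#' midpoint between the outermost interior point and that exterior AR
#' point (chromosome ends clamp). Regions containing no points are
#' dropped. A coarse step can miss a discordance-free stretch only
#' slightly longer than the window; lower \code{stepBp} for exhaustive
#' detection.
#'
#' @param track data.frame from \code{\link{discordanceTrack}}.
#' @param windowBp window length in bp (default 5e6).
#' @param stepBp window step in bp (default 1e6).
#' @param maxDiscordant maximum AR points tolerated per window (default 0).
#' @param chromLength chromosome length in bp (required).
#' @return data.frame with columns start, end (0-based half-open), n_AA,
#'   n_AR; segments are sorted and non-overlapping.
#' @export
detectSharedSegments <- function(track, windowBp = 5e6, stepBp = 1e6,
                                 maxDiscordant = 0L, chromLength) {
  if (missing(chromLength) || is.null(chromLength))
    stop("chromLength is required")
  empty <- data.frame(start = numeric(), end = numeric(),
                      n_AA = integer(), n_AR = integer())
  if (nrow(track) == 0L) return(empty)
  arPos <- track$pos[track$status == "AR"]
  allPos <- track$pos
  starts <- unique(c(seq(0, max(0, chromLength - windowBp), by = stepBp),
                     max(0, chromLength - windowBp)))
  # AR count in [s, s+windowBp) for position p: 0-based p-1 in window
  cnt <- findInterval(starts + windowBp - 0.5, arPos - 1) -
    findInterval(starts - 0.5, arPos - 1)
  flagged <- cnt <= maxDiscordant
  if (!any(flagged)) return(empty)
  # merge overlapping/adjacent flagged windows (all share one width, so
  # two flagged windows merge iff their starts differ by <= windowBp)
  fs <- sort(starts[flagged])
  grp <- cumsum(c(TRUE, diff(fs) > windowBp))
  merged <- lapply(split(fs, grp), function(g)
    c(g[1], g[length(g)] + windowBp))
  segs <- lapply(merged, function(reg) {
    a <- reg[1]; b <- reg[2]
    prevAR <- arPos[arPos - 1 < a]
    prevAR <- if (length(prevAR)) max(prevAR) else NA_real_
    nextAR <- arPos[arPos - 1 >= b]
    nextAR <- if (length(nextAR)) min(nextAR) else NA_real_
    lo <- if (is.na(prevAR)) -Inf else prevAR
    hi <- if (is.na(nextAR)) Inf else nextAR
    interior <- allPos[allPos > lo & allPos < hi]
    if (length(interior) == 0L) return(NULL)
    start <- if (is.na(prevAR)) 0
             else floor((prevAR + min(interior)) / 2)
    end <- if (is.na(nextAR)) chromLength
           else ceiling((max(interior) + nextAR) / 2) - 1
    inSeg <- track$pos - 1 >= start & track$pos - 1 < end
    data.frame(start = start, end = end,
               n_AA = sum(inSeg & track$status == "AA"),
               n_AR = sum(inSeg & track$status == "AR"))
  })
  segs <- do.call(rbind, segs[!vapply(segs, is.null, logical(1))])
  if (is.null(segs)) return(empty)
  segs <- unique(segs[order(segs$start), , drop = FALSE])
  rownames(segs) <- NULL
  segs
}

#' Shared-segment filter for one kindred pair
#'
#' Retains a call iff its position falls inside a detected shared segment
#' AND the call is concordant (present in both members of the pair). All
#' other calls are rejected with reason "shared-segment": concordant calls
#' outside segments are identical by state, not by descent, and residual
#' discordant calls inside a segment are likely erroneous.
#'
#' @param callsA,callsB \code{SampleCallSet}s of the pair.
#' @param segments data.frame from \code{\link{detectSharedSegments}}.
#' @return list with \code{callsets} (list of the two retained
#'   \code{SampleCallSet}s) and \code{entries} (ledger rows).
#' @export
sharedSegmentFilter <- function(callsA, callsB, segments) {
  inside <- function(pos) {
    ok <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(segments)))
      ok <- ok | (pos - 1 >= segments$start[i] & pos - 1 < segments$end[i])
    ok
  }
  kA <- variantKeys(callsA)
  kB <- variantKeys(callsB)
  one <- function(cs, own, other) {
    cl <- calls(cs)
    keep <- (own %in% other) & inside(cl$pos)
    entries <- rbind(
      .ledgerRows(sampleID(cs), cl[keep, , drop = FALSE],
                  "shared-segment", "retain", "shared-segment-ok"),
      .ledgerRows(sampleID(cs), cl[!keep, , drop = FALSE],
                  "shared-segment", "reject", "shared-segment"))
    list(callset = .withCalls(cs, cl[keep, , drop = FALSE]),
         entries = entries)
  }
  ra <- one(callsA, kA, kB)
  rb <- one(callsB, kB, kA)
  list(callsets = list(ra$callset, rb$callset),
       entries = rbind(ra$entries, rb$entries))
}

#' Check linkage intervals against segment boundaries
#'
#' An interval "crosses" a segment when exactly one of the segment's two
#' boundaries lies strictly in the interval's interior, i.e. the interval
#' straddles a recombination boundary. Linked markers should rarely cross
#' identical-by-descent segment boundaries when those boundaries track
#' real recombination sites.
#'
#' @param segments data.frame with start, end (half-open).
#' @param linkedIntervals data.frame with start, end (half-open).
#' @return list with \code{count} (number of crossing intervals) and
#'   \code{offending} (the crossing intervals with the boundary crossed).
#' @export
checkLinkageCrossings <- function(segments, linkedIntervals) {
  off <- list()
  for (i in seq_len(nrow(linkedIntervals))) {
    s <- linkedIntervals$start[i]; e <- linkedIntervals$end[i]
    for (j in seq_len(nrow(segments))) {
      inb <- c(segments$start[j], segments$end[j])
      inside <- inb > s & inb < e
      if (sum(inside) == 1L) {
        off[[length(off) + 1L]] <-
          data.frame(start = s, end = e, boundary = inb[inside])
        break
      }
    }
  }
  off <- if (length(off)) do.call(rbind, off)
         else data.frame(start = numeric(), end = numeric(),
                         boundary = numeric())
  list(count = nrow(off), offending = off)
}
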