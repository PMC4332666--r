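# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# minimal call table at given positions, defaults chosen to pass both
# pre-filters (depth 20, 10 alt reads per strand)
makeCalls <- function(pos, ref = "A", alt = "G", genotype = 1,
                      depth = 20L, altFwd = 10L, altRev = 10L,
                      funcClass = "missense", chrom = "X") {
  n <- length(pos)
  data.frame(chrom = chrom, pos = as.integer(pos),
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             genotype = rep_len(genotype, n),
             depth = rep_len(depth, n),
             altFwd = rep_len(altFwd, n), altRev = rep_len(altRev, n),
             funcClass = rep_len(funcClass, n),
             stringsAsFactors = FALSE)
}

makeCallSet <- function(id, pos, ...) SampleCallSet(id, makeCalls(pos, ...))

# variant keys of a causal-truth row
causalKey <- function(ca) paste(ca$chrom, ca$pos, ca$ref, ca$alt, sep = ":")

# tiny deterministic cohort simulation used by several files
smallSim <- function(seed = 1, nSporadic = 6L, nPairs = 3L, ...) {
  cfg <- simulationConfig(nSporadic = nSporadic,
                          pairRelationships = rep("brothers", nPairs),
                          nPanelVariants = 800L,
                          ancestryOutliers = 0L, ...)
  panel <- simulateReferencePanel(cfg, seed)
  sim <- simulateCohort(cfg, panel, seed)
  c(sim, list(config = cfg, panel = panel,
              panels = simulateFilterPanels(panel, cfg, seed)))
}

# brute-force oracle: maximal AR-free intervals of length >= windowBp
# (0-based half-open, bounded by exterior AR points / chromosome ends)
bruteForceSegments <- function(track, windowBp, chromLength) {
  ar <- sort(track$pos[track$status == "AR"]) - 1  # 0-based
  bounds <- c(-1, ar, chromLength)
  out <- list()
  for (i in seq_len(length(bounds) - 1L)) {
    lo <- bounds[i] + 1
    hi <- bounds[i + 1L]
    if (hi - lo >= windowBp)
      out[[length(out) + 1L]] <- c(lo, hi)
  }
  out
}

# points of a track inside a set of half-open intervals
pointsInside <- function(track, start, end) {
  sel <- rep(FALSE, nrow(track))
  for (i in seq_along(start))
    sel <- sel | (track$pos - 1 >= start[i] & track$pos - 1 < end[i])
  track$pos[sel]
}
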