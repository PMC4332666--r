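# Discordance tracks, shared-segment detection vs brute force, the
# shared-segment filter, and linkage-interval crossings.

track <- function(pos, status) data.frame(pos = as.integer(pos),
                                          status = status,
                                          stringsAsFactors = FALSE)

test_that("discordance track is set algebra on variant keys", {
  a <- makeCallSet("A", c(100, 200))
  b <- makeCallSet("B", c(200, 300))
  tr <- discordanceTrack(a, b)
  expect_equal(tr$pos, c(100L, 200L, 300L))
  expect_equal(tr$status, c("AR", "AA", "AR"))
  same <- discordanceTrack(a, a)
  expect_true(all(same$status == "AA"))
  disj <- discordanceTrack(a, makeCallSet("C", c(500, 600)))
  expect_true(all(disj$status == "AR"))
})

test_that("no discordance yields one chromosome-spanning segment", {
  tr <- track(c(2e6, 8e6), c("AA", "AA"))
  segs <- detectSharedSegments(tr, chromLength = 2e7)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$start, 0)
  expect_equal(segs$end, 2e7)
  expect_equal(segs$n_AA, 2L)
  expect_equal(segs$n_AR, 0L)
})

test_that("saturating discordance yields no segments", {
  pos <- seq(1e5, 2e7, by = 1e5)
  tr <- track(pos, rep("AR", length(pos)))
  segs <- detectSharedSegments(tr, chromLength = 2e7)
  expect_equal(nrow(segs), 0L)
  expect_error(detectSharedSegments(tr, chromLength = NULL), "required")
})

test_that("a planted discordance-free stretch is recovered within one gap", {
  set.seed(21)
  L <- 6e7
  segTrue <- c(2e7, 4e7)  # 20 Mb shared stretch
  arPos <- sort(sample(c(sample.int(segTrue[1] - 1, 150),
                         segTrue[2] + sample.int(L - segTrue[2] - 1, 150))))
  aaPos <- sort(segTrue[1] + sample.int(diff(segTrue) - 1, 40))
  tr <- track(sort(c(arPos, aaPos)),
              ifelse(sort(c(arPos, aaPos)) %in% aaPos, "AA", "AR"))
  segs <- detectSharedSegments(tr, windowBp = 5e6, stepBp = 1e6,
                               chromLength = L)
  expect_equal(nrow(segs), 1L)
  # boundaries lie between the planted breakpoint's flanking points
  leftGap <- c(max(arPos[arPos < segTrue[1]]), min(aaPos))
  rightGap <- c(max(aaPos), min(arPos[arPos > segTrue[2]]))
  expect_gte(segs$start, leftGap[1])
  expect_lte(segs$start, leftGap[2])
  expect_gte(segs$end, rightGap[1])
  expect_lte(segs$end, rightGap[2])
  expect_equal(segs$n_AA, 40L)
  expect_equal(segs$n_AR, 0L)
})

test_that("detection matches maximal AR-free intervals on random tracks", {
  set.seed(22)
  for (rep in 1:100) {
    L <- 1e6
    n <- sample(20:120, 1)
    pos <- sort(sample.int(L - 1, n))
    status <- sample(c("AA", "AR"), n, TRUE, prob = c(0.6, 0.4))
    tr <- track(pos, status)
    w <- 5e4
    segs <- detectSharedSegments(tr, windowBp = w, stepBp = 1,
                                 chromLength = L)
    oracle <- bruteForceSegments(tr, w, L)
    oracle <- Filter(function(iv) {
      length(pointsInside(tr, iv[1], iv[2])) > 0
    }, oracle)
    expect_equal(nrow(segs), length(oracle))
    for (i in seq_along(oracle)) {
      # identical point content, boundaries within the refinement gap
      expect_equal(pointsInside(tr, segs$start[i], segs$end[i]),
                   pointsInside(tr, oracle[[i]][1], oracle[[i]][2]))
    }
  }
})

test_that("segment coverage is monotone in the discordance tolerance", {
  set.seed(23)
  for (rep in 1:10) {
    L <- 1e6
    n <- 80
    pos <- sort(sample.int(L - 1, n))
    status <- sample(c("AA", "AR"), n, TRUE, prob = c(0.7, 0.3))
    tr <- track(pos, status)
    cov <- vapply(0:3, function(md) {
      segs <- detectSharedSegments(tr, windowBp = 5e4, stepBp = 1e3,
                                   maxDiscordant = md, chromLength = L)
      sum(segs$end - segs$start)
    }, numeric(1))
    expect_true(all(diff(cov) >= 0))
  }
})

test_that("shared-segment filter keeps concordant calls inside segments", {
  a <- makeCallSet("A", c(1e6, 6e6, 9e6))
  b <- makeCallSet("B", c(1e6, 6e6, 12e6))
  segs <- data.frame(start = 0, end = 7e6)
  r <- sharedSegmentFilter(a, b, segs)
  expect_equal(calls(r$callsets[[1]])$pos, c(1e6, 6e6))   # AA inside
  expect_equal(calls(r$callsets[[2]])$pos, c(1e6, 6e6))
  # AA outside a segment is rejected; AR inside is rejected
  segs2 <- data.frame(start = 8e6, end = 13e6)
  r2 <- sharedSegmentFilter(a, b, segs2)
  expect_equal(nCalls(r2$callsets[[1]]), 0L)   # 9e6 is discordant
  expect_equal(nCalls(r2$callsets[[2]]), 0L)   # 12e6 discordant, 1e6/6e6 out
  expect_true(all(r2$entries$reason[r2$entries$decision == "reject"] ==
                    "shared-segment"))
})

test_that("linkage crossings count intervals straddling one boundary", {
  segs <- data.frame(start = 1e6, end = 5e6)
  expect_equal(checkLinkageCrossings(
    segs, data.frame(start = 2e6, end = 3e6))$count, 0L)  # inside
  r <- checkLinkageCrossings(segs, data.frame(start = 5e5, end = 2e6))
  expect_equal(r$count, 1L)                               # straddles start
  expect_equal(r$offending$boundary, 1e6)
  expect_equal(checkLinkageCrossings(
    segs, data.frame(start = 5e5, end = 6e6))$count, 0L)  # spans both
})

test_that("true segment boundaries coincide with linkage intervals", {
  sim <- smallSim(8)
  link <- sim$truth$linkage
  for (p1 in names(sim$truth$segments)) {
    segs <- sim$truth$segments[[p1]]
    expect_equal(checkLinkageCrossings(segs, link)$count, 0L)
  }
})
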