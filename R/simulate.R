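# Synthetic cohort, reference panel, and ground-truth generator.
#
# The generator emulates the inputs of a male X-chromosome exome study:
# a cohort of sporadic cases and affected relative pairs with
# recombination-bounded shared segments, one planted causal variant per
# family, three classes of injected calling errors (strand-biased,
# clustered, batch-systematic) plus within-pair discordance noise, and
# sex-resolved reference panels with clinical annotations.

.MEIOSES <- c("brothers" = 2, "half-brothers" = 2,
              "cousins" = 4, "uncle-nephew" = 3)
.SHAREPROB <- c("brothers" = 0.5, "half-brothers" = 0.5,
                "cousins" = 0.125, "uncle-nephew" = 0.25)

.FUNC_PROBS <- c(nonsense = 0.004, frameshift = 0.004, splicing = 0.012,
                 missense = 0.12, synonymous = 0.25, intronic = 0.50,
                 other = 0.11)

#' Simulation configuration
#'
#' Defaults describe the emulated study: 30 sporadic affected males plus
#' 26 affected pairs (22 brother, 2 half-brother, 1 cousin and 1
#' uncle-nephew pairs) on a 155.27-Mb X chromosome, sequenced at mean
#' depth 49 in libraries of 12. Variant density is scaled to roughly
#' 1,000 calls per sample for test speed. Recombination is a Poisson
#' number of breakpoints per meiosis; relationship depth sets the number
#' of meioses and the per-interval sharing probability.
#'
#' @param nSporadic sporadic samples (default 30).
#' @param pairRelationships character vector, one relationship per pair.
#' @param chromLength chromosome length bp.
#' @param nPanelVariants polymorphic sites in the master panel.
#' @param freqShape1,freqShape2 Beta parameters of the allele-frequency
#'   distribution (mean 0.2 by default, giving ~1,000 calls/sample).
#' @param pathogenicFrac fraction of panel records flagged pathogenic.
#' @param nGenes,nKnownGenes target gene set and its known subset.
#' @param causalKnownProb probability a planted causal gene is drawn from
#'   the known list.
#' @param meanDepth mean sequencing depth.
#' @param strandBiasRate,clusterRate injected error counts per genuine
#'   call (strand-biased singletons; clustered pairs within 10 bp).
#' @param batchSystematicPerBatch systematic error keys injected into
#'   every sample of each library batch.
#' @param discordanceNoiseRate within-pair discordant strand-biased calls
#'   per genuine call, planted inside true shared segments.
#' @param batchSize samples per library batch.
#' @param crossoversPerMeiosis expected recombination breakpoints per
#'   meiosis on the X.
#' @param minCausalSegmentBp minimum length of the shared segment hosting
#'   a pair's causal variant; pair sharing structures are redrawn until
#'   one segment reaches it, reflecting that mapped families come to
#'   attention through sizeable linkage regions.
#' @param dbsnpCoverage,evsCoverage,maleMiniCoverage fraction of master
#'   panel sites carried by each derived subtraction panel.
#' @param ancestryOutliers number of samples simulated with admixed
#'   (population-B) ancestry contribution.
#' @param admixture admixture proportion for those samples.
#' @param parMask pseudoautosomal mask (half-open intervals).
#' @return a list of class "kxSimConfig".
#' @export
simulationConfig <- function(
    nSporadic = 30L,
    pairRelationships = c(rep("brothers", 22), rep("half-brothers", 2),
                          "cousins", "uncle-nephew"),
    chromLength = 155270560,
    nPanelVariants = 5000L,
    freqShape1 = 1, freqShape2 = 4,
    pathogenicFrac = 0.002,
    nGenes = 975L, nKnownGenes = 103L,
    causalKnownProb = 0.5,
    meanDepth = 49,
    strandBiasRate = 0.02, clusterRate = 0.01,
    batchSystematicPerBatch = 5L,
    discordanceNoiseRate = 0.005,
    batchSize = 12L,
    crossoversPerMeiosis = 1.8,
    minCausalSegmentBp = 1e7,
    dbsnpCoverage = 0.9, evsCoverage = 0.55, maleMiniCoverage = 0.3,
    ancestryOutliers = 5L, admixture = 0.3,
    parMask = parMaskHg19) {
  stopifnot(all(pairRelationships %in% names(.MEIOSES)))
  cfg <- as.list(environment())
  class(cfg) <- "kxSimConfig"
  cfg
}

.inPar <- function(pos, parMask) {
  if (is.null(parMask)) return(rep(FALSE, length(pos)))
  .inIntervals(pos, parMask)
}

# draw n new positions keeping >= minGap bp from all reserved positions
.drawPositions <- function(n, lo, hi, reserved, minGap = 25L,
                           parMask = NULL) {
  out <- integer(0)
  res <- sort(reserved)
  tries <- 0L
  while (length(out) < n && tries < 200L) {
    tries <- tries + 1L
    lo <- ceiling(lo); hi <- floor(hi)
    p <- as.integer(lo + sample.int(max(1, hi - lo), 1L))
    if (.inPar(p, parMask)) next
    i <- findInterval(p, res)
    nearL <- if (i >= 1L) res[i] else -Inf
    nearR <- if (i < length(res)) res[i + 1L] else Inf
    if (p - nearL >= minGap && nearR - p >= minGap) {
      res <- sort(c(res, p))
      out <- c(out, p)
      tries <- 0L
    }
  }
  if (length(out) < n)
    stop("could not place ", n, " positions in [", lo, ",", hi, ")")
  out
}

.randAllele <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)
.randAlt <- function(ref) {
  vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
         character(1), USE.NAMES = FALSE)
}

# depth and strand-split alt depths for a genuine call
.depthDraw <- function(n, meanDepth, forceBoth = FALSE) {
  d <- pmax(stats::rpois(n, meanDepth), if (forceBoth) 2L else 1L)
  if (forceBoth) {
    fwd <- 1L + stats::rbinom(n, d - 2L, 0.5)
  } else {
    fwd <- stats::rbinom(n, d, 0.5)
  }
  data.frame(depth = d, altFwd = fwd, altRev = d - fwd)
}

#' Simulate the master reference panel
#'
#' Draws polymorphic sites outside the pseudoautosomal regions with
#' Beta-distributed population-A allele frequencies, an independent
#' population-B frequency column, sex-resolved carrier counts consistent
#' with the frequency (binomial over 525 male chromosomes and 1,134
#' female chromosomes), and a configurable fraction of low-frequency
#' records flagged pathogenic. Deterministic given the seed.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param seed integer seed.
#' @return a \code{ReferencePanel} ("synthetic-master").
#' @export
simulateReferencePanel <- function(config, seed) {
  set.seed(seed)
  L <- config$chromLength
  pos <- sort(sample.int(L - 1L, ceiling(config$nPanelVariants * 1.2)))
  pos <- pos[!.inPar(pos, config$parMask)]
  pos <- unique(pos)[seq_len(config$nPanelVariants)]
  n <- length(pos)
  fA <- stats::rbeta(n, config$freqShape1, config$freqShape2)
  fB <- stats::rbeta(n, config$freqShape1, config$freqShape2)
  clin <- rep("none", n)
  nPath <- round(config$pathogenicFrac * n)
  if (nPath > 0) {
    idx <- sample.int(n, nPath)
    clin[idx] <- sample(c("pathogenic", "probable-pathogenic"), nPath,
                        replace = TRUE)
    fA[idx] <- stats::runif(nPath, 1e-4, 0.005)  # pathogenic alleles rare
  }
  maleCar <- stats::rbinom(n, 525L, fA)
  femCopies <- stats::rbinom(n, 1134L, fA)
  ref <- .randAllele(n)
  ReferencePanel(data.frame(
    chrom = "X", pos = pos, ref = ref, alt = .randAlt(ref),
    maf = fA, allele_count = maleCar + femCopies,
    male_carrier_count = maleCar,
    female_only = maleCar == 0L & femCopies > 0L,
    hemizygous_annotated = maleCar >= 1L,
    clin_sig = clin, freq_popA = fA, freq_popB = fB,
    stringsAsFactors = FALSE),
    source = "synthetic-master")
}

# sharing structure for one pair: Poisson breakpoints over all meioses,
# each inter-breakpoint interval shared with the relationship's
# probability; adjacent shared intervals merge. Redrawn until the largest
# shared segment can host the causal variant.
.drawSharing <- function(relationship, config) {
  L <- config$chromLength
  m <- .MEIOSES[[relationship]]
  q <- .SHAREPROB[[relationship]]
  repeat {
    nbp <- stats::rpois(1L, config$crossoversPerMeiosis * m)
    bp <- sort(round(stats::runif(nbp, 1, L - 1)))
    bounds <- unique(c(0, bp, L))
    ns <- length(bounds) - 1L
    shared <- stats::runif(ns) < q
    if (!any(shared)) next
    segs <- data.frame(start = bounds[-length(bounds)][shared],
                       end = bounds[-1][shared])
    # merge adjacent shared intervals
    merged <- segs[1, , drop = FALSE]
    for (i in seq_len(nrow(segs))[-1]) {
      if (segs$start[i] == merged$end[nrow(merged)])
        merged$end[nrow(merged)] <- segs$end[i]
      else merged <- rbind(merged, segs[i, ])
    }
    if (max(merged$end - merged$start) >= config$minCausalSegmentBp)
      return(list(segments = merged, breakpoints = bp))
  }
}

#' Simulate a cohort with ground truth
#'
#' Generates per-sample haploid call sets from the panel's population-A
#' frequencies. Kindred pairs share identical haplotypes inside
#' recombination-bounded shared segments and draw independently outside;
#' a subset of samples carries an admixed population-B contribution. One
#' causal variant (a novel nonsense key absent from every panel) is
#' planted per family — inside the pair's largest shared segment, or
#' anywhere for sporadic cases — in a gene drawn from the known-gene list
#' with configurable probability. Errors are injected per class:
#' strand-biased calls (no reverse-strand support), clustered call pairs
#' within 10 bp, batch-systematic keys recurring in every sample of a
#' library batch, and within-pair discordant strand-biased calls inside
#' true shared segments. The emitted linkage intervals partition the
#' chromosome at the union of all recombination breakpoints, so true
#' segment boundaries always coincide with linkage-interval boundaries.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param panel master \code{ReferencePanel} from
#'   \code{\link{simulateReferencePanel}}.
#' @param seed integer seed (internally offset from the panel's stream).
#' @return list with \code{cohort} (named list of \code{SampleCallSet}),
#'   \code{design} (\code{CohortDesign}) and \code{truth} (list: causal
#'   table, per-pair true segments, injected error table, gene map, known
#'   genes, linkage intervals, ancestry labels, gene bounds).
#' @export
simulateCohort <- function(config, panel, seed) {
  set.seed(seed + 1000003L)
  L <- config$chromLength
  rec <- panelRecords(panel)
  nPairs <- length(config$pairRelationships)

  sporadicIds <- sprintf("S%02d", seq_len(config$nSporadic))
  pairIds <- lapply(seq_len(nPairs), function(i)
    c(sprintf("P%02da", i), sprintf("P%02db", i)))
  allIds <- c(sporadicIds, unlist(pairIds))
  batch <- paste0("lib", ((seq_along(allIds) - 1L) %/% config$batchSize) + 1L)
  names(batch) <- allIds

  design <- CohortDesign(
    samples = data.frame(sample_id = allIds, sex = "male",
                         batch = unname(batch), stringsAsFactors = FALSE),
    pairs = data.frame(sample1 = vapply(pairIds, `[`, character(1), 1L),
                       sample2 = vapply(pairIds, `[`, character(1), 2L),
                       relationship = config$pairRelationships,
                       stringsAsFactors = FALSE),
    sporadic = sporadicIds)

  admixed <- if (config$ancestryOutliers > 0L)
    sample(sporadicIds, min(config$ancestryOutliers, length(sporadicIds)))
  else character(0)
  ancestry <- stats::setNames(
    ifelse(allIds %in% admixed, "admixed", "popA"), allIds)

  geneBounds <- round(seq(0, L, length.out = config$nGenes + 1L))
  geneIds <- sprintf("XG%03d", seq_len(config$nGenes))
  knownGenes <- sort(sample(geneIds, config$nKnownGenes))
  geneOf <- function(pos) geneIds[findInterval(pos - 1L, geneBounds,
                                               rightmost.closed = TRUE)]

  siteFunc <- sample(names(.FUNC_PROBS), nrow(rec), replace = TRUE,
                     prob = .FUNC_PROBS)
  freqOf <- function(id) {
    if (ancestry[[id]] == "admixed")
      (1 - config$admixture) * rec$freq_popA +
        config$admixture * rec$freq_popB
    else rec$freq_popA
  }

  reserved <- rec$pos   # growing global register of occupied positions
  newSites <- function(n, lo = 0L, hi = L) {
    p <- .drawPositions(n, lo, hi, reserved, minGap = 25L,
                        parMask = config$parMask)
    reserved <<- c(reserved, p)
    p
  }

  genoOf <- list()       # per sample: logical vector over panel sites
  segsOf <- list()       # per pair id1: true shared segments
  allBreakpoints <- numeric(0)
  for (s in sporadicIds)
    genoOf[[s]] <- stats::runif(nrow(rec)) < freqOf(s)
  for (i in seq_len(nPairs)) {
    sh <- .drawSharing(config$pairRelationships[i], config)
    segsOf[[pairIds[[i]][1]]] <- sh$segments
    allBreakpoints <- c(allBreakpoints, sh$breakpoints)
    f <- freqOf(pairIds[[i]][1])
    gA <- stats::runif(nrow(rec)) < f
    gB <- stats::runif(nrow(rec)) < f
    inShared <- .inIntervals(rec$pos, sh$segments)
    gB[inShared] <- gA[inShared]
    genoOf[[pairIds[[i]][1]]] <- gA
    genoOf[[pairIds[[i]][2]]] <- gB
  }

  # causal variants: one novel key per family
  causal <- list()
  plantCausal <- function(lo, hi) {
    gFit <- which(geneBounds[-length(geneBounds)] >= lo &
                    geneBounds[-1] <= hi)
    gFit <- gFit[!.inPar(geneBounds[gFit] + 1L, config$parMask)]
    known <- gFit[geneIds[gFit] %in% knownGenes]
    unknown <- setdiff(gFit, known)
    pick <- if (stats::runif(1) < config$causalKnownProb && length(known))
      known else if (length(unknown)) unknown else gFit
    g <- if (length(pick) > 1L) sample(pick, 1L) else pick
    pos <- newSites(1L, max(geneBounds[g], lo),
                    min(geneBounds[g + 1L], hi))
    ref <- .randAllele(1L)
    list(pos = pos, ref = ref, alt = .randAlt(ref), gene = geneIds[g])
  }
  for (i in seq_len(nPairs)) {
    segs <- segsOf[[pairIds[[i]][1]]]
    big <- segs[which.max(segs$end - segs$start), ]
    len <- big$end - big$start
    cv <- plantCausal(big$start + 0.1 * len, big$end - 0.1 * len)
    causal[[length(causal) + 1L]] <- data.frame(
      family = paste0("F", i), sample_ids = paste(pairIds[[i]],
                                                  collapse = ","),
      chrom = "X", pos = cv$pos, ref = cv$ref, alt = cv$alt,
      gene_id = cv$gene, known = cv$gene %in% knownGenes,
      stringsAsFactors = FALSE)
  }
  for (j in seq_along(sporadicIds)) {
    cv <- plantCausal(0L, L)
    causal[[length(causal) + 1L]] <- data.frame(
      family = paste0("FS", j), sample_ids = sporadicIds[j],
      chrom = "X", pos = cv$pos, ref = cv$ref, alt = cv$alt,
      gene_id = cv$gene, known = cv$gene %in% knownGenes,
      stringsAsFactors = FALSE)
  }
  causal <- do.call(rbind, causal)

  # assemble genuine calls per sample
  cohort <- list()
  errors <- list()
  addErr <- function(class, sample, pos, ref, alt) {
    errors[[length(errors) + 1L]] <<- data.frame(
      class = class, sample_id = sample, chrom = "X", pos = pos,
      ref = ref, alt = alt, stringsAsFactors = FALSE)
  }
  batchKeys <- list()
  for (b in unique(batch)) {
    nks <- config$batchSystematicPerBatch
    if (nks > 0L) {
      p <- newSites(nks)
      r <- .randAllele(nks)
      batchKeys[[b]] <- data.frame(pos = p, ref = r, alt = .randAlt(r),
                                   stringsAsFactors = FALSE)
    }
  }

  for (s in allIds) {
    g <- genoOf[[s]]
    idx <- which(g)
    dd <- .depthDraw(length(idx), config$meanDepth)
    cl <- data.frame(chrom = "X", pos = rec$pos[idx], ref = rec$ref[idx],
                     alt = rec$alt[idx], genotype = 1,
                     depth = dd$depth, altFwd = dd$altFwd,
                     altRev = dd$altRev, funcClass = siteFunc[idx],
                     stringsAsFactors = FALSE)
    nGenuine <- nrow(cl)
    # causal call(s) for this sample
    mine <- causal[vapply(strsplit(causal$sample_ids, ",", fixed = TRUE),
                          function(x) s %in% x, logical(1)), ,
                   drop = FALSE]
    if (nrow(mine)) {
      dd <- .depthDraw(nrow(mine), config$meanDepth, forceBoth = TRUE)
      cl <- rbind(cl, data.frame(
        chrom = "X", pos = mine$pos, ref = mine$ref, alt = mine$alt,
        genotype = 1, depth = dd$depth, altFwd = dd$altFwd,
        altRev = dd$altRev, funcClass = "nonsense",
        stringsAsFactors = FALSE))
    }
    # strand-biased singletons
    nsb <- stats::rpois(1L, config$strandBiasRate * nGenuine)
    if (nsb > 0L) {
      p <- newSites(nsb)
      r <- .randAllele(nsb)
      a <- .randAlt(r)
      d <- pmax(stats::rpois(nsb, 15), 1L)
      cl <- rbind(cl, data.frame(
        chrom = "X", pos = p, ref = r, alt = a, genotype = 1,
        depth = d, altFwd = d, altRev = 0L,
        funcClass = sample(names(.FUNC_PROBS), nsb, replace = TRUE,
                           prob = .FUNC_PROBS),
        stringsAsFactors = FALSE))
      addErr("strand", s, p, r, a)
    }
    # clustered pairs within 10 bp
    ncl <- stats::rpois(1L, config$clusterRate * nGenuine)
    if (ncl > 0L) {
      anchor <- newSites(ncl)
      mate <- anchor + sample(2:10, ncl, replace = TRUE)
      p <- c(anchor, mate)
      r <- .randAllele(2L * ncl)
      a <- .randAlt(r)
      dd <- .depthDraw(2L * ncl, config$meanDepth, forceBoth = TRUE)
      cl <- rbind(cl, data.frame(
        chrom = "X", pos = p, ref = r, alt = a, genotype = 1,
        depth = dd$depth, altFwd = dd$altFwd, altRev = dd$altRev,
        funcClass = sample(names(.FUNC_PROBS), 2L * ncl, replace = TRUE,
                           prob = .FUNC_PROBS),
        stringsAsFactors = FALSE))
      addErr("cluster", s, p, r, a)
    }
    # batch-systematic keys
    bk <- batchKeys[[batch[[s]]]]
    if (!is.null(bk) && nrow(bk)) {
      dd <- .depthDraw(nrow(bk), config$meanDepth, forceBoth = TRUE)
      cl <- rbind(cl, data.frame(
        chrom = "X", pos = bk$pos, ref = bk$ref, alt = bk$alt,
        genotype = 1, depth = dd$depth, altFwd = dd$altFwd,
        altRev = dd$altRev, funcClass = "other",
        stringsAsFactors = FALSE))
      addErr("batch", s, bk$pos, bk$ref, bk$alt)
    }
    cohort[[s]] <- cl
  }

  # within-pair discordance noise: strand-biased calls inside true shared
  # segments of one member only (removed by the strand pre-filter)
  for (i in seq_len(nPairs)) {
    segs <- segsOf[[pairIds[[i]][1]]]
    nGenuine <- sum(genoOf[[pairIds[[i]][1]]])
    nd <- stats::rpois(1L, config$discordanceNoiseRate * nGenuine)
    for (k in seq_len(nd)) {
      seg <- segs[sample.int(nrow(segs), 1L,
                             prob = segs$end - segs$start), ]
      p <- tryCatch(newSites(1L, seg$start, seg$end),
                    error = function(e) NULL)
      if (is.null(p)) next
      r <- .randAllele(1L)
      a <- .randAlt(r)
      victim <- sample(pairIds[[i]], 1L)
      d <- pmax(stats::rpois(1L, 15), 1L)
      cohort[[victim]] <- rbind(cohort[[victim]], data.frame(
        chrom = "X", pos = p, ref = r, alt = a, genotype = 1,
        depth = d, altFwd = d, altRev = 0L, funcClass = "other",
        stringsAsFactors = FALSE))
      addErr("discordance", victim, p, r, a)
    }
  }

  cohort <- lapply(allIds, function(s)
    SampleCallSet(s, cohort[[s]], batch = batch[[s]]))
  names(cohort) <- allIds

  # gene map over every key seen in the cohort
  allCalls <- unique(do.call(rbind, lapply(cohort, function(cs)
    calls(cs)[c("chrom", "pos", "ref", "alt", "funcClass")])))
  geneMap <- data.frame(allCalls[c("chrom", "pos", "ref", "alt")],
                        gene_id = geneOf(allCalls$pos),
                        func_class = allCalls$funcClass,
                        stringsAsFactors = FALSE)
  rownames(geneMap) <- NULL

  bp <- sort(unique(c(0, allBreakpoints, L)))
  linkage <- data.frame(start = bp[-length(bp)], end = bp[-1])
  errors <- if (length(errors)) do.call(rbind, errors)
            else data.frame(class = character(), sample_id = character(),
                            chrom = character(), pos = integer(),
                            ref = character(), alt = character())

  list(cohort = cohort, design = design,
       truth = list(causal = causal, segments = segsOf, errors = errors,
                    geneMap = geneMap, knownGenes = knownGenes,
                    linkage = linkage, ancestry = ancestry,
                    geneBounds = geneBounds))
}

#' Derive subtraction panels from the master panel
#'
#' Real reference resources cover overlapping but different subsets of
#' segregating variation. Each derived panel samples the master records
#' with its coverage probability: a dbSNP-like panel (widest), an
#' EVS-like panel restricted to hemizygous-annotated records, a smaller
#' male-population panel, and a clinical panel holding the records with a
#' pathogenic annotation.
#'
#' @param panel master \code{ReferencePanel}.
#' @param config a \code{\link{simulationConfig}}.
#' @param seed integer seed.
#' @return list of \code{ReferencePanel}s: dbsnp, evs, male1000g,
#'   clinical.
#' @export
simulateFilterPanels <- function(panel, config, seed) {
  set.seed(seed + 2000003L)
  rec <- panelRecords(panel)
  n <- nrow(rec)
  sub <- function(cov, label) {
    ReferencePanel(rec[stats::runif(n) < cov, , drop = FALSE],
                   source = label)
  }
  list(dbsnp = sub(config$dbsnpCoverage, "synthetic-dbsnp"),
       evs = sub(config$evsCoverage, "synthetic-evs"),
       male1000g = sub(config$maleMiniCoverage, "synthetic-male1000g"),
       clinical = ReferencePanel(
         rec[rec$clin_sig %in% c("probable-pathogenic", "pathogenic"), ,
             drop = FALSE], source = "synthetic-clinical"))
}

#' Fixture: a recurrent rare pathogenic variant across unrelated carriers
#'
#' Builds a reduced cohort in which one pathogenic-annotated key with MAF
#' below 1% is planted in two unrelated sporadic samples and in both
#' members of one brother pair (inside their largest shared segment). The
#' key is lost to the cross-cohort rule without clinical rescue and
#' retained in all four carriers with it.
#'
#' @param seed integer seed.
#' @param config optional \code{\link{simulationConfig}}; defaults to a
#'   reduced cohort (6 sporadic + 3 brother pairs, 800 panel sites).
#' @return list with cohort, design, panels, truth, plus \code{key},
#'   \code{keyRow} and \code{carriers} describing the planted variant.
#' @export
simulateRecurrentPathogenicScenario <- function(seed, config = NULL) {
  if (is.null(config))
    config <- simulationConfig(
      nSporadic = 6L, pairRelationships = rep("brothers", 3),
      nPanelVariants = 800L, batchSystematicPerBatch = 2L,
      ancestryOutliers = 0L)
  panel <- simulateReferencePanel(config, seed)
  sim <- simulateCohort(config, panel, seed)
  panels <- simulateFilterPanels(panel, config, seed)
  set.seed(seed + 3000003L)

  pair <- c(designPairs(sim$design)$sample1[1],
            designPairs(sim$design)$sample2[1])
  segs <- sim$truth$segments[[pair[1]]]
  big <- segs[which.max(segs$end - segs$start), ]
  occupied <- sort(unique(unlist(lapply(sim$cohort,
                                        function(cs) calls(cs)$pos))))
  pos <- .drawPositions(1L, big$start + 0.2 * (big$end - big$start),
                        big$end - 0.2 * (big$end - big$start),
                        occupied, minGap = 25L, parMask = config$parMask)
  ref <- .randAllele(1L)
  alt <- .randAlt(ref)
  carriers <- c(designSporadic(sim$design)[1:2], pair)
  for (s in carriers) {
    dd <- .depthDraw(1L, config$meanDepth, forceBoth = TRUE)
    cl <- rbind(calls(sim$cohort[[s]]), data.frame(
      chrom = "X", pos = pos, ref = ref, alt = alt, genotype = 1,
      depth = dd$depth, altFwd = dd$altFwd, altRev = dd$altRev,
      funcClass = "nonsense", stringsAsFactors = FALSE))
    sim$cohort[[s]] <- SampleCallSet(s, cl,
                                     batch = sampleBatch(sim$cohort[[s]]))
  }
  keyRow <- data.frame(chrom = "X", pos = pos, ref = ref, alt = alt,
                       maf = 0.002, clin_sig = "pathogenic",
                       stringsAsFactors = FALSE)
  crec <- panelRecords(panels$clinical)
  panels$clinical <- ReferencePanel(
    rbind(crec[c("chrom", "pos", "ref", "alt", "maf", "clin_sig")],
          keyRow), source = "synthetic-clinical")
  sim$truth$geneMap <- rbind(
    sim$truth$geneMap,
    data.frame(chrom = "X", pos = pos, ref = ref, alt = alt,
               gene_id = sprintf("XG%03d",
                                 findInterval(pos - 1L,
                                              sim$truth$geneBounds,
                                              rightmost.closed = TRUE)),
               func_class = "nonsense", stringsAsFactors = FALSE))
  c(sim, list(panels = panels,
              key = paste("X", pos, ref, alt, sep = ":"),
              keyRow = keyRow, carriers = carriers))
}
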