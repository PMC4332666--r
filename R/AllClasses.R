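#' @import methods
NULL

.CALL_COLUMNS <- c("chrom", "pos", "ref", "alt", "genotype", "depth",
                   "altFwd", "altRev", "funcClass")

.FUNC_CLASSES <- c("nonsense", "frameshift", "splicing", "missense",
                   "synonymous", "intronic", "other")

.CLIN_SIG <- c("none", "probable-pathogenic", "pathogenic", "other")

.DECISIONS <- c("retain", "reject", "rescue")

#' Pseudoautosomal regions of the human X chromosome (hg19)
#'
#' Default interval mask, 0-based half-open coordinates. Calls and panel
#' records falling inside these intervals are excluded from X-specific
#' analyses because both sexes are diploid there.
#'
#' @format A data.frame with columns \code{start} and \code{end}.
#' @export
parMaskHg19 <- data.frame(
  start = c(60000L, 154931043L),
  end   = c(2699520L, 155260560L)
)

# ---- SampleCallSet ---------------------------------------------------------

#' SampleCallSet: haploid variant calls for one male sample
#'
#' Holds the per-sample variant calls the pipeline filters. Each row of
#' \code{calls} is one call with 1-based position, reference and alternate
#' allele, alt-allele copy number (0 or 1 for a valid haploid call; other
#' values are admitted so pathological genotype releases can be audited),
#' total read depth, strand-split alternate read depths and a functional
#' class. Rows are sorted by (chrom, pos, ref, alt) and keys are unique.
#'
#' @slot sampleID single sample identifier.
#' @slot sex sample sex; the pipeline models hemizygous males.
#' @slot batch sequencing-library batch label.
#' @slot calls data.frame with columns chrom, pos, ref, alt, genotype,
#'   depth, altFwd, altRev, funcClass.
#' @export
setClass("SampleCallSet",
  slots = c(sampleID = "character", sex = "character",
            batch = "character", calls = "data.frame"))

setValidity("SampleCallSet", function(object) {
  msg <- character()
  cl <- object@calls
  if (length(object@sampleID) != 1L) msg <- c(msg, "sampleID must be length 1")
  if (!all(.CALL_COLUMNS %in% names(cl)))
    msg <- c(msg, paste("calls must have columns:",
                        paste(.CALL_COLUMNS, collapse = ", ")))
  if (nrow(cl) > 0L && all(.CALL_COLUMNS %in% names(cl))) {
    if (any(cl$pos < 1L)) msg <- c(msg, "pos must be >= 1")
    if (any(cl$ref == cl$alt)) msg <- c(msg, "ref must differ from alt")
    bad <- !is.na(cl$altFwd) & !is.na(cl$altRev) &
      (cl$altFwd < 0L | cl$altRev < 0L | cl$depth < cl$altFwd + cl$altRev)
    if (any(bad)) msg <- c(msg, "need depth >= altFwd + altRev >= 0")
    key <- paste(cl$chrom, cl$pos, cl$ref, cl$alt)
    if (anyDuplicated(key)) msg <- c(msg, "duplicate (chrom,pos,ref,alt) keys")
    if (is.unsorted(order(cl$chrom, cl$pos, cl$ref, cl$alt)))
      msg <- c(msg, "calls must be sorted")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SampleCallSet
#'
#' Sorts the calls by (chrom, pos, ref, alt), fills optional columns with
#' defaults and validates the haploid-call invariants. Duplicate variant
#' keys within the sample are an error.
#'
#' @param sampleID sample identifier.
#' @param calls data.frame of calls; \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt} are required, remaining columns default to genotype 1,
#'   depth/strand depths NA and funcClass "other".
#' @param sex sample sex (default "male").
#' @param batch library batch label (default "batch1").
#' @return A \code{SampleCallSet}.
#' @export
SampleCallSet <- function(sampleID, calls, sex = "male", batch = "batch1") {
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  if (nrow(calls) == 0L && length(names(calls)) == 0L)
    calls <- data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character())
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(calls)))
  if (is.null(calls$genotype)) calls$genotype <- rep(1, nrow(calls))
  if (is.null(calls$depth)) calls$depth <- rep(NA_integer_, nrow(calls))
  if (is.null(calls$altFwd)) calls$altFwd <- rep(NA_integer_, nrow(calls))
  if (is.null(calls$altRev)) calls$altRev <- rep(NA_integer_, nrow(calls))
  if (is.null(calls$funcClass)) calls$funcClass <- rep("other", nrow(calls))
  calls$chrom <- as.character(calls$chrom)
  calls$pos <- as.integer(calls$pos)
  calls$ref <- as.character(calls$ref)
  calls$alt <- as.character(calls$alt)
  calls <- calls[.CALL_COLUMNS]
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt)
  if (anyDuplicated(key))
    stop("duplicate variant key(s) in sample '", sampleID, "': ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  o <- order(calls$chrom, calls$pos, calls$ref, calls$alt)
  calls <- calls[o, , drop = FALSE]
  rownames(calls) <- NULL
  new("SampleCallSet", sampleID = as.character(sampleID),
      sex = sex, batch = batch, calls = calls)
}

# ---- CohortDesign ----------------------------------------------------------

#' CohortDesign: sample roster with declared kindred pairings
#'
#' Declares which samples form affected relative pairs (brothers,
#' half-brothers, cousins, uncle-nephew) and which are sporadic cases.
#' Every sample belongs to exactly one pair or to the sporadic group.
#'
#' @slot samples data.frame with columns sample_id, sex, batch.
#' @slot pairs data.frame with columns sample1, sample2, relationship.
#' @slot sporadic character vector of sporadic sample ids.
#' @export
setClass("CohortDesign",
  slots = c(samples = "data.frame", pairs = "data.frame",
            sporadic = "character"))

setValidity("CohortDesign", function(object) {
  msg <- character()
  p <- object@pairs
  if (!all(c("sample1", "sample2", "relationship") %in% names(p)))
    msg <- c(msg, "pairs needs columns sample1, sample2, relationship")
  else {
    if (any(p$sample1 == p$sample2)) msg <- c(msg, "pair members must differ")
    declared <- c(p$sample1, p$sample2, object@sporadic)
    if (anyDuplicated(declared))
      msg <- c(msg, "each sample may appear in exactly one pair or sporadic")
    if (!setequal(declared, object@samples$sample_id))
      msg <- c(msg, "pairs/sporadic must partition the sample roster")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CohortDesign
#'
#' @param samples data.frame with columns sample_id and optionally sex,
#'   batch (defaults "male", "batch1").
#' @param pairs data.frame with columns sample1, sample2, relationship
#'   (zero rows allowed).
#' @param sporadic character vector of unpaired sample ids.
#' @return A \code{CohortDesign}.
#' @export
CohortDesign <- function(samples, pairs = NULL, sporadic = character()) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(samples$sex)) samples$sex <- "male"
  if (is.null(samples$batch)) samples$batch <- "batch1"
  if (is.null(pairs) || nrow(as.data.frame(pairs)) == 0L)
    pairs <- data.frame(sample1 = character(), sample2 = character(),
                        relationship = character())
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  new("CohortDesign", samples = samples, pairs = pairs,
      sporadic = as.character(sporadic))
}

# ---- ReferencePanel --------------------------------------------------------

#' ReferencePanel: population variant table used as a subtraction filter
#'
#' Emulates the reference variant resources the pipeline subtracts:
#' a dbSNP-like table with clinical-significance codes and allele counts,
#' a population VCF with sex-resolved carrier counts, or an EVS-like table
#' with hemizygous-male annotations. Record keys are unique.
#'
#' @slot records data.frame keyed by (chrom, pos, ref, alt) with columns
#'   maf, allele_count, male_carrier_count, female_only,
#'   hemizygous_annotated, clin_sig and optional population frequency
#'   columns freq_popA / freq_popB.
#' @slot source free-text label for the panel origin.
#' @slot nMaleChr number of male X chromosomes behind the panel.
#' @slot nFemaleInd number of female individuals behind the panel.
#' @export
setClass("ReferencePanel",
  slots = c(records = "data.frame", source = "character",
            nMaleChr = "integer", nFemaleInd = "integer"))

setValidity("ReferencePanel", function(object) {
  msg <- character()
  r <- object@records
  need <- c("chrom", "pos", "ref", "alt", "maf")
  if (!all(need %in% names(r)))
    msg <- c(msg, paste("records needs columns:", paste(need, collapse = ", ")))
  else if (nrow(r) > 0L) {
    if (anyDuplicated(paste(r$chrom, r$pos, r$ref, r$alt)))
      msg <- c(msg, "duplicate panel keys")
    if (any(r$maf < 0 | r$maf > 1, na.rm = TRUE))
      msg <- c(msg, "maf must lie in [0,1]")
    ok <- is.na(r$allele_count) | is.na(r$male_carrier_count) |
      r$allele_count >= r$male_carrier_count
    if (!all(ok)) msg <- c(msg, "allele_count must be >= male_carrier_count")
    if (!all(r$clin_sig %in% .CLIN_SIG))
      msg <- c(msg, paste("clin_sig must be one of:",
                          paste(.CLIN_SIG, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ReferencePanel
#'
#' @param records data.frame with at least chrom, pos, ref, alt, maf;
#'   missing optional columns are filled with NA / "none".
#' @param source label for the panel origin.
#' @param nMaleChr male X chromosomes behind the panel (default 525, the
#'   male complement of the 1000 Genomes Phase 1 release).
#' @param nFemaleInd female individuals behind the panel (default 567).
#' @return A \code{ReferencePanel}.
#' @export
ReferencePanel <- function(records, source = "panel",
                           nMaleChr = 525L, nFemaleInd = 567L) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) == 0L && length(names(records)) == 0L)
    records <- data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          maf = numeric())
  n <- nrow(records)
  if (is.null(records$allele_count))
    records$allele_count <- rep(NA_integer_, n)
  if (is.null(records$male_carrier_count))
    records$male_carrier_count <- rep(NA_integer_, n)
  if (is.null(records$female_only)) records$female_only <- rep(NA, n)
  if (is.null(records$hemizygous_annotated))
    records$hemizygous_annotated <- rep(NA, n)
  if (is.null(records$clin_sig)) records$clin_sig <- rep("none", n)
  records$pos <- as.integer(records$pos)
  rownames(records) <- NULL
  new("ReferencePanel", records = records, source = source,
      nMaleChr = as.integer(nMaleChr), nFemaleInd = as.integer(nFemaleInd))
}

# ---- FilterLedger ----------------------------------------------------------

#' FilterLedger: per-variant, per-sample provenance of filter decisions
#'
#' Records one row per (sample, variant, stage) with the terminal decision
#' at that stage: retain, reject, or rescue, plus a reason code. The ledger
#' is the audit trail from which stage-by-stage reduction reports are
#' reconstructed.
#'
#' @slot entries data.frame with columns sample_id, chrom, pos, ref, alt,
#'   stage, decision, reason.
#' @export
setClass("FilterLedger", slots = c(entries = "data.frame"))

setValidity("FilterLedger", function(object) {
  e <- object@entries
  need <- c("sample_id", "chrom", "pos", "ref", "alt",
            "stage", "decision", "reason")
  msg <- character()
  if (!all(need %in% names(e)))
    msg <- c(msg, paste("entries needs columns:", paste(need, collapse = ", ")))
  else if (nrow(e) > 0L) {
    if (!all(e$decision %in% .DECISIONS))
      msg <- c(msg, "decision must be retain, reject or rescue")
    if (anyDuplicated(paste(e$sample_id, e$chrom, e$pos, e$ref, e$alt, e$stage)))
      msg <- c(msg, "one terminal decision per (sample, variant, stage)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FilterLedger
#'
#' @param entries data.frame of ledger rows (may be empty).
#' @return A \code{FilterLedger}.
#' @export
FilterLedger <- function(entries = NULL) {
  if (is.null(entries) || nrow(as.data.frame(entries)) == 0L)
    entries <- data.frame(sample_id = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character(), stage = character(),
                          decision = character(), reason = character())
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  rownames(entries) <- NULL
  new("FilterLedger", entries = entries)
}
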