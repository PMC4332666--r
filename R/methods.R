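# Accessors and show methods for the core classes.

#' Variant key strings
#'
#' Builds the canonical "chrom:pos:ref:alt" key used throughout the
#' pipeline to match variants across samples and panels.
#'
#' @param df data.frame with columns chrom, pos, ref, alt.
#' @return character vector of keys.
#' @export
variantKey <- function(df)
  paste(df$chrom, as.integer(df$pos), df$ref, df$alt, sep = ":")

#' @rdname SampleCallSet-class
#' @export
setMethod("sampleID", "SampleCallSet", function(x) x@sampleID)

#' @rdname SampleCallSet-class
#' @export
setMethod("calls", "SampleCallSet", function(x) x@calls)

#' @rdname SampleCallSet-class
#' @export
setMethod("nCalls", "SampleCallSet", function(x) nrow(x@calls))

#' @rdname SampleCallSet-class
#' @export
setMethod("variantKeys", "SampleCallSet", function(x) variantKey(x@calls))

#' @rdname SampleCallSet-class
#' @export
setMethod("sampleBatch", "SampleCallSet", function(x) x@batch)

setMethod("show", "SampleCallSet", function(object) {
  cat("SampleCallSet for", object@sampleID,
      "(", object@sex, ", batch", object@batch, ")\n")
  cat(" ", nrow(object@calls), "haploid calls on",
      paste(unique(object@calls$chrom), collapse = ","), "\n")
  if (nrow(object@calls))
    cat("  positions", min(object@calls$pos), "-", max(object@calls$pos), "\n")
})

#' @rdname CohortDesign-class
#' @export
setMethod("designSamples", "CohortDesign", function(x) x@samples)

#' @rdname CohortDesign-class
#' @export
setMethod("designPairs", "CohortDesign", function(x) x@pairs)

#' @rdname CohortDesign-class
#' @export
setMethod("designSporadic", "CohortDesign", function(x) x@sporadic)

setMethod("show", "CohortDesign", function(object) {
  cat("CohortDesign:", nrow(object@samples), "samples;",
      nrow(object@pairs), "kindred pairs;",
      length(object@sporadic), "sporadic cases\n")
  if (nrow(object@pairs))
    print(table(object@pairs$relationship))
})

#' Declared kin lookup
#'
#' @param design a \code{CohortDesign}.
#' @return named character vector mapping each paired sample to its kin.
#' @export
kinOf <- function(design) {
  p <- designPairs(design)
  stats::setNames(c(p$sample2, p$sample1), c(p$sample1, p$sample2))
}

#' @rdname ReferencePanel-class
#' @export
setMethod("panelRecords", "ReferencePanel", function(x) x@records)

#' @rdname ReferencePanel-class
#' @export
setMethod("panelKeys", "ReferencePanel", function(x) variantKey(x@records))

setMethod("show", "ReferencePanel", function(object) {
  cat("ReferencePanel '", object@source, "': ",
      nrow(object@records), " records (",
      object@nMaleChr, " male chr, ",
      object@nFemaleInd, " female individuals)\n", sep = "")
  cs <- table(object@records$clin_sig)
  if (length(cs)) print(cs)
})

#' @rdname FilterLedger-class
#' @export
setMethod("ledgerEntries", "FilterLedger", function(x) x@entries)

setMethod("show", "FilterLedger", function(object) {
  e <- object@entries
  cat("FilterLedger:", nrow(e), "entries\n")
  if (nrow(e)) print(table(e$stage, e$decision))
})

#' Append entries to a ledger
#'
#' @param ledger a \code{FilterLedger}.
#' @param entries data.frame of new ledger rows.
#' @return a new \code{FilterLedger}.
#' @export
appendLedger <- function(ledger, entries) {
  FilterLedger(rbind(ledgerEntries(ledger),
                     entries[names(ledgerEntries(ledger))]))
}

# internal: make ledger entry rows for one sample
.ledgerRows <- function(sampleID, cl, stage, decision, reason) {
  if (nrow(cl) == 0L)
    return(data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      stage = character(), decision = character(),
                      reason = character()))
  data.frame(sample_id = sampleID, chrom = cl$chrom, pos = cl$pos,
             ref = cl$ref, alt = cl$alt, stage = stage,
             decision = decision, reason = reason,
             stringsAsFactors = FALSE)
}

# internal: replace the calls of a SampleCallSet, keeping metadata
.withCalls <- function(x, cl) {
  rownames(cl) <- NULL
  methods::initialize(x, calls = cl)
}
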