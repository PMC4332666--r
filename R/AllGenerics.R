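#' @rdname SampleCallSet-class
#' @param object,x an object.
#' @export
setGeneric("sampleID", function(x) standardGeneric("sampleID"))

#' @rdname SampleCallSet-class
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname SampleCallSet-class
#' @export
setGeneric("nCalls", function(x) standardGeneric("nCalls"))

#' @rdname SampleCallSet-class
#' @export
setGeneric("variantKeys", function(x) standardGeneric("variantKeys"))

#' @rdname SampleCallSet-class
#' @export
setGeneric("sampleBatch", function(x) standardGeneric("sampleBatch"))

#' @rdname CohortDesign-class
#' @export
setGeneric("designSamples", function(x) standardGeneric("designSamples"))

#' @rdname CohortDesign-class
#' @export
setGeneric("designPairs", function(x) standardGeneric("designPairs"))

#' @rdname CohortDesign-class
#' @export
setGeneric("designSporadic", function(x) standardGeneric("designSporadic"))

#' @rdname ReferencePanel-class
#' @export
setGeneric("panelRecords", function(x) standardGeneric("panelRecords"))

#' @rdname ReferencePanel-class
#' @export
setGeneric("panelKeys", function(x) standardGeneric("panelKeys"))

#' @rdname FilterLedger-class
#' @export
setGeneric("ledgerEntries", function(x) standardGeneric("ledgerEntries"))
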