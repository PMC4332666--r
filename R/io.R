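#' @importClassesFrom vcfR vcfR
NULL

# VCF, TSV and BED input/output.
#
# The VCF dialect: per-sample GT (haploid allele index) and DP, with
# strand-split alternate-allele depths in the FORMAT fields ADF/ADR
# (configurable; Number=A, one value per alt allele). The functional class
# travels in an INFO key (default FUNC). Multi-allelic records are split
# into biallelic calls on read because all matching is keyed on
# (chrom, pos, ref, alt).

.VCF_META <- function(chromLength = 155270560) c(
  "##fileformat=VCFv4.2",
  sprintf("##contig=<ID=X,length=%d>", chromLength),
  "##INFO=<ID=FUNC,Number=1,Type=String,Description=\"Functional class\">",
  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
  "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
  "##FORMAT=<ID=ADF,Number=A,Type=Integer,Description=\"Alt forward-strand depth\">",
  "##FORMAT=<ID=ADR,Number=A,Type=Integer,Description=\"Alt reverse-strand depth\">")

.parseInfoKey <- function(info, key) {
  hit <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
  out <- rep(NA_character_, length(info))
  found <- lengths(regmatches(info, gregexpr(paste0("(^|;)", key, "="), info))) > 0
  out[found] <- sub(paste0("^;?", key, "="), "",
                    regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info)))
  out
}

#' Read one sample's haploid calls from a VCF
#'
#' Parses GT as the alt-allele copy number (haploid allele index), DP as
#' total depth, and the strand-split alternate depths from a configurable
#' FORMAT field pair. Multi-allelic records are split into biallelic calls;
#' reference (genotype 0) and missing calls are dropped. A sidecar TSV of
#' pos, altFwd, altRev may replace the FORMAT fields.
#'
#' @param path VCF file (plain or bgzipped).
#' @param sampleID sample column to read.
#' @param strandFields length-2 character: FORMAT keys for forward/reverse
#'   alternate depths (default ADF, ADR).
#' @param funcKey INFO key holding the functional class (default FUNC);
#'   calls without it get "other".
#' @param strandSidecar optional TSV path with columns pos, altFwd, altRev.
#' @param parMask data.frame of half-open intervals to exclude (default
#'   \code{parMaskHg19}); use NULL to keep pseudoautosomal calls.
#' @return A \code{SampleCallSet}.
#' @export
readSampleVcf <- function(path, sampleID,
                          strandFields = c("ADF", "ADR"),
                          funcKey = "FUNC",
                          strandSidecar = NULL,
                          parMask = parMaskHg19) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e)))
  fix <- v@fix
  if (nrow(fix) == 0L)
    return(SampleCallSet(sampleID, data.frame()))
  scols <- colnames(v@gt)
  if (!(sampleID %in% scols))
    stop("sample '", sampleID, "' not present in ", path,
         " (has: ", paste(setdiff(scols, "FORMAT"), collapse = ", "), ")")
  fmt <- strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)
  val <- strsplit(v@gt[, sampleID], ":", fixed = TRUE)
  pull <- function(keyname) {
    mapply(function(f, x) {
      i <- match(keyname, f)
      if (is.na(i) || i > length(x)) NA_character_ else x[[i]]
    }, fmt, val, USE.NAMES = FALSE)
  }
  gt <- pull("GT")
  dp <- suppressWarnings(as.integer(pull("DP")))
  adf <- pull(strandFields[1])
  adr <- pull(strandFields[2])
  info <- fix[, "INFO"]
  func <- .parseInfoKey(ifelse(is.na(info), "", info), funcKey)
  func[is.na(func) | !(func %in% .FUNC_CLASSES)] <- "other"

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    adfv <- suppressWarnings(as.integer(strsplit(
      ifelse(is.na(adf[i]), "", adf[i]), ",", fixed = TRUE)[[1]]))
    adrv <- suppressWarnings(as.integer(strsplit(
      ifelse(is.na(adr[i]), "", adr[i]), ",", fixed = TRUE)[[1]]))
    gi <- suppressWarnings(as.numeric(gt[i]))
    if (is.na(gi) || gi == 0) next
    ai <- as.integer(gi)
    if (!is.na(ai) && ai >= 1 && ai <= length(alts) && gi == ai) {
      rows[[i]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[ai], genotype = 1,
        depth = dp[i],
        altFwd = if (ai <= length(adfv)) adfv[ai] else NA_integer_,
        altRev = if (ai <= length(adrv)) adrv[ai] else NA_integer_,
        funcClass = func[i], stringsAsFactors = FALSE)
    } else {
      # ambiguous genotype (non-integer or out of allele range): keep the
      # raw copy number against the first alt so it can be audited
      rows[[i]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[1], genotype = gi,
        depth = dp[i],
        altFwd = if (length(adfv)) adfv[1] else NA_integer_,
        altRev = if (length(adrv)) adrv[1] else NA_integer_,
        funcClass = func[i], stringsAsFactors = FALSE)
    }
  }
  cl <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(cl)) cl <- data.frame()
  if (!is.null(strandSidecar) && nrow(cl)) {
    sc <- utils::read.delim(strandSidecar, stringsAsFactors = FALSE)
    i <- match(cl$pos, sc$pos)
    cl$altFwd <- sc$altFwd[i]
    cl$altRev <- sc$altRev[i]
  }
  if (!is.null(parMask) && nrow(cl)) {
    inPar <- rep(FALSE, nrow(cl))
    for (j in seq_len(nrow(parMask)))
      inPar <- inPar | (cl$pos - 1L >= parMask$start[j] &
                        cl$pos - 1L < parMask$end[j])
    cl <- cl[!inPar, , drop = FALSE]
  }
  SampleCallSet(sampleID, cl)
}

#' Write a SampleCallSet to VCF
#'
#' Emits one record per call with GT/DP/ADF/ADR FORMAT fields and the
#' functional class in INFO. A write-then-read round trip reproduces the
#' call collection exactly.
#'
#' @param callset a \code{SampleCallSet}.
#' @param path output path; vcfR compresses, so use a ".vcf.gz" suffix.
#' @param chromLength contig length for the header.
#' @return invisibly, the path written.
#' @export
writeSampleVcf <- function(callset, path, chromLength = 155270560) {
  cl <- calls(callset)
  fix <- matrix(NA_character_, nrow = nrow(cl), ncol = 8,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER", "INFO")))
  gt <- matrix(NA_character_, nrow = nrow(cl), ncol = 2,
               dimnames = list(NULL, c("FORMAT", sampleID(callset))))
  if (nrow(cl)) {
    fix[, "CHROM"] <- cl$chrom
    fix[, "POS"] <- as.character(cl$pos)
    fix[, "REF"] <- cl$ref
    fix[, "ALT"] <- cl$alt
    fix[, "INFO"] <- paste0("FUNC=", cl$funcClass)
    gt[, "FORMAT"] <- "GT:DP:ADF:ADR"
    fmtNum <- function(x) ifelse(is.na(x), ".", as.character(x))
    gt[, 2] <- paste(fmtNum(cl$genotype), fmtNum(cl$depth),
                     fmtNum(cl$altFwd), fmtNum(cl$altRev), sep = ":")
  }
  v <- methods::new("vcfR", meta = .VCF_META(chromLength), fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Write filtered outputs for one sample
#'
#' Emits the retained calls as VCF plus the sample's ledger slice as TSV.
#' The ledger must cover every call of the input callset.
#'
#' @param callset the retained \code{SampleCallSet}.
#' @param ledger a \code{FilterLedger} covering the sample.
#' @param dir output directory (created if missing).
#' @return invisibly, named character vector of written paths.
#' @export
writeOutputs <- function(callset, ledger, dir) {
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  vcf <- file.path(dir, paste0(sampleID(callset), ".filtered.vcf.gz"))
  led <- file.path(dir, paste0(sampleID(callset), ".ledger.tsv"))
  writeSampleVcf(callset, vcf)
  e <- ledgerEntries(ledger)
  writeLedgerTsv(FilterLedger(e[e$sample_id == sampleID(callset), ,
                                drop = FALSE]), led)
  invisible(c(vcf = vcf, ledger = led))
}

#' Write / read a ledger as TSV
#'
#' @param ledger a \code{FilterLedger}.
#' @param path TSV path.
#' @return \code{writeLedgerTsv}: invisibly the path;
#'   \code{readLedgerTsv}: a \code{FilterLedger}.
#' @export
writeLedgerTsv <- function(ledger, path) {
  utils::write.table(ledgerEntries(ledger), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLedgerTsv
#' @export
readLedgerTsv <- function(path) {
  FilterLedger(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Read / write a cohort design table
#'
#' TSV with columns sample_id, kin_id (or "-"), relationship (or "-") and
#' batch; one row per sample.
#'
#' @param path TSV path.
#' @param design a \code{CohortDesign}.
#' @return \code{readDesignTsv}: a \code{CohortDesign}.
#' @export
readDesignTsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  paired <- d$kin_id != "-"
  seen <- character()
  p1 <- character(); p2 <- character(); rel <- character()
  for (i in which(paired)) {
    if (d$sample_id[i] %in% seen) next
    p1 <- c(p1, d$sample_id[i]); p2 <- c(p2, d$kin_id[i])
    rel <- c(rel, d$relationship[i])
    seen <- c(seen, d$sample_id[i], d$kin_id[i])
  }
  CohortDesign(
    samples = data.frame(sample_id = d$sample_id, sex = "male",
                         batch = d$batch, stringsAsFactors = FALSE),
    pairs = data.frame(sample1 = p1, sample2 = p2, relationship = rel,
                       stringsAsFactors = FALSE),
    sporadic = d$sample_id[!paired])
}

#' @rdname readDesignTsv
#' @export
writeDesignTsv <- function(design, path) {
  s <- designSamples(design)
  kin <- kinOf(design)
  p <- designPairs(design)
  relOf <- stats::setNames(c(p$relationship, p$relationship),
                           c(p$sample1, p$sample2))
  out <- data.frame(
    sample_id = s$sample_id,
    kin_id = ifelse(s$sample_id %in% names(kin), kin[s$sample_id], "-"),
    relationship = ifelse(s$sample_id %in% names(relOf),
                          relOf[s$sample_id], "-"),
    batch = s$batch, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a reference panel as TSV
#'
#' @param path TSV path.
#' @param panel a \code{ReferencePanel}.
#' @param source,nMaleChr,nFemaleInd panel metadata for reading.
#' @return \code{readPanelTsv}: a \code{ReferencePanel}.
#' @export
readPanelTsv <- function(path, source = "panel",
                         nMaleChr = 525L, nFemaleInd = 567L) {
  ReferencePanel(utils::read.delim(path, stringsAsFactors = FALSE),
                 source = source, nMaleChr = nMaleChr,
                 nFemaleInd = nFemaleInd)
}

#' @rdname readPanelTsv
#' @export
writePanelTsv <- function(panel, path) {
  utils::write.table(panelRecords(panel), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write half-open intervals as BED
#'
#' BED3 on the X chromosome; start is 0-based inclusive, end exclusive.
#'
#' @param path BED path.
#' @param intervals data.frame with columns start, end (chrom optional).
#' @param chrom chromosome name for writing.
#' @return \code{readBed}: data.frame with chrom, start, end.
#' @export
readBed <- function(path) {
  b <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(b)[1:3] <- c("chrom", "start", "end")
  b[1:3]
}

#' @rdname readBed
#' @export
writeBed <- function(intervals, path, chrom = "X") {
  b <- data.frame(chrom = if (is.null(intervals$chrom)) chrom
                  else intervals$chrom,
                  start = intervals$start, end = intervals$end)
  utils::write.table(b, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- genotype audit and array concordance ---------------------------------

#' Audit genotype copy-numbers for ploidy consistency
#'
#' Classifies every non-zero genotype into exactly-1, exactly-2, or
#' ambiguous (any non-integer or any value outside {1, 2}). On a haploid
#' male X chromosome only 0/1 are legitimate, so both the exactly-2 and the
#' ambiguous fractions flag pathologies of a release; the classification
#' itself is ploidy-agnostic and interpretation is the caller's.
#'
#' @param genotypes numeric vector of alt-allele copy numbers.
#' @param expectedPloidy 1 or 2; recorded in the result for interpretation.
#' @return list with nNonzero, fracOne, fracTwo, fracAmbiguous,
#'   expectedPloidy. Fractions sum to 1 over non-zero calls.
#' @export
auditGenotypePloidy <- function(genotypes, expectedPloidy = 1L) {
  stopifnot(expectedPloidy %in% c(1L, 2L))
  g <- genotypes[!is.na(genotypes) & genotypes != 0]
  if (length(g) == 0L)
    stop("genotype audit undefined: all genotypes are zero")
  one <- g == 1
  two <- g == 2
  list(nNonzero = length(g),
       fracOne = mean(one),
       fracTwo = mean(two),
       fracAmbiguous = mean(!one & !two),
       expectedPloidy = as.integer(expectedPloidy))
}

#' Concordance between sequencing calls and array genotypes
#'
#' Fraction of positions present in both inputs where the genotypes agree.
#'
#' @param callset a \code{SampleCallSet}.
#' @param arrayGenotypes data.frame with columns pos, genotype.
#' @return fraction in [0, 1].
#' @export
genotypeConcordance <- function(callset, arrayGenotypes) {
  cl <- calls(callset)
  i <- match(arrayGenotypes$pos, cl$pos)
  keep <- !is.na(i)
  if (!any(keep))
    stop("concordance undefined: no overlapping positions")
  mean(arrayGenotypes$genotype[keep] == cl$genotype[i[keep]])
}
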