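# Read cleaning: FASTQ parsing, 3' adapter trimming, whole-read quality
# and length filters, and collapsing to unique tags.

#' Read a small RNA FASTQ file
#'
#' Parses a (plain or gzipped) Phred-scored FASTQ into a data.frame of
#' id / sequence / quality. Lowercase bases are uppercased; characters
#' outside A, C, G, T, N are a format error.
#'
#' @param path FASTQ path.
#' @return data.frame with columns id, sequence, quality.
#' @export
readSmallRnaFastq <- function(path) {
    # the QualityScaledDNAStringSet constructor warns that it drops the
    # mcols readDNAStringSet attaches for FASTQ input; that is expected
    x <- withCallingHandlers(
        Biostrings::readQualityScaledDNAStringSet(path),
        warning = function(w) {
            if (grepl("metadata columns", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
    seqs <- toupper(as.character(x))
    if (any(grepl("[^ACGTN]", seqs)))
        stop("FASTQ contains characters outside A, C, G, T, N")
    data.frame(id = names(x), sequence = unname(seqs),
               quality = unname(as.character(Biostrings::quality(x))),
               stringsAsFactors = FALSE)
}

#' Trim 3' adapters
#'
#' Removes the longest read suffix that matches a prefix of the adapter
#' with at least `minOverlap` nt of overlap and at most one substitution
#' per 7 nt of overlap (integer division, so a 10 nt overlap tolerates
#' one substitution). Qualities are trimmed alongside. Reads whose whole
#' sequence is adapter are flagged as adapter dimers
#' (adapter-to-adapter ligation products); reads with no recognizable
#' adapter pass through unchanged, flagged `no_adapter` (the length
#' filter removes them downstream if they are read-through artifacts).
#'
#' @param reads data.frame with sequence and quality columns (as from
#'   [readSmallRnaFastq()]).
#' @param adapter non-empty adapter sequence.
#' @param minOverlap minimum adapter overlap, nt.
#' @return the input data.frame with sequence/quality trimmed and a new
#'   `adapterFlag` column: one of "trimmed", "dimer", "no_adapter".
#' @export
trimAdapter <- function(reads, adapter, minOverlap = 6L) {
    if (!nzchar(adapter)) stop("adapter must be non-empty")
    pos <- locate_adapter_cpp(reads$sequence, toupper(adapter),
                              as.integer(minOverlap), 7L)
    flag <- ifelse(pos < 0L, "no_adapter",
                   ifelse(pos == 0L, "dimer", "trimmed"))
    keepLen <- ifelse(pos < 0L, nchar(reads$sequence), pos)
    reads$sequence <- substr(reads$sequence, 1L, keepLen)
    reads$quality <- substr(reads$quality, 1L, keepLen)
    reads$adapterFlag <- flag
    reads
}

#' Whole-read quality filter
#'
#' Rejects a read when its sequence contains an ambiguous base (N), when
#' more than 4 bases have quality below 10, or when more than 6 bases
#' have quality in the 10-12 band. The two thresholds count disjoint
#' quality bands, so a read sitting exactly at both limits (4 bases at
#' Q9 plus 6 bases at Q12) still passes. No base-level trimming is done:
#' the read is accepted or rejected whole.
#'
#' @param reads data.frame with sequence and quality columns.
#' @param offset Phred offset (33 for Phred+33, 64 for legacy Phred+64).
#' @return character vector per read: "pass", "contains_N",
#'   "low_quality_q10" or "low_quality_q13".
#' @export
qualityFilter <- function(reads, offset = 33L) {
    if (nrow(reads) == 0L) return(character(0))
    if (any(nchar(reads$sequence) != nchar(reads$quality)))
        stop("sequence and quality strings differ in length")
    tal <- quality_tally_cpp(reads$sequence, reads$quality,
                             as.integer(offset), 10L, 13L)
    n10 <- tal[, 1L]
    band13 <- tal[, 2L] - tal[, 1L]
    ifelse(tal[, 3L] == 1L, "contains_N",
           ifelse(n10 > 4L, "low_quality_q10",
                  ifelse(band13 > 6L, "low_quality_q13", "pass")))
}

#' Insert length filter
#'
#' Keeps trimmed reads of 16-30 nt inclusive.
#'
#' @param sequences character vector of trimmed read sequences.
#' @return logical vector, TRUE for reads inside the window.
#' @export
lengthFilter <- function(sequences) {
    w <- nchar(sequences)
    w >= 16L & w <= 30L
}

#' Collapse clean reads to unique tags
#'
#' One tag per distinct sequence with the number of reads collapsed into
#' it; the read total is conserved exactly. Tags come back sorted by
#' descending count, then lexicographically.
#'
#' @param sequences character vector of clean read sequences.
#' @return a [SmallRNATagSet-class].
#' @export
collapseTags <- function(sequences) {
    SmallRNATagSet(sequences)
}

#' Run the full read QC stage
#'
#' Adapter trimming, then the N/quality filter, then the 16-30 nt length
#' filter (adapter dimers are tallied separately), then tag collapsing.
#'
#' @param reads data.frame from [readSmallRnaFastq()], or a FASTQ path.
#' @param adapter 3' adapter sequence.
#' @param offset Phred offset.
#' @return list with elements `tags` (a [SmallRNATagSet-class]) and
#'   `report` (a [QcReport-class]).
#' @examples
#' fq <- data.frame(id = "r1",
#'                  sequence = paste0(strrep("ACGT", 5), "TGGAATTCTCGGG"),
#'                  quality = strrep("I", 33))
#' runReadQc(fq, adapter = "TGGAATTCTCGGGTGCCAAGG")
#' @export
runReadQc <- function(reads, adapter = "TGGAATTCTCGGGTGCCAAGG",
                      offset = 33L) {
    if (is.character(reads) && length(reads) == 1L)
        reads <- readSmallRnaFastq(reads)
    raw <- nrow(reads)
    reads <- trimAdapter(reads, adapter)
    qual <- qualityFilter(reads, offset)
    isDimer <- reads$adapterFlag == "dimer"
    lenOk <- lengthFilter(reads$sequence)
    rej <- c(adapter_dimer = sum(isDimer & qual == "pass"),
             contains_N = sum(qual == "contains_N"),
             low_quality_q10 = sum(qual == "low_quality_q10"),
             low_quality_q13 = sum(qual == "low_quality_q13"),
             length = sum(qual == "pass" & !isDimer & !lenOk))
    keep <- qual == "pass" & !isDimer & lenOk
    clean <- reads$sequence[keep]
    tags <- collapseTags(clean)
    hist <- tabulate(nchar(clean) - 15L, nbins = 15L)
    names(hist) <- as.character(16:30)
    report <- new("QcReport", rawReads = as.integer(raw),
                  cleanReads = as.integer(sum(keep)),
                  uniqueTags = length(tags),
                  rejections = setNames(as.integer(rej), names(rej)),
                  lengthHistogram = setNames(as.integer(hist),
                                             names(hist)))
    list(tags = tags, report = report)
}

#' Write collapsed tags as FASTA
#'
#' Headers follow the `>tag{id}_x{count}` convention common for
#' collapsed small RNA sets.
#'
#' @param tags a [SmallRNATagSet-class].
#' @param path output path.
#' @export
writeTagFasta <- function(tags, path) {
    writeLines(paste0(">", tagId(tags), "_x", tagCount(tags), "\n",
                      tagSequence(tags)), path)
    invisible(path)
}
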