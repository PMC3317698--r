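#' Collapsed small RNA tags
#'
#' A set of unique small RNA sequences ("tags") with the number of clean
#' reads collapsed into each. Tags are the pipeline's atomic unit: every
#' annotation, conserved-miRNA and hairpin-discovery step operates on
#' tags, never on raw reads. Tags are kept sorted by descending count and
#' then lexicographically by sequence, so a tag set built from the same
#' reads is always ordered identically.
#'
#' @slot sequence character, uppercase ACGT, 16-30 nt.
#' @slot count integer, reads collapsed into each tag (>= 1).
#' @slot id character, stable tag identifiers ("tag1", "tag2", ...)
#'   assigned in sort order.
#'
#' @examples
#' ts <- SmallRNATagSet(c("ACGTACGTACGTACGTA", "ACGTACGTACGTACGTA",
#'                        "TGCATGCATGCATGCA"))
#' tagCount(ts)
#' @export
setClass("SmallRNATagSet",
         representation(sequence = "character", count = "integer",
                        id = "character"))

setValidity("SmallRNATagSet", function(object) {
    n <- length(object@sequence)
    if (length(object@count) != n || length(object@id) != n)
        return("sequence, count and id must have equal length")
    if (n == 0L) return(TRUE)
    if (anyDuplicated(object@sequence))
        return("tag sequences must be unique")
    w <- nchar(object@sequence)
    if (any(w < 16L | w > 30L))
        return("tag lengths must be within 16-30 nt")
    if (any(grepl("[^ACGT]", object@sequence)))
        return("tags must contain only A, C, G, T")
    if (any(object@count < 1L))
        return("tag counts must be >= 1")
    TRUE
})

#' @param reads character vector of clean read sequences (or tag
#'   sequences with `counts` supplied).
#' @param counts optional integer vector of pre-computed counts, one per
#'   element of `reads`; identical sequences are merged either way.
#' @rdname SmallRNATagSet-class
#' @export
SmallRNATagSet <- function(reads = character(0), counts = NULL) {
    if (is.null(counts)) counts <- rep(1L, length(reads))
    stopifnot(length(counts) == length(reads))
    if (length(reads) == 0L)
        return(new("SmallRNATagSet", sequence = character(0),
                   count = integer(0), id = character(0)))
    agg <- rowsum(as.integer(counts), group = reads, reorder = FALSE)
    seqs <- rownames(agg)
    cnts <- as.integer(agg[, 1L])
    o <- order(-cnts, seqs)
    new("SmallRNATagSet", sequence = seqs[o], count = cnts[o],
        id = paste0("tag", seq_along(o)))
}

#' @param x,object a `SmallRNATagSet`.
#' @rdname SmallRNATagSet-class
#' @export
tagSequence <- function(x) x@sequence

#' @rdname SmallRNATagSet-class
#' @export
tagCount <- function(x) x@count

#' @rdname SmallRNATagSet-class
#' @export
tagId <- function(x) x@id

#' @rdname SmallRNATagSet-class
#' @export
setMethod("length", "SmallRNATagSet", function(x) length(x@sequence))

#' @param i index for subsetting.
#' @rdname SmallRNATagSet-class
#' @export
setMethod("[", "SmallRNATagSet", function(x, i) {
    new("SmallRNATagSet", sequence = x@sequence[i], count = x@count[i],
        id = x@id[i])
})

#' @rdname SmallRNATagSet-class
#' @export
setMethod("show", "SmallRNATagSet", function(object) {
    cat("SmallRNATagSet with", length(object), "tags,",
        sum(object@count), "reads\n")
    if (length(object) > 0L) {
        k <- min(5L, length(object))
        for (i in seq_len(k))
            cat(sprintf("  %s  %s  x%d\n", object@id[i],
                        object@sequence[i], object@count[i]))
        if (length(object) > k) cat("  ...\n")
    }
})

#' @rdname SmallRNATagSet-class
#' @export
setMethod("as.data.frame", "SmallRNATagSet", function(x) {
    data.frame(id = x@id, sequence = x@sequence, count = x@count,
               stringsAsFactors = FALSE)
})

#' Read QC accounting
#'
#' Bookkeeping for the read cleaning stage: raw and clean read totals,
#' per-rule rejection tallies, and the clean-read length histogram over
#' the 16-30 nt window. The invariants `raw = clean + sum(rejections)`
#' and `sum(histogram) = clean` are enforced, so no read can be silently
#' lost or double counted.
#'
#' @slot rawReads,cleanReads,uniqueTags integer counts.
#' @slot rejections named integer vector of per-rule rejection counts.
#' @slot lengthHistogram named integer vector, clean reads per insert
#'   length ("16" ... "30").
#' @export
setClass("QcReport",
         representation(rawReads = "integer", cleanReads = "integer",
                        uniqueTags = "integer", rejections = "integer",
                        lengthHistogram = "integer"))

setValidity("QcReport", function(object) {
    if (object@rawReads != object@cleanReads + sum(object@rejections))
        return("rawReads must equal cleanReads + sum(rejections)")
    if (sum(object@lengthHistogram) != object@cleanReads)
        return("length histogram must sum to cleanReads")
    TRUE
})

#' @param object a `QcReport`.
#' @rdname QcReport-class
#' @export
setMethod("show", "QcReport", function(object) {
    cat("QcReport:", object@rawReads, "raw ->", object@cleanReads,
        "clean reads;", object@uniqueTags, "unique tags\n")
    if (sum(object@rejections) > 0) {
        cat("rejections:\n")
        for (r in names(object@rejections))
            if (object@rejections[[r]] > 0)
                cat(sprintf("  %-16s %d\n", r, object@rejections[[r]]))
    }
})

#' @rdname QcReport-class
#' @export
rawReads <- function(x) x@rawReads

#' @rdname QcReport-class
#' @export
cleanReads <- function(x) x@cleanReads

#' @rdname QcReport-class
#' @export
rejectionTally <- function(x) x@rejections

#' @param x a `QcReport`.
#' @rdname QcReport-class
#' @export
lengthHistogram <- function(x) x@lengthHistogram

#' RNA secondary structure fold
#'
#' The minimum free energy secondary structure of one sequence under the
#' package's stacked base-pair energy model: a dot-bracket string of the
#' same length as the sequence and the total energy in kcal/mol. The
#' structure is always properly nested (no pseudoknots), pairs only
#' Watson-Crick or G:U partners, and keeps hairpin loops of at least 3
#' unpaired bases.
#'
#' @slot sequence the folded sequence (DNA or RNA alphabet as given).
#' @slot structure dot-bracket string.
#' @slot mfe minimum free energy, kcal/mol (<= 0).
#' @seealso [foldRna()]
#' @export
setClass("FoldResult",
         representation(sequence = "character", structure = "character",
                        mfe = "numeric"))

setValidity("FoldResult", function(object) {
    if (nchar(object@sequence) != nchar(object@structure))
        return("structure and sequence must have equal length")
    p <- tryCatch(pairTable(object@structure), error = function(e) e)
    if (inherits(p, "error")) return(conditionMessage(p))
    if (object@mfe > 1e-9) return("mfe must be <= 0")
    paired <- !is.na(p)
    if (object@mfe == 0 && any(paired))
        return("mfe 0 implies an unpaired structure")
    if (any(paired) && object@mfe >= 0)
        return("paired structure implies mfe < 0")
    TRUE
})

#' @param x,object a `FoldResult`.
#' @rdname FoldResult-class
#' @export
mfe <- function(x) x@mfe

#' @rdname FoldResult-class
#' @export
dotBracket <- function(x) x@structure

#' @rdname FoldResult-class
#' @export
foldedSequence <- function(x) x@sequence

#' @rdname FoldResult-class
#' @export
setMethod("show", "FoldResult", function(object) {
    cat("FoldResult (", nchar(object@sequence), " nt, mfe ",
        object@mfe, " kcal/mol)\n", sep = "")
    cat(object@sequence, "\n", object@structure, "\n", sep = "")
})

#' Candidate miRNA precursor hairpin
#'
#' One excised genomic window evaluated as a miRNA precursor: its fold,
#' the position of the candidate mature tag on the window, the duplex
#' statistics against the opposite arm, the theoretical miRNA* and the
#' final verdict. Coordinates are 0-based half-open; `matureStart` /
#' `starStart` are offsets on the (strand-oriented) window.
#'
#' @slot chrom,start,end,strand genomic window locus (0-based half-open).
#' @slot precursor window sequence, 5' to 3' on its strand.
#' @slot fold a [FoldResult-class] for the window.
#' @slot matureSeq,matureStart the candidate mature and its window offset.
#' @slot starSeq,starStart theoretical miRNA* (duplex partner with 2-nt
#'   3' overhangs); NA when the duplex could not be resolved.
#' @slot duplexMismatches mature bases left unpaired opposite the star.
#' @slot bulgedBases asymmetric unpaired bases within the duplex.
#' @slot hasStarRead whether a sequenced tag supports the miRNA*.
#' @slot verdict logical pass/fail.
#' @slot reason failure reason, "" when passing.
#' @export
setClass("HairpinCandidate",
         representation(chrom = "character", start = "numeric",
                        end = "numeric", strand = "character",
                        precursor = "character", fold = "FoldResult",
                        matureSeq = "character", matureStart = "numeric",
                        starSeq = "character", starStart = "numeric",
                        duplexMismatches = "integer",
                        bulgedBases = "integer", hasStarRead = "logical",
                        verdict = "logical", reason = "character"))

#' @param object a `HairpinCandidate`.
#' @rdname HairpinCandidate-class
#' @export
setMethod("show", "HairpinCandidate", function(object) {
    cat(sprintf("HairpinCandidate %s:%d-%d(%s)  %s\n", object@chrom,
                object@start, object@end, object@strand,
                if (object@verdict) "PASS" else
                    paste0("FAIL(", object@reason, ")")))
    cat(sprintf("  mature %s @%d  mfe %.1f  mismatches %d  bulges %d  star read: %s\n",
                object@matureSeq, object@matureStart, object@fold@mfe,
                object@duplexMismatches, object@bulgedBases,
                object@hasStarRead))
})

#' @param x a `HairpinCandidate`.
#' @rdname HairpinCandidate-class
#' @export
verdict <- function(x) x@verdict

#' @rdname HairpinCandidate-class
#' @export
matureSequence <- function(x) x@matureSeq

#' @rdname HairpinCandidate-class
#' @export
starSequence <- function(x) x@starSeq

#' Truth ledger for a synthetic small RNA dataset
#'
#' The generator's record of everything planted in the synthetic genome:
#' each pre-miRNA hairpin with its mature and theoretical miRNA*
#' sequences and loci, and each ncRNA contaminant locus. Downstream
#' stages never see this object; it exists so that recovery (precision /
#' recall against known truth) can be scored.
#'
#' All coordinates are 0-based half-open on the plus strand of the
#' stored genome; `strand` records which strand the planted feature
#' reads 5' to 3' on.
#'
#' @slot genome a [Biostrings::DNAStringSet] after planting.
#' @slot mirnas data.frame: name, mature, star, family, chrom, start,
#'   end (mature locus), strand, precStart, precEnd, starStart, starEnd,
#'   emitsStar.
#' @slot ncrnas data.frame: class, name, sequence, chrom, start, end.
#' @slot seed integer seed the genome/planting was generated under.
#' @export
setClass("TruthSet",
         representation(genome = "DNAStringSet", mirnas = "data.frame",
                        ncrnas = "data.frame", seed = "integer"))

setValidity("TruthSet", function(object) {
    m <- object@mirnas
    if (nrow(m) > 0) {
        w <- nchar(m$mature)
        if (any(w < 20L | w > 24L))
            return("planted mature lengths must be within 20-24 nt")
        for (i in seq_len(nrow(m))) {
            chr <- object@genome[[m$chrom[i]]]
            seg <- as.character(Biostrings::subseq(chr, m$start[i] + 1L,
                                                   m$end[i]))
            want <- if (m$strand[i] == "+") m$mature[i] else
                revComp(m$mature[i])
            if (seg != want)
                return(sprintf("mature %s not at its recorded locus",
                               m$name[i]))
        }
    }
    TRUE
})

#' @param object a `TruthSet`.
#' @rdname TruthSet-class
#' @export
setMethod("show", "TruthSet", function(object) {
    cat("TruthSet:", nrow(object@mirnas), "planted miRNA hairpins,",
        nrow(object@ncrnas), "planted ncRNA loci, genome of",
        length(object@genome), "sequence(s) /",
        sum(Biostrings::width(object@genome)), "nt\n")
})

#' @param x a `TruthSet`.
#' @rdname TruthSet-class
#' @export
truthGenome <- function(x) x@genome

#' @rdname TruthSet-class
#' @export
plantedMirnas <- function(x) x@mirnas

#' @rdname TruthSet-class
#' @export
plantedNcrnas <- function(x) x@ncrnas

#' Simulated small RNA sequencing library
#'
#' A table of simulated reads (sequence plus Phred+33 quality) together
#' with the per-read source bookkeeping: which planted entity each read
#' was fragmented or copied from, how many sequencing errors were
#' injected, and whether the read was deliberately quality-degraded.
#'
#' @slot reads data.frame: id, sequence, quality, sourceType (mature /
#'   star / ncrna / degradation), sourceName, insertLength, nErrors,
#'   degraded.
#' @slot adapter 3' adapter appended to every insert.
#' @slot errorRate per-base substitution probability.
#' @slot seed integer seed.
#' @export
setClass("SimulatedLibrary",
         representation(reads = "data.frame", adapter = "character",
                        errorRate = "numeric", seed = "integer"))

#' @param object a `SimulatedLibrary`.
#' @rdname SimulatedLibrary-class
#' @export
setMethod("show", "SimulatedLibrary", function(object) {
    src <- table(object@reads$sourceType)
    cat("SimulatedLibrary:", nrow(object@reads), "reads (",
        paste(names(src), as.integer(src), collapse = ", "), ")\n")
})

#' @param x a `SimulatedLibrary`.
#' @rdname SimulatedLibrary-class
#' @export
libraryReads <- function(x) x@reads
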