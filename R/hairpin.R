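# Novel miRNA discovery: genome mapping of unannotated tags, precursor
# excision, MFE folding, structural evaluation against plant miRNA
# annotation criteria, miRNA* evidence, and family clustering.

#' Map tags to a genome by exact matching
#'
#' Finds every exact occurrence of each tag on the plus strand and of
#' its reverse complement on the minus strand. Tags with more than
#' `maxLoci` total hits are flagged repetitive and excluded from
#' downstream discovery.
#'
#' @param tags a [SmallRNATagSet-class] (or character vector).
#' @param genome a [Biostrings::DNAStringSet].
#' @param maxLoci repetitive-tag threshold (default 20).
#' @return list with `loci` (data.frame: tag_id, sequence, chrom, start,
#'   end, strand; 0-based half-open coordinates) and `repetitive`
#'   (character vector of excluded tag ids).
#' @export
mapToGenome <- function(tags, genome, maxLoci = 20L) {
    if (is.character(tags)) tags <- SmallRNATagSet(tags)
    stopifnot(is(genome, "DNAStringSet"))
    seqs <- tagSequence(tags)
    ids <- tagId(tags)
    empty <- data.frame(tag_id = character(0), sequence = character(0),
                        chrom = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        stringsAsFactors = FALSE)
    if (length(seqs) == 0L) return(list(loci = empty,
                                        repetitive = character(0)))
    hits <- vector("list", 2L * length(unique(nchar(seqs))) *
                       length(genome))
    hi <- 0L
    # group tags by width so a constant-width PDict can be used per group
    for (w in sort(unique(nchar(seqs)))) {
        sel <- which(nchar(seqs) == w)
        fwd <- Biostrings::DNAStringSet(seqs[sel])
        rev <- Biostrings::reverseComplement(fwd)
        pdF <- Biostrings::PDict(fwd)
        pdR <- Biostrings::PDict(rev)
        for (ci in seq_along(genome)) {
            chrom <- names(genome)[ci]
            for (str in c("+", "-")) {
                pd <- if (str == "+") pdF else pdR
                m <- Biostrings::matchPDict(pd, genome[[ci]])
                starts <- Biostrings::startIndex(m)
                n <- lengths(starts)
                if (sum(n) == 0L) next
                hi <- hi + 1L
                hits[[hi]] <- data.frame(
                    tag_id = rep(ids[sel], n),
                    sequence = rep(seqs[sel], n),
                    chrom = chrom,
                    start = unlist(starts, use.names = FALSE) - 1L,
                    end = unlist(starts, use.names = FALSE) - 1L + w,
                    strand = str, stringsAsFactors = FALSE)
            }
        }
    }
    loci <- if (hi > 0L) do.call(rbind, hits[seq_len(hi)]) else empty
    nHits <- table(loci$tag_id)
    repetitive <- names(nHits)[nHits > maxLoci]
    loci <- loci[!(loci$tag_id %in% repetitive), , drop = FALSE]
    loci <- loci[order(loci$tag_id, loci$chrom, loci$start,
                       loci$strand), , drop = FALSE]
    rownames(loci) <- NULL
    list(loci = loci, repetitive = repetitive)
}

#' Excise candidate precursor windows around a mapped tag
#'
#' Two windows per locus, so the mature can sit on either hairpin arm:
#' `[start - flank, end + 20)` and `[start - 20, end + flank)`, clipped
#' to the chromosome. Minus-strand windows are reverse complemented so
#' the tag always reads 5' to 3' on the returned sequence.
#'
#' @param loci data.frame as returned in `mapToGenome()$loci` (any
#'   subset of rows).
#' @param genome a [Biostrings::DNAStringSet].
#' @param flank flanking length on the far side of each window, nt.
#' @return data.frame: tag_id, sequence (tag), chrom, winStart, winEnd,
#'   strand, window (the excised sequence, strand-oriented).
#' @export
excisePrecursors <- function(loci, genome, flank = 150L) {
    stopifnot(is(genome, "DNAStringSet"))
    chromLen <- setNames(Biostrings::width(genome), names(genome))
    out <- vector("list", nrow(loci))
    for (i in seq_len(nrow(loci))) {
        s <- loci$start[i]
        e <- loci$end[i]
        cl <- chromLen[[loci$chrom[i]]]
        wins <- unique(rbind(
            c(max(0L, s - flank), min(cl, e + 20L)),
            c(max(0L, s - 20L), min(cl, e + flank))))
        sq <- vapply(seq_len(nrow(wins)), function(k) {
            w <- as.character(Biostrings::subseq(
                genome[[loci$chrom[i]]], wins[k, 1L] + 1L, wins[k, 2L]))
            if (loci$strand[i] == "-") revComp(w) else w
        }, character(1))
        out[[i]] <- data.frame(
            tag_id = loci$tag_id[i], sequence = loci$sequence[i],
            chrom = loci$chrom[i], winStart = wins[, 1L],
            winEnd = wins[, 2L], strand = loci$strand[i],
            window = sq, stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Fold a sequence into its minimum free energy structure
#'
#' Interval dynamic programming over a stacked base-pair energy model:
#' G:C pairs score `eGC`, A:U pairs `eAU` and G:U wobbles `eGU`
#' kcal/mol; hairpin loops keep at least `minloop` unpaired bases and
#' pseudoknots are not considered. Energy ties are broken toward more
#' base pairs, and the traceback prefers pairing the 5'-most base, so
#' the reported structure is deterministic. The model is intentionally
#' additive and oracle-verifiable; a nearest-neighbour engine can be
#' substituted behind the same interface without changing any caller.
#'
#' @param sequence one sequence, 10-400 nt, ACGT/U.
#' @param eGC,eAU,eGU base-pair energies, kcal/mol (negative).
#' @param minloop minimum hairpin loop length, nt.
#' @return a [FoldResult-class].
#' @examples
#' foldRna("GGGAAAACCC") # "(((....)))", -9 kcal/mol
#' @export
foldRna <- function(sequence, eGC = -3.0, eAU = -2.0, eGU = -1.0,
                    minloop = 3L) {
    sequence <- toupper(sequence)
    n <- nchar(sequence)
    if (n < 10L || n > 400L)
        stop("sequence length must be within [10, 400]")
    if (grepl("[^ACGTU]", sequence))
        stop("sequence must contain only A, C, G, T, U")
    r <- fold_cpp(chartr("U", "T", sequence), eGC, eAU, eGU,
                  as.integer(minloop))
    new("FoldResult", sequence = sequence, structure = r$structure,
        mfe = r$mfe)
}

#' Default thresholds for hairpin evaluation
#'
#' Plant miRNA annotation criteria: at most 4 mature bases unpaired
#' opposite the miRNA* region, at most 2 asymmetrically bulged bases in
#' the duplex, precursor MFE at or below `mfeMax` kcal/mol (under the
#' package's energy model) and a 20-24 nt mature.
#'
#' @param maxDuplexMismatch,maxBulge,mfeMax,matureLen see above.
#' @return a named list.
#' @export
hairpinThresholds <- function(maxDuplexMismatch = 4L, maxBulge = 2L,
                              mfeMax = -18, matureLen = c(20L, 24L)) {
    list(maxDuplexMismatch = as.integer(maxDuplexMismatch),
         maxBulge = as.integer(maxBulge), mfeMax = mfeMax,
         matureLen = as.integer(matureLen))
}

# Duplex statistics of a mature placed at 1-based [mS, mE] on a folded
# window. Returns list(mismatches, bulges, arm, starLo, starHi) with
# star coordinates 1-based inclusive (NA when unresolvable).
.duplexStats <- function(partner, mS, mE) {
    m <- mS:mE
    p <- partner[m]
    paired <- which(!is.na(p))
    if (length(paired) == 0L)
        return(list(mismatches = length(m), bulges = NA_integer_,
                    arm = NA_character_, starLo = NA_integer_,
                    starHi = NA_integer_))
    pp <- p[paired]
    if (any(pp >= mS & pp <= mE)) # folds onto itself: spans the loop
        return(list(mismatches = NA_integer_, bulges = NA_integer_,
                    arm = "loop", starLo = NA_integer_,
                    starHi = NA_integer_))
    if (all(pp > mE)) arm <- "5p"
    else if (all(pp < mS)) arm <- "3p"
    else # partners on both sides: mature crosses the terminal loop
        return(list(mismatches = NA_integer_, bulges = NA_integer_,
                    arm = "loop", starLo = NA_integer_,
                    starHi = NA_integer_))
    mismatches <- length(m) - length(paired)
    # interior unpaired mature bases (between first and last paired)
    interior <- seq(min(paired), max(paired))
    uMInt <- sum(is.na(p[interior]))
    span <- seq(min(pp), max(pp))
    uS <- sum(is.na(partner[span]))
    bulges <- abs(uS - uMInt)
    # theoretical star with 2-nt 3' overhangs: anchor at the deepest
    # pairable positions and extrapolate across unpaired ends
    mPaired <- m[paired]
    q1 <- mPaired[mPaired <= (mE - 2L)]
    q1 <- if (length(q1)) max(q1) else min(mPaired)
    q2 <- min(mPaired)
    lo <- partner[q1] - ((mE - 2L) - q1)
    hi <- partner[q2] + (q2 - mS) + 2L
    list(mismatches = as.integer(mismatches),
         bulges = as.integer(bulges), arm = arm,
         starLo = as.integer(min(lo, hi)),
         starHi = as.integer(max(lo, hi)))
}

#' Evaluate an excised window as a miRNA precursor
#'
#' Locates the mature tag on the window, reads the mature/miRNA* duplex
#' off the fold, and applies the structural criteria: the mature must
#' lie entirely within one arm (no base in the terminal loop), have at
#' most `maxDuplexMismatch` bases unpaired opposite the star region, at
#' most `maxBulge` asymmetrically bulged bases, a 20-24 nt length, and
#' the window MFE must be at or below `mfeMax`. The theoretical miRNA*
#' (duplex partner with 2-nt 3' overhangs) is recorded for
#' [findStar()].
#'
#' @param window data.frame row from [excisePrecursors()] (or a list
#'   with the same fields).
#' @param tag the mature candidate sequence (must occur in the window).
#' @param fold optional pre-computed [FoldResult-class] for the window.
#' @param thresholds list from [hairpinThresholds()].
#' @return a [HairpinCandidate-class].
#' @export
evaluateHairpin <- function(window, tag, fold = NULL,
                            thresholds = hairpinThresholds()) {
    if (is.data.frame(window)) window <- as.list(window[1L, ])
    wseq <- toupper(window$window)
    off <- regexpr(tag, wseq, fixed = TRUE)[[1L]]
    if (off < 0L) stop("tag not found in window (internal error)")
    if (is.null(fold)) fold <- foldRna(wseq)
    partner <- pairTable(fold@structure)
    L <- nchar(tag)
    mS <- off
    mE <- off + L - 1L
    ds <- .duplexStats(partner, mS, mE)
    fail <- NULL
    if (L < thresholds$matureLen[1L] || L > thresholds$matureLen[2L])
        fail <- "mature_length"
    else if (identical(ds$arm, "loop"))
        fail <- "mature_in_loop"
    else if (is.na(ds$arm))
        fail <- "no_duplex"
    else if (ds$mismatches > thresholds$maxDuplexMismatch)
        fail <- "duplex_mismatches"
    else if (ds$bulges > thresholds$maxBulge)
        fail <- "bulged_bases"
    else if (fold@mfe > thresholds$mfeMax)
        fail <- "mfe"
    starSeq <- NA_character_
    starStart <- NA_real_
    if (!is.na(ds$starLo) && ds$starLo >= 1L &&
        ds$starHi <= nchar(wseq)) {
        starSeq <- substr(wseq, ds$starLo, ds$starHi)
        starStart <- ds$starLo - 1L
    }
    new("HairpinCandidate",
        chrom = as.character(window$chrom %||% NA_character_),
        start = as.numeric(window$winStart %||% NA_real_),
        end = as.numeric(window$winEnd %||% NA_real_),
        strand = as.character(window$strand %||% "+"),
        precursor = wseq, fold = fold, matureSeq = tag,
        matureStart = off - 1L, starSeq = starSeq,
        starStart = starStart,
        duplexMismatches = if (is.na(ds$mismatches)) NA_integer_ else
            ds$mismatches,
        bulgedBases = if (is.na(ds$bulges)) NA_integer_ else ds$bulges,
        hasStarRead = FALSE, verdict = is.null(fail),
        reason = fail %||% "")
}

# Window offset (0-based, inclusive lo/hi) -> genomic 0-based half-open.
.windowToGenomic <- function(cand, lo0, hi0) {
    if (cand@strand == "+")
        c(cand@start + lo0, cand@start + hi0 + 1)
    else
        c(cand@end - hi0 - 1, cand@end - lo0)
}

#' Look for sequenced miRNA* support
#'
#' Computes the genomic locus of the candidate's theoretical miRNA* and
#' flags the candidate when a sequenced tag maps there within 2 nt at
#' either end. Absence of a star read never fails a candidate; most
#' genuine plant miRNAs are sequenced without their star.
#'
#' @param candidate a passing [HairpinCandidate-class].
#' @param tagLoci data.frame of mapped tag loci (from
#'   `mapToGenome()$loci`).
#' @param tol positional tolerance at each end, nt.
#' @return the candidate with `hasStarRead` set.
#' @export
findStar <- function(candidate, tagLoci, tol = 2L) {
    if (is.na(candidate@starStart)) return(candidate)
    lo0 <- candidate@starStart
    hi0 <- lo0 + nchar(candidate@starSeq) - 1
    g <- .windowToGenomic(candidate, lo0, hi0)
    hit <- tagLoci$chrom == candidate@chrom &
        tagLoci$strand == candidate@strand &
        abs(tagLoci$start - g[1L]) <= tol &
        abs(tagLoci$end - g[2L]) <= tol &
        # the mature itself does not count as its own star
        !(tagLoci$sequence == candidate@matureSeq)
    candidate@hasStarRead <- any(hit)
    candidate
}

#' Cluster novel matures into families
#'
#' Greedy star-linkage clustering: seeds are processed in descending
#' read count (ties lexicographic), and a mature joins a family when it
#' has the same length as the seed and differs from it by at most
#' `maxSub` substitutions, so every member stays within `maxSub` of its
#' family seed. Families are named miRn001, miRn002, ... in seed order.
#'
#' @param matures data.frame with columns sequence and count
#'   (deduplicated).
#' @param maxSub maximum substitutions to the family seed.
#' @return data.frame: family, sequence, count, is_seed.
#' @export
clusterFamilies <- function(matures, maxSub = 2L) {
    if (is.null(matures) || nrow(matures) == 0L)
        return(data.frame(family = character(0), sequence = character(0),
                          count = integer(0), is_seed = logical(0),
                          stringsAsFactors = FALSE))
    matures <- matures[!duplicated(matures$sequence), , drop = FALSE]
    o <- order(-matures$count, matures$sequence)
    sq <- matures$sequence[o]
    ct <- matures$count[o]
    fam <- rep(NA_integer_, length(sq))
    seeds <- integer(0)
    nf <- 0L
    for (i in seq_along(sq)) {
        if (!is.na(fam[i])) next
        nf <- nf + 1L
        fam[i] <- nf
        seeds <- c(seeds, i)
        for (j in seq_along(sq)) {
            if (!is.na(fam[j]) || nchar(sq[j]) != nchar(sq[i])) next
            d <- sum(utf8ToInt(sq[i]) != utf8ToInt(sq[j]))
            if (d <= maxSub) fam[j] <- nf
        }
    }
    data.frame(family = sprintf("miRn%03d", fam), sequence = sq,
               count = ct, is_seed = seq_along(sq) %in% seeds,
               stringsAsFactors = FALSE)
}

#' Summary statistics of a family table
#'
#' @param families data.frame with a `family` column (one row per
#'   member), e.g. from [clusterFamilies()].
#' @param nMembers,nFamilies alternatively, give the totals directly.
#' @return list with nMembers, nFamilies and meanMembers (1 decimal, as
#'   conventionally reported).
#' @export
familyStats <- function(families = NULL, nMembers = NULL,
                        nFamilies = NULL) {
    if (!is.null(families)) {
        nMembers <- nrow(families)
        nFamilies <- length(unique(families$family))
    }
    list(nMembers = nMembers, nFamilies = nFamilies,
         meanMembers = if (nFamilies > 0)
             round(nMembers / nFamilies, 1) else NA_real_)
}

#' Discover novel miRNAs from unannotated tags
#'
#' The full discovery track: map tags to the genome, excise candidate
#' windows, fold, evaluate against the hairpin criteria, attach miRNA*
#' evidence, keep the best candidate per tag (passing preferred, then
#' lowest MFE, then 5'-most window) and cluster the passing matures
#' into families.
#'
#' @param tags a [SmallRNATagSet-class] of unannotated tags.
#' @param genome a [Biostrings::DNAStringSet].
#' @param thresholds from [hairpinThresholds()].
#' @param flank window flank, nt.
#' @param maxLoci repetitive-tag threshold.
#' @param minCount skip tags with fewer reads than this (singletons are
#'   dominated by sequencing errors).
#' @param extraStarTags optional [SmallRNATagSet-class] of additional
#'   sequenced tags (e.g. conserved miRNA calls) whose genome loci may
#'   provide miRNA* support; they are never evaluated as candidates.
#' @return list: `candidates` (data.frame, one row per evaluated tag
#'   with verdict, locus, mfe, duplex stats, star evidence, family),
#'   `objects` (named list of the best [HairpinCandidate-class] per
#'   passing tag), `families` (from [clusterFamilies()]), `repetitive`.
#' @export
discoverNovel <- function(tags, genome,
                          thresholds = hairpinThresholds(),
                          flank = 150L, maxLoci = 20L, minCount = 2L,
                          extraStarTags = NULL) {
    keep <- tagCount(tags) >= minCount
    tags <- tags[which(keep)]
    mp <- mapToGenome(tags, genome, maxLoci = maxLoci)
    loci <- mp$loci
    emptyCand <- data.frame(
        tag_id = character(0), sequence = character(0),
        chrom = character(0), matureStart = numeric(0),
        matureEnd = numeric(0), strand = character(0), mfe = numeric(0),
        duplexMismatches = integer(0), bulgedBases = integer(0),
        hasStarRead = logical(0), verdict = logical(0),
        reason = character(0), count = integer(0),
        stringsAsFactors = FALSE)
    if (nrow(loci) == 0L)
        return(list(candidates = emptyCand, objects = list(),
                    families = clusterFamilies(NULL),
                    repetitive = mp$repetitive))
    wins <- excisePrecursors(loci, genome, flank = flank)
    counts <- setNames(tagCount(tags), tagId(tags))
    best <- list()
    for (i in seq_len(nrow(wins))) {
        cand <- evaluateHairpin(wins[i, ], wins$sequence[i],
                                thresholds = thresholds)
        tid <- wins$tag_id[i]
        prev <- best[[tid]]
        better <- is.null(prev) ||
            (cand@verdict && !prev@verdict) ||
            (cand@verdict == prev@verdict && cand@fold@mfe < prev@fold@mfe)
        if (better) best[[tid]] <- cand
    }
    starLoci <- loci
    if (!is.null(extraStarTags) && length(extraStarTags) > 0L)
        starLoci <- rbind(loci, mapToGenome(extraStarTags, genome,
                                            maxLoci = maxLoci)$loci)
    best <- lapply(best, findStar, tagLoci = starLoci)
    rows <- lapply(names(best), function(tid) {
        cand <- best[[tid]]
        off <- cand@matureStart
        g <- .windowToGenomic(cand, off, off + nchar(cand@matureSeq) - 1)
        data.frame(tag_id = tid, sequence = cand@matureSeq,
                   chrom = cand@chrom, matureStart = g[1L],
                   matureEnd = g[2L], strand = cand@strand,
                   mfe = cand@fold@mfe,
                   duplexMismatches = cand@duplexMismatches,
                   bulgedBases = cand@bulgedBases,
                   hasStarRead = cand@hasStarRead,
                   verdict = cand@verdict, reason = cand@reason,
                   count = counts[[tid]], stringsAsFactors = FALSE)
    })
    cands <- do.call(rbind, rows)
    rownames(cands) <- NULL
    passing <- cands[cands$verdict, , drop = FALSE]
    fams <- clusterFamilies(passing[, c("sequence", "count")])
    if (nrow(fams) > 0L && nrow(passing) > 0L)
        cands$family <- fams$family[match(cands$sequence, fams$sequence)]
    else cands$family <- NA_character_
    list(candidates = cands, objects = best[passing$tag_id],
         families = fams, repetitive = mp$repetitive)
}
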