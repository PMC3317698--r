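# Synthetic genome / library generator with a truth ledger. Everything
# downstream is benchmarked against what this module plants.

#' Generate a random genome
#'
#' Draws `nChrom` uppercase ACGT chromosomes of `chromLen` nt with the
#' given GC fraction. Deterministic under `seed`.
#'
#' @param nChrom number of chromosomes (>= 1).
#' @param chromLen chromosome length in nt (>= 1000).
#' @param gc GC fraction in (0, 1).
#' @param seed integer seed.
#' @return a [Biostrings::DNAStringSet] named chr1, chr2, ...
#' @examples
#' g <- generateGenome(1, 10000, gc = 0.44, seed = 42)
#' @export
generateGenome <- function(nChrom = 1L, chromLen = 100000L, gc = 0.44,
                           seed = 1L) {
    if (nChrom < 1L || chromLen < 1000L)
        stop("nChrom must be >= 1 and chromLen >= 1000")
    if (gc <= 0 || gc >= 1) stop("gc must be strictly between 0 and 1")
    seqs <- withSeed(seed, vapply(seq_len(nChrom), function(i)
        randomDna(chromLen, gc), character(1)))
    names(seqs) <- paste0("chr", seq_len(nChrom))
    Biostrings::DNAStringSet(seqs)
}

# Draw a mature miRNA sequence that survives the poly-A artifact filter
# and has no long homopolymer (keeps genome occurrences unique in
# practice).
.drawMature <- function(len) {
    repeat {
        m <- randomDna(len, gc = 0.5)
        if (!grepl("A{6,}|C{6,}|G{6,}|T{6,}", m) &&
            mean(strsplit(m, "")[[1]] == "A") < 0.5)
            return(m)
    }
}

#' Plant pre-miRNA hairpins in a genome
#'
#' Inserts `nMirna` non-overlapping stem-loop precursors into the
#' genome. Each precursor is built as `F + M + loop + revcomp(M) +
#' revcomp(F)` (flank `F`, mature `M`), so the mature arm pairs
#' perfectly with the star arm and the theoretical miRNA* (duplex
#' partner with 2-nt 3' overhangs) is known by construction. Precursor
#' lengths are drawn uniformly from `precLenRange` and loops from
#' `loopRange`; half the hairpins land on the minus strand.
#'
#' @param genome a [Biostrings::DNAStringSet], e.g. from
#'   [generateGenome()].
#' @param nMirna number of hairpins to plant.
#' @param matureLenRange mature length range, inclusive (within 20-24).
#' @param precLenRange,loopRange precursor and terminal loop length
#'   ranges, nt.
#' @param nStar how many hairpins will later emit miRNA* reads (marked
#'   in the ledger; the library simulator honours the mark).
#' @param seed integer seed.
#' @return a [TruthSet-class] holding the modified genome and the ledger.
#' @export
plantHairpins <- function(genome, nMirna = 30L,
                          matureLenRange = c(20L, 24L),
                          precLenRange = c(120L, 200L),
                          loopRange = c(8L, 15L),
                          nStar = min(15L, nMirna), seed = 1L) {
    stopifnot(is(genome, "DNAStringSet"))
    if (nMirna < 0L) stop("nMirna must be >= 0")
    if (matureLenRange[1] < 20L || matureLenRange[2] > 24L)
        stop("matureLenRange must be within [20, 24]")
    glen <- sum(Biostrings::width(genome))
    if (nMirna > 0 && glen < nMirna * (max(precLenRange) + 100L))
        stop("insufficient genome space to host ", nMirna, " precursors")
    gchar <- setNames(as.character(genome), names(genome))
    empty <- data.frame(name = character(0), mature = character(0),
                        star = character(0), family = character(0),
                        chrom = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        precStart = integer(0), precEnd = integer(0),
                        starStart = integer(0), starEnd = integer(0),
                        emitsStar = logical(0), stringsAsFactors = FALSE)
    emptyNc <- data.frame(class = character(0), name = character(0),
                          sequence = character(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          stringsAsFactors = FALSE)
    if (nMirna == 0L)
        return(new("TruthSet", genome = genome, mirnas = empty,
                   ncrnas = emptyNc, seed = as.integer(seed)))

    res <- withSeed(seed, {
        occupied <- lapply(gchar, function(x) integer(0))
        rows <- vector("list", nMirna)
        starIdx <- sort(sample.int(nMirna, min(nStar, nMirna)))
        for (i in seq_len(nMirna)) {
            L <- sample(seq(matureLenRange[1], matureLenRange[2]), 1L)
            loopLen <- sample(seq(loopRange[1], loopRange[2]), 1L)
            precLen <- sample(seq(precLenRange[1], precLenRange[2]), 1L)
            f <- max(10L, (precLen - 2L * L - loopLen) %/% 2L)
            precLen <- 2L * f + 2L * L + loopLen
            # draw until the fold of the designed precursor recovers the
            # designed duplex exactly: some random stems admit co-optimal
            # slipped pairings, and planted hairpins must satisfy the
            # evaluation criteria by construction
            mS <- f
            mE <- f + L - 1L
            sLo <- precLen - 1L - (mE - 2L)
            sHi <- precLen - 1L - mS + 2L
            repeat {
                mature <- .drawMature(L)
                flank <- randomDna(f, gc = 0.5)
                loop <- randomDna(loopLen, gc = 0.3)
                X <- paste0(flank, mature)
                prec <- paste0(X, loop, revComp(X))
                # theoretical star: duplex partner of the mature with
                # 2-nt 3' overhangs; on this construct, precursor
                # position p pairs with precLen - 1 - p (0-based)
                star <- substr(prec, sLo + 1L, sHi + 1L)
                cand <- evaluateHairpin(
                    list(window = prec, chrom = "prec", winStart = 0L,
                         winEnd = precLen, strand = "+"), mature)
                if (cand@verdict && cand@duplexMismatches == 0L &&
                    cand@bulgedBases == 0L &&
                    identical(cand@starSeq, star)) break
            }
            # non-overlapping placement with 50 nt padding
            repeat {
                chrom <- sample(names(gchar), 1L)
                maxStart <- nchar(gchar[[chrom]]) - precLen - 50L
                g0 <- sample.int(maxStart, 1L) + 25L # 0-based insert pos
                span <- seq(g0 - 50L, g0 + precLen + 50L)
                if (!any(span %in% occupied[[chrom]])) break
            }
            occupied[[chrom]] <- c(occupied[[chrom]],
                                   seq(g0 - 25L, g0 + precLen + 25L))
            strand <- if (i %% 2L == 0L) "-" else "+"
            ins <- if (strand == "+") prec else revComp(prec)
            substr(gchar[[chrom]], g0 + 1L, g0 + precLen) <- ins
            if (strand == "+") {
                mStart <- g0 + mS
                mEnd <- g0 + mE + 1L
                stStart <- g0 + sLo
                stEnd <- g0 + sHi + 1L
            } else {
                mStart <- g0 + precLen - mE - 1L
                mEnd <- g0 + precLen - mS
                stStart <- g0 + precLen - sHi - 1L
                stEnd <- g0 + precLen - sLo
            }
            rows[[i]] <- data.frame(
                name = sprintf("mir%03d", i), mature = mature,
                star = star, family = sprintf("mir%03d", i),
                chrom = chrom, start = mStart, end = mEnd,
                strand = strand, precStart = g0,
                precEnd = g0 + precLen, starStart = stStart,
                starEnd = stEnd, emitsStar = i %in% starIdx,
                stringsAsFactors = FALSE)
        }
        list(gchar = gchar, mirnas = do.call(rbind, rows))
    })
    new("TruthSet", genome = Biostrings::DNAStringSet(res$gchar),
        mirnas = res$mirnas,
        ncrnas = data.frame(class = character(0), name = character(0),
                            sequence = character(0), chrom = character(0),
                            start = integer(0), end = integer(0),
                            stringsAsFactors = FALSE),
        seed = as.integer(seed))
}

#' Plant ncRNA contaminant loci
#'
#' Adds random rRNA/tRNA/snRNA/snoRNA/repeat loci to a [TruthSet-class]
#' genome, avoiding all previously planted features. Library reads
#' simulated from these loci are random fragments of the planted
#' sequence, so they are exact substrings and the annotation cascade can
#' remove them.
#'
#' @param truth a [TruthSet-class] from [plantHairpins()].
#' @param nNcrna number of ncRNA loci.
#' @param classes classes cycled over the loci.
#' @param lenRange ncRNA locus length range, nt.
#' @param seed integer seed.
#' @return the updated [TruthSet-class].
#' @export
plantNcrnas <- function(truth, nNcrna = 10L,
                        classes = c("rRNA", "tRNA", "snRNA", "snoRNA",
                                    "repeat"),
                        lenRange = c(120L, 300L), seed = 2L) {
    stopifnot(is(truth, "TruthSet"))
    if (nNcrna == 0L) return(truth)
    gchar <- setNames(as.character(truth@genome), names(truth@genome))
    busy <- truth@mirnas[, c("chrom", "precStart", "precEnd")]
    res <- withSeed(seed, {
        rows <- vector("list", nNcrna)
        occ <- split(unlist(lapply(seq_len(nrow(busy)), function(i)
            seq(busy$precStart[i] - 50L, busy$precEnd[i] + 50L))),
            rep(busy$chrom, times = busy$precEnd - busy$precStart + 101L))
        occ <- lapply(setNames(names(gchar), names(gchar)),
                      function(ch) occ[[ch]] %||% integer(0))
        for (i in seq_len(nNcrna)) {
            len <- sample(seq(lenRange[1], lenRange[2]), 1L)
            sq <- randomDna(len, gc = 0.5)
            repeat {
                chrom <- sample(names(gchar), 1L)
                maxStart <- nchar(gchar[[chrom]]) - len - 50L
                g0 <- sample.int(maxStart, 1L) + 25L
                span <- seq(g0 - 40L, g0 + len + 40L)
                if (!any(span %in% occ[[chrom]])) break
            }
            occ[[chrom]] <- c(occ[[chrom]], span)
            substr(gchar[[chrom]], g0 + 1L, g0 + len) <- sq
            cls <- classes[(i - 1L) %% length(classes) + 1L]
            rows[[i]] <- data.frame(
                class = cls, name = sprintf("%s_%02d", cls, i),
                sequence = sq, chrom = chrom, start = g0,
                end = g0 + len, stringsAsFactors = FALSE)
        }
        do.call(rbind, rows)
    })
    new("TruthSet", genome = Biostrings::DNAStringSet(gchar),
        mirnas = truth@mirnas, ncrnas = rbind(truth@ncrnas, res),
        seed = truth@seed)
}

# Phred+33 quality string for one read: per-read mean Q drawn upstream,
# per-base jitter, clipped to [2, 41].
.qualString <- function(n, meanQ) {
    q <- pmin(41L, pmax(2L, as.integer(round(rnorm(n, meanQ, 3)))))
    intToUtf8(q + 33L)
}

# Inject substitution errors at rate `rate`; returns list(seq, n).
.injectErrors <- function(sq, rate) {
    if (rate <= 0) return(list(seq = sq, n = 0L))
    ch <- strsplit(sq, "")[[1]]
    hit <- which(runif(length(ch)) < rate)
    for (p in hit) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    list(seq = paste(ch, collapse = ""), n = length(hit))
}

#' Simulate a small RNA sequencing library
#'
#' Draws reads from the planted miRNA hairpins (mature and, for marked
#' hairpins, miRNA* at roughly 10% of the mature abundance), from planted
#' ncRNA loci (random 16-30 nt fragments) and from random unplanted
#' genome windows (degradation). Inserts get the 3' adapter appended and
#' are truncated to `readLength`; Phred+33 qualities are drawn per read
#' with mean quality in [25, 40]. A configurable fraction of reads is
#' deliberately degraded (an N, or low-quality bases placed exactly at
#' the whole-read filter boundaries) so that every rejection path in the
#' QC stage is exercised.
#'
#' Per-hairpin abundances are heavy-tailed (log-normal, mu 2, sigma 1.5)
#' on top of a floor of `minMirnaReads` reads each, emulating the strong
#' family-abundance skew of real plant small RNA libraries.
#'
#' @param truth a [TruthSet-class].
#' @param nReads total reads to simulate.
#' @param ncrnaFraction expected fraction of reads from ncRNA loci.
#' @param degradationFraction expected fraction of random genome
#'   fragments.
#' @param errorRate per-base substitution probability in [0, 1].
#' @param adapter 3' adapter sequence.
#' @param readLength raw read length before trimming.
#' @param degradedFraction fraction of reads with injected N / boundary
#'   low-quality bases.
#' @param minMirnaReads abundance floor per planted hairpin.
#' @param seed integer seed.
#' @return a [SimulatedLibrary-class].
#' @export
simulateLibrary <- function(truth, nReads = 50000L, ncrnaFraction = 0.3,
                            degradationFraction = 0.05,
                            errorRate = 0.001,
                            adapter = "TGGAATTCTCGGGTGCCAAGG",
                            readLength = 36L, degradedFraction = 0.04,
                            minMirnaReads = 22L, seed = 3L) {
    stopifnot(is(truth, "TruthSet"))
    if (errorRate < 0 || errorRate > 1)
        stop("errorRate must be within [0, 1]")
    if (ncrnaFraction < 0 || ncrnaFraction > 1)
        stop("ncrnaFraction must be within [0, 1]")
    cols <- c("id", "sequence", "quality", "sourceType", "sourceName",
              "insertLength", "nErrors", "degraded")
    if (nReads == 0L) {
        df <- data.frame(id = character(0), sequence = character(0),
                         quality = character(0), sourceType = character(0),
                         sourceName = character(0),
                         insertLength = integer(0), nErrors = integer(0),
                         degraded = logical(0), stringsAsFactors = FALSE)
        return(new("SimulatedLibrary", reads = df, adapter = adapter,
                   errorRate = errorRate, seed = as.integer(seed)))
    }
    mir <- truth@mirnas
    nc <- truth@ncrnas
    if (nrow(nc) == 0L) ncrnaFraction <- 0
    if (nrow(mir) == 0L && ncrnaFraction + degradationFraction < 1)
        stop("no planted miRNAs: set ncrnaFraction/degradationFraction",
             " to cover all reads")
    gchar <- setNames(as.character(truth@genome), names(truth@genome))
    # fragment length skew toward 21 and 24 nt, as in real plant
    # small RNA libraries
    fragLens <- 16:30
    fragProb <- c(1, 1, 1, 1, 2, 8, 3, 3, 10, 2, 1, 1, 1, 1, 1)

    reads <- withSeed(seed, {
        src <- sample(c("ncrna", "degradation", "mature"), nReads,
                      replace = TRUE,
                      prob = c(ncrnaFraction, degradationFraction,
                               max(0, 1 - ncrnaFraction -
                                       degradationFraction)))
        nMir <- sum(src == "mature")
        # per-hairpin allocation: floor + heavy-tailed remainder
        mirCounts <- integer(nrow(mir))
        if (nrow(mir) > 0L && nMir > 0L) {
            floorN <- min(minMirnaReads, nMir %/% max(1L, nrow(mir)))
            w <- rlnorm(nrow(mir), meanlog = 2, sdlog = 1.5)
            extra <- nMir - floorN * nrow(mir)
            mirCounts <- rep(floorN, nrow(mir))
            if (extra > 0L)
                mirCounts <- mirCounts +
                    tabulate(sample.int(nrow(mir), extra, replace = TRUE,
                                        prob = w),
                             nbins = nrow(mir))
            # carve star reads out of marked hairpins' allocation
            starCounts <- ifelse(mir$emitsStar,
                                 pmax(2L, as.integer(round(0.1 * mirCounts))),
                                 0L)
            starCounts <- pmin(starCounts, pmax(mirCounts - 2L, 0L))
            matCounts <- mirCounts - starCounts
        } else {
            matCounts <- starCounts <- integer(nrow(mir))
        }
        ncWeights <- if (nrow(nc) > 0L)
            rlnorm(nrow(nc), meanlog = 2, sdlog = 1.5) else numeric(0)

        inserts <- character(nReads)
        stype <- character(nReads)
        sname <- character(nReads)
        k <- 0L
        emit <- function(n, sq, type, nm) {
            if (n <= 0L) return(invisible())
            idx <- k + seq_len(n)
            inserts[idx] <<- sq
            stype[idx] <<- type
            sname[idx] <<- nm
            k <<- k + n
        }
        for (i in seq_len(nrow(mir))) {
            emit(matCounts[i], mir$mature[i], "mature", mir$name[i])
            emit(starCounts[i], mir$star[i], "star", mir$name[i])
        }
        nNc <- sum(src == "ncrna")
        if (nNc > 0L) {
            pick <- sample.int(nrow(nc), nNc, replace = TRUE,
                               prob = ncWeights)
            for (j in seq_len(nNc)) {
                e <- pick[j]
                flen <- min(sample(fragLens, 1L, prob = fragProb),
                            nchar(nc$sequence[e]))
                fs <- sample.int(nchar(nc$sequence[e]) - flen + 1L, 1L)
                emit(1L, substr(nc$sequence[e], fs, fs + flen - 1L),
                     "ncrna", nc$name[e])
            }
        }
        nDeg <- sum(src == "degradation")
        if (nDeg > 0L) {
            busy <- rbind(
                data.frame(chrom = mir$chrom, lo = mir$precStart,
                           hi = mir$precEnd),
                data.frame(chrom = nc$chrom, lo = nc$start, hi = nc$end))
            for (j in seq_len(nDeg)) {
                flen <- sample(fragLens, 1L, prob = fragProb)
                repeat {
                    chrom <- sample(names(gchar), 1L)
                    fs <- sample.int(nchar(gchar[[chrom]]) - flen, 1L)
                    b <- busy[busy$chrom == chrom, , drop = FALSE]
                    if (!any(fs < b$hi + 5L & fs + flen > b$lo - 5L))
                        break
                }
                sq <- substr(gchar[[chrom]], fs + 1L, fs + flen)
                if (runif(1) < 0.5) sq <- revComp(sq)
                emit(1L, sq, "degradation",
                     sprintf("%s_%d", chrom, fs))
            }
        }
        stopifnot(k == nReads)
        ord <- sample.int(nReads) # shuffle read order
        inserts <- inserts[ord]
        stype <- stype[ord]
        sname <- sname[ord]

        seqs <- character(nReads)
        quals <- character(nReads)
        nerr <- integer(nReads)
        degraded <- logical(nReads)
        nDegrade <- as.integer(round(degradedFraction * nReads))
        degradeIdx <- if (nDegrade > 0L) sample.int(nReads, nDegrade)
            else integer(0)
        degraded[degradeIdx] <- TRUE
        degType <- sample(c("N", "q10", "q13", "boundary"),
                          length(degradeIdx), replace = TRUE)
        degMap <- setNames(degType, degradeIdx)
        for (r in seq_len(nReads)) {
            err <- .injectErrors(inserts[r], errorRate)
            raw <- substr(paste0(err$seq, adapter,
                                 strrep("A", readLength)), 1L, readLength)
            meanQ <- runif(1, 25, 40)
            q <- pmin(41L, pmax(2L,
                as.integer(round(rnorm(readLength, meanQ, 3)))))
            q[q < 15L] <- 15L # baseline reads stay clear of the filters
            if (degraded[r]) {
                ch <- strsplit(raw, "")[[1]]
                mode <- degMap[[as.character(r)]]
                pos <- sample.int(nchar(err$seq),
                                  min(10L, nchar(err$seq)))
                if (mode == "N") {
                    ch[pos[1]] <- "N"
                } else if (mode == "q10") {
                    q[pos[seq_len(5L)]] <- 9L # > 4 bases under Q10
                } else if (mode == "q13") {
                    q[pos[seq_len(7L)]] <- 12L # > 6 bases in [10, 13)
                } else {
                    q[pos[seq_len(4L)]] <- 9L # exactly at both limits
                    q[pos[5L:10L]] <- 12L
                }
                raw <- paste(ch, collapse = "")
            }
            seqs[r] <- raw
            quals[r] <- intToUtf8(q + 33L)
            nerr[r] <- err$n
        }
        data.frame(id = sprintf("r%06d", seq_len(nReads)),
                   sequence = seqs, quality = quals, sourceType = stype,
                   sourceName = sname, insertLength = nchar(inserts),
                   nErrors = nerr, degraded = degraded,
                   stringsAsFactors = FALSE)
    })
    new("SimulatedLibrary", reads = reads, adapter = adapter,
        errorRate = errorRate, seed = as.integer(seed))
}

#' Write a simulated library and truth ledger to disk
#'
#' Writes the FASTQ (Phred+33; the read source is carried in the header
#' comment), the genome FASTA, a truth ledger TSV and the planted loci
#' as GFF3. Identical library objects produce byte-identical files.
#'
#' @param lib a [SimulatedLibrary-class].
#' @param truth the matching [TruthSet-class].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the written paths.
#' @export
writeSimulatedData <- function(lib, truth, dir) {
    stopifnot(is(lib, "SimulatedLibrary"), is(truth, "TruthSet"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(fastq = file.path(dir, "reads.fastq"),
                  genome = file.path(dir, "genome.fa"),
                  truth = file.path(dir, "truth.tsv"),
                  gff = file.path(dir, "truth.gff3"))
    r <- lib@reads
    con <- file(paths$fastq, open = "wb")
    writeLines(paste0("@", r$id, " src:", r$sourceType, ":",
                      r$sourceName, "\n", r$sequence, "\n+\n", r$quality),
               con, sep = "\n")
    close(con)
    Biostrings::writeXStringSet(truth@genome, paths$genome)
    m <- truth@mirnas
    led <- rbind(
        data.frame(name = m$name, class = "miRNA", chrom = m$chrom,
                   start = m$start, end = m$end, strand = m$strand,
                   sequence = m$mature, stringsAsFactors = FALSE),
        data.frame(name = truth@ncrnas$name, class = truth@ncrnas$class,
                   chrom = truth@ncrnas$chrom,
                   start = truth@ncrnas$start, end = truth@ncrnas$end,
                   strand = "+", sequence = truth@ncrnas$sequence,
                   stringsAsFactors = FALSE))
    write.table(led, paths$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    gr <- GenomicRanges::GRanges(
        seqnames = led$chrom,
        ranges = IRanges::IRanges(start = led$start + 1L, end = led$end),
        strand = led$strand)
    S4Vectors::mcols(gr)$type <- ifelse(led$class == "miRNA",
                                        "miRNA", "ncRNA")
    S4Vectors::mcols(gr)$ID <- led$name
    rtracklayer::export(gr, paths$gff, format = "gff3")
    invisible(paths)
}

#' Write catalog FASTA files from a truth ledger
#'
#' `writeNcrnaCatalog` writes the planted ncRNA sequences as a
#' class-annotated FASTA (`>class|name`). `writeMatureCatalog` writes a
#' mature miRNA catalog containing the first `nConserved` planted
#' matures (these become "conserved" miRNAs for the pipeline) plus
#' `nDecoy` random decoy matures, so conserved assignment has both true
#' and absent entries to discriminate.
#'
#' @param truth a [TruthSet-class].
#' @param path output FASTA path.
#' @param nConserved planted matures to include.
#' @param nDecoy random decoy entries.
#' @param seed seed for decoy generation.
#' @return invisibly, the path.
#' @export
writeNcrnaCatalog <- function(truth, path) {
    nc <- truth@ncrnas
    writeLines(paste0(">", nc$class, "|", nc$name, "\n", nc$sequence),
               path)
    invisible(path)
}

#' @rdname writeNcrnaCatalog
#' @export
writeMatureCatalog <- function(truth, path, nConserved = 10L,
                               nDecoy = 30L, seed = 4L) {
    m <- truth@mirnas
    nConserved <- min(nConserved, nrow(m))
    ids <- sprintf("xxx-miR%03da", seq_len(nConserved + nDecoy))
    seqs <- withSeed(seed, c(m$mature[seq_len(nConserved)],
                             vapply(seq_len(nDecoy), function(i)
                                 .drawMature(sample(20:24, 1L)),
                                 character(1))))
    writeLines(paste0(">", ids, "\n", seqs), path)
    invisible(list(path = path,
                   conserved = setNames(ids[seq_len(nConserved)],
                                        m$name[seq_len(nConserved)])))
}
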