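# Plant-style miRNA target prediction: seed-weighted complementarity
# penalties with a fixed call cutoff.

#' Target scoring weights
#'
#' The widely used plant complementarity penalty scheme: 1.0 per
#' mismatch, 0.5 per G:U wobble, 2.0 per gap (gapped mode only), all
#' doubled at miRNA positions `seedStart`-`seedEnd` (counted from the
#' miRNA 5' end).
#'
#' @param mismatch,gu,gap penalty points.
#' @param seedStart,seedEnd 1-based inclusive seed-weighted region.
#' @param seedMult multiplier inside the seed-weighted region.
#' @return named list of weights.
#' @export
targetWeights <- function(mismatch = 1.0, gu = 0.5, gap = 2.0,
                          seedStart = 2L, seedEnd = 13L, seedMult = 2) {
    list(mismatch = mismatch, gu = gu, gap = gap,
         seedStart = as.integer(seedStart), seedEnd = as.integer(seedEnd),
         seedMult = seedMult)
}

# Pairing class of miRNA base m against target base t (both DNA
# alphabet, antiparallel partners): 0 = Watson-Crick, 1 = G:U wobble,
# 2 = mismatch.
.pairClass <- function(m, t) {
    wc <- (m == "A" & t == "T") | (m == "T" & t == "A") |
        (m == "G" & t == "C") | (m == "C" & t == "G")
    gu <- (m == "G" & t == "T") | (m == "T" & t == "G")
    ifelse(wc, 0L, ifelse(gu, 1L, 2L))
}

#' Score one miRNA target site
#'
#' Aligns the miRNA (5' to 3') antiparallel against a transcript window
#' (5' to 3'): miRNA position i faces site position `length(site) - i +
#' 1`. Each position contributes 0 for Watson-Crick complementarity,
#' `gu` for a G:U wobble and `mismatch` otherwise, doubled inside the
#' seed-weighted region. In the default ungapped mode the site should be
#' the same length as the miRNA; a longer site (up to +3 nt) leaves its
#' 5'-most bases as an unpenalized overhang, and miRNA positions beyond
#' a shorter site count as mismatches.
#'
#' @param mirna miRNA sequence, 5' to 3' (RNA or DNA alphabet).
#' @param site transcript window, 5' to 3'.
#' @param weights from [targetWeights()].
#' @return list with `score` and `alignment` (three strings: miRNA 3'
#'   to 5', pairing marks, site 5' to 3'; "|" Watson-Crick, "o" G:U,
#'   " " mismatch).
#' @examples
#' scoreSite("ACGUACGUACGUACGUACGUA",
#'           as.character(Biostrings::reverseComplement(
#'               Biostrings::DNAString("ACGTACGTACGTACGTACGTA"))))
#' @export
scoreSite <- function(mirna, site, weights = targetWeights()) {
    mirna <- normalizeDna(mirna)
    site <- normalizeDna(site)
    L <- nchar(mirna)
    Ls <- nchar(site)
    if (abs(Ls - L) > 3L)
        stop("site length must be within the miRNA length +/- 3")
    m <- strsplit(mirna, "")[[1L]]
    s <- strsplit(site, "")[[1L]]
    # miRNA position i faces site position Ls - i + 1
    faced <- Ls - seq_len(L) + 1L
    cls <- integer(L)
    ok <- faced >= 1L
    cls[!ok] <- 2L # miRNA overhangs a short site: mismatch
    cls[ok] <- .pairClass(m[ok], s[faced[ok]])
    mult <- ifelse(seq_len(L) >= weights$seedStart &
                       seq_len(L) <= weights$seedEnd, weights$seedMult, 1)
    pen <- c(0, weights$gu, weights$mismatch)[cls + 1L]
    score <- sum(pen * mult)
    marks <- c("|", "o", " ")[cls + 1L]
    alignment <- c(mirna3to5 = paste(rev(m), collapse = ""),
                   marks = paste(rev(marks), collapse = ""),
                   site5to3 = site)
    list(score = score, alignment = alignment)
}

#' Scan a transcript for target sites
#'
#' Slides a window of miRNA length over the transcript, scores every
#' window with [scoreSite()] and reports sites under the cutoff. In
#' gapped mode, windows one base longer are also tried with a single
#' 1-nt site bulge (penalized as a gap). Overlapping candidate sites
#' are resolved to the lower-scoring one (ties to the 5'-most);
#' surviving hits come back best score first.
#'
#' @param mirna miRNA sequence, 5' to 3'.
#' @param transcript transcript sequence, 5' to 3'.
#' @param cutoff score cutoff; a site is called when score < cutoff.
#' @param weights from [targetWeights()].
#' @param gapped also consider single 1-nt site bulges.
#' @return data.frame: start, end (0-based half-open on the
#'   transcript), score, alignment (the three alignment strings pasted
#'   with "/").
#' @export
scanTranscript <- function(mirna, transcript, cutoff = 3.0,
                           weights = targetWeights(), gapped = FALSE) {
    mirna <- normalizeDna(mirna)
    transcript <- normalizeDna(transcript)
    L <- nchar(mirna)
    n <- nchar(transcript)
    empty <- data.frame(start = integer(0), end = integer(0),
                        score = numeric(0), alignment = character(0),
                        stringsAsFactors = FALSE)
    if (n < L) stop("transcript shorter than the miRNA")
    mi <- match(utf8ToInt(mirna), c(65L, 67L, 71L, 84L)) # A C G T
    ti <- match(utf8ToInt(transcript), c(65L, 67L, 71L, 84L))
    # penalty lookup, miRNA base x target base
    pen <- matrix(weights$mismatch, 4L, 4L)
    pen[1L, 4L] <- 0; pen[4L, 1L] <- 0
    pen[3L, 2L] <- 0; pen[2L, 3L] <- 0
    pen[3L, 4L] <- weights$gu; pen[4L, 3L] <- weights$gu
    mult <- ifelse(seq_len(L) >= weights$seedStart &
                       seq_len(L) <= weights$seedEnd, weights$seedMult, 1)
    nWin <- n - L + 1L
    scores <- numeric(nWin)
    for (i in seq_len(L)) {
        # window w (1-based start) faces miRNA pos i with target base
        # at w + L - i
        idx <- seq_len(nWin) + L - i
        scores <- scores + mult[i] * pen[cbind(rep(mi[i], nWin), ti[idx])]
    }
    hits <- which(scores < cutoff)
    out <- if (length(hits)) data.frame(
        start = hits - 1L, end = hits - 1L + L, score = scores[hits],
        stringsAsFactors = FALSE) else empty[, 1:3]
    if (gapped && n >= L + 1L) {
        gm <- vapply(seq_len(n - L), function(w) {
            site <- substr(transcript, w, w + L)
            best <- Inf
            for (d in seq_len(L + 1L)) { # delete one site base (bulge)
                sg <- paste0(substr(site, 1L, d - 1L),
                             substr(site, d + 1L, L + 1L))
                sc <- scoreSite(mirna, sg, weights)$score
                # gap penalty at the bulged position, seed-doubled
                gpos <- L + 1L - d + 1L
                gmult <- if (gpos >= weights$seedStart &&
                             gpos <= weights$seedEnd) weights$seedMult
                    else 1
                best <- min(best, sc + weights$gap * gmult)
            }
            best
        }, numeric(1))
        gh <- which(gm < cutoff)
        if (length(gh))
            out <- rbind(out, data.frame(start = gh - 1L,
                                         end = gh - 1L + L + 1L,
                                         score = gm[gh],
                                         stringsAsFactors = FALSE))
    }
    if (nrow(out) == 0L) return(empty)
    # resolve overlaps: lower score wins, ties to the 5'-most site
    out <- out[order(out$score, out$start), , drop = FALSE]
    kept <- logical(nrow(out))
    for (i in seq_len(nrow(out)))
        kept[i] <- !any(kept & out$start < out$end[i] &
                            out$end > out$start[i])
    out <- out[kept, , drop = FALSE]
    out$alignment <- vapply(seq_len(nrow(out)), function(i) {
        site <- substr(transcript, out$start[i] + 1L, out$end[i])
        paste(scoreSite(mirna, site, weights)$alignment, collapse = "/")
    }, character(1))
    rownames(out) <- NULL
    out
}

#' Predict targets for a set of miRNAs
#'
#' Scans every (miRNA, transcript) pair with [scanTranscript()] and
#' returns all called sites plus per-family rollup counts.
#'
#' @param mirnas named character vector of miRNA sequences (names are
#'   ids), or a data.frame with id, sequence and optionally family.
#' @param transcripts a named [Biostrings::DNAStringSet] or named
#'   character vector.
#' @param cutoff score cutoff.
#' @param weights from [targetWeights()].
#' @param gapped passed to [scanTranscript()].
#' @return list: `hits` (data.frame mirna, transcript, start, end,
#'   score, alignment) and `families` (data.frame family, hits).
#' @export
predictTargets <- function(mirnas, transcripts, cutoff = 3.0,
                           weights = targetWeights(), gapped = FALSE) {
    if (is.data.frame(mirnas)) {
        fam <- if ("family" %in% names(mirnas)) mirnas$family else
            mirnas$id
        sq <- setNames(mirnas$sequence, mirnas$id)
        famMap <- setNames(fam, mirnas$id)
    } else {
        sq <- mirnas
        famMap <- setNames(names(mirnas), names(mirnas))
    }
    if (is(transcripts, "DNAStringSet"))
        transcripts <- setNames(as.character(transcripts),
                                names(transcripts))
    if (length(transcripts) == 0L) stop("empty transcriptome")
    rows <- list()
    for (mid in names(sq)) {
        for (tid in names(transcripts)) {
            h <- scanTranscript(sq[[mid]], transcripts[[tid]],
                                cutoff = cutoff, weights = weights,
                                gapped = gapped)
            if (nrow(h) > 0L)
                rows[[length(rows) + 1L]] <- cbind(
                    data.frame(mirna = mid, transcript = tid,
                               stringsAsFactors = FALSE), h)
        }
    }
    hits <- if (length(rows)) do.call(rbind, rows) else
        data.frame(mirna = character(0), transcript = character(0),
                   start = integer(0), end = integer(0),
                   score = numeric(0), alignment = character(0),
                   stringsAsFactors = FALSE)
    rownames(hits) <- NULL
    famHits <- if (nrow(hits) > 0L) {
        tb <- table(famMap[hits$mirna])
        data.frame(family = names(tb), hits = as.integer(tb),
                   stringsAsFactors = FALSE)
    } else data.frame(family = character(0), hits = integer(0),
                      stringsAsFactors = FALSE)
    list(hits = hits, families = famHits)
}
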