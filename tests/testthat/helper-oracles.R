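# Independent oracles and shared fixtures. Everything here is written
# against the definitions, not against the package internals: the fold
# oracle enumerates structures recursively, the duplex recount re-reads
# the dot-bracket string from scratch, and the site rescorer walks the
# two sequences position by position.

# Brute-force minimum free energy by unmemoized recursive enumeration of
# all properly nested structures (hairpin loops >= minloop, WC + GU
# pairs only). Exponential, fine for n <= 22.
oracleMfe <- function(seq, eGC = -3, eAU = -2, eGU = -1, minloop = 3) {
    s <- strsplit(chartr("U", "T", toupper(seq)), "")[[1]]
    pe <- function(a, b) {
        k <- paste0(a, b)
        if (k %in% c("GC", "CG")) eGC
        else if (k %in% c("AT", "TA")) eAU
        else if (k %in% c("GT", "TG")) eGU
        else NA_real_
    }
    rec <- function(i, j) {
        if (j - i < minloop + 1) return(0)
        b <- rec(i + 1, j)
        for (k in (i + minloop + 1):j) {
            e <- pe(s[i], s[k])
            if (!is.na(e))
                b <- min(b, e + rec(i + 1, k - 1) + rec(k + 1, j))
        }
        b
    }
    if (length(s) < minloop + 2) return(0)
    rec(1, length(s))
}

# Recompute the energy of a reported structure by summing pair energies
# off the dot-bracket string; also checks pair legality and loop size.
structureEnergy <- function(seq, db, eGC = -3, eAU = -2, eGU = -1,
                            minloop = 3) {
    s <- strsplit(chartr("U", "T", toupper(seq)), "")[[1]]
    ch <- strsplit(db, "")[[1]]
    stack <- integer(0)
    e <- 0
    for (i in seq_along(ch)) {
        if (ch[i] == "(") stack <- c(stack, i)
        else if (ch[i] == ")") {
            j <- stack[length(stack)]
            stack <- stack[-length(stack)]
            stopifnot(i - j - 1 >= minloop ||
                          any(ch[(j + 1):(i - 1)] != "."))
            k <- paste0(s[j], s[i])
            stopifnot(k %in% c("GC", "CG", "AT", "TA", "GT", "TG"))
            e <- e + switch(k, GC = eGC, CG = eGC, AT = eAU, TA = eAU,
                            GT = eGU, TG = eGU)
        }
    }
    stopifnot(length(stack) == 0)
    e
}

# Independent recount of duplex mismatches / asymmetric bulges for a
# mature at 1-based [mS, mE] on a dot-bracket structure.
recountDuplex <- function(db, mS, mE) {
    ch <- strsplit(db, "")[[1]]
    partner <- rep(NA_integer_, length(ch))
    st <- integer(0)
    for (i in seq_along(ch)) {
        if (ch[i] == "(") st <- c(st, i)
        else if (ch[i] == ")") {
            partner[st[length(st)]] <- i
            partner[i] <- st[length(st)]
            st <- st[-length(st)]
        }
    }
    p <- partner[mS:mE]
    paired <- which(!is.na(p))
    mism <- (mE - mS + 1) - length(paired)
    span <- seq(min(p[paired]), max(p[paired]))
    uS <- sum(is.na(partner[span]))
    interior <- seq(min(paired), max(paired))
    uM <- sum(is.na(p[interior]))
    list(mismatches = mism, bulges = abs(uS - uM))
}

# Independent per-position rescoring of a target site: walks the miRNA
# against the site antiparallel and sums penalties from scratch.
rescoreSite <- function(mirna, site, weights = targetWeights()) {
    m <- strsplit(chartr("U", "T", toupper(mirna)), "")[[1]]
    s <- strsplit(chartr("U", "T", toupper(site)), "")[[1]]
    tot <- 0
    for (i in seq_along(m)) {
        j <- length(s) - i + 1
        pen <- if (j < 1) weights$mismatch else {
            pair <- paste0(m[i], s[j])
            if (pair %in% c("AT", "TA", "GC", "CG")) 0
            else if (pair %in% c("GT", "TG")) weights$gu
            else weights$mismatch
        }
        if (i >= weights$seedStart && i <= weights$seedEnd)
            pen <- pen * weights$seedMult
        tot <- tot + pen
    }
    tot
}

rcChar <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# Build a small synthetic dataset on disk; returns truth, library and a
# ready pipeline config. Cached per parameter signature so several test
# files can share one simulation.
.simCache <- new.env(parent = emptyenv())
makeSim <- function(nMirna = 8, nNcrna = 5, nReads = 6000,
                    errorRate = 0, degradedFraction = 0,
                    chromLen = 60000, nConserved = 3, seed = 11) {
    key <- paste(nMirna, nNcrna, nReads, errorRate, degradedFraction,
                 chromLen, nConserved, seed, sep = "_")
    if (!is.null(.simCache[[key]])) return(.simCache[[key]])
    dir <- file.path(tempdir(), paste0("sim", key))
    g <- generateGenome(1, chromLen, gc = 0.44, seed = seed)
    tr <- plantHairpins(g, nMirna = nMirna, nStar = ceiling(nMirna / 2),
                        seed = seed + 1)
    tr <- plantNcrnas(tr, nNcrna = nNcrna, seed = seed + 2)
    lib <- simulateLibrary(tr, nReads = nReads,
                           errorRate = errorRate,
                           degradedFraction = degradedFraction,
                           seed = seed + 3)
    writeSimulatedData(lib, tr, dir)
    writeNcrnaCatalog(tr, file.path(dir, "ncrna.fa"))
    writeMatureCatalog(tr, file.path(dir, "mature.fa"),
                       nConserved = nConserved, seed = seed + 4)
    cfg <- pipelineConfig(reads = file.path(dir, "reads.fastq"),
                          genome = file.path(dir, "genome.fa"),
                          ncrnaCatalog = file.path(dir, "ncrna.fa"),
                          matureCatalog = file.path(dir, "mature.fa"))
    out <- list(truth = tr, lib = lib, dir = dir, cfg = cfg)
    .simCache[[key]] <- out
    out
}

# A FASTQ-style read data.frame with every base at the given quality.
fakeRead <- function(sequence, q = 35, quality = NULL) {
    data.frame(id = "r1", sequence = sequence,
               quality = quality %||%
                   strrep(intToUtf8(q + 33L), nchar(sequence)),
               stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
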