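test_that("foldRna reproduces hand-checked structures", {
    f <- foldRna("GGGAAAACCC")
    expect_equal(dotBracket(f), "(((....)))")
    expect_equal(mfe(f), -9.0) # three G:C pairs at -3 each

    f0 <- foldRna("AAAAAAAAAA")
    expect_equal(dotBracket(f0), "..........")
    expect_equal(mfe(f0), 0)

    expect_error(foldRna("ACGTACGTN"), "length|A, C, G, T")
    expect_error(foldRna(strrep("A", 500)), "length")
})

test_that("fold MFE matches exhaustive enumeration and structures are legal", {
    set.seed(404)
    for (i in 1:60) {
        n <- sample(10:18, 1)
        sq <- paste(sample(c("A", "C", "G", "T"), n, TRUE),
                    collapse = "")
        f <- foldRna(sq)
        expect_equal(mfe(f), oracleMfe(sq), label = sq)
        # the reported structure independently re-scores to its mfe
        expect_equal(structureEnergy(sq, dotBracket(f)), mfe(f),
                     label = sq)
    }
})

test_that("mapToGenome finds planted loci on both strands", {
    tag <- "ACGTTGCAACGGTTCAACGTA"
    chrom <- paste0(strrep("G", 1000), tag, strrep("C", 979))
    genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
    mp <- mapToGenome(SmallRNATagSet(tag), genome)
    expect_equal(nrow(mp$loci), 1L)
    expect_equal(mp$loci$start, 1000)
    expect_equal(mp$loci$end, 1021)
    expect_equal(mp$loci$strand, "+")

    rc <- rcChar(tag)
    mpr <- mapToGenome(SmallRNATagSet(rc), genome)
    expect_equal(mpr$loci$strand, "-")
    expect_equal(mpr$loci$start, 1000)

    absent <- mapToGenome(SmallRNATagSet(strrep("AT", 10)), genome)
    expect_equal(nrow(absent$loci), 0L)

    # repetitive tags are flagged and excluded
    rep25 <- paste(rep(c(strrep("T", 30), tag), 25), collapse = "")
    genome2 <- Biostrings::DNAStringSet(c(chr1 = rep25))
    mp2 <- mapToGenome(SmallRNATagSet(tag), genome2, maxLoci = 20)
    expect_equal(nrow(mp2$loci), 0L)
    expect_length(mp2$repetitive, 1L)
})

test_that("precursor windows follow the two-window rule and clip at bounds", {
    genome <- generateGenome(1, 2000, seed = 1)
    loci <- data.frame(tag_id = "t1", sequence = strrep("A", 21),
                       chrom = "chr1", start = 1000, end = 1021,
                       strand = "+", stringsAsFactors = FALSE)
    w <- excisePrecursors(loci, genome, flank = 150)
    expect_equal(w$winStart, c(850, 980))
    expect_equal(w$winEnd, c(1041, 1171))

    edge <- loci
    edge$start <- 5
    edge$end <- 26
    we <- excisePrecursors(edge, genome, flank = 150)
    expect_equal(we$winStart[1], 0)

    minus <- loci
    minus$strand <- "-"
    wm <- excisePrecursors(minus, genome, flank = 150)
    slice <- as.character(Biostrings::subseq(genome[[1]], 851, 1041))
    expect_equal(wm$window[1], rcChar(slice))
})

test_that("evaluateHairpin fails matures in the loop and weak stems", {
    # strong stem with the 'mature' laid across the terminal loop
    stem <- "GCGCGCGCGCATCGATCGATGC"
    prec <- paste0(stem, "CACACACC", rcChar(stem))
    midTag <- substr(prec, nchar(stem) - 5, nchar(stem) - 6 + 21)
    cand <- evaluateHairpin(list(window = prec, chrom = "c",
                                 winStart = 0, winEnd = nchar(prec),
                                 strand = "+"), midTag)
    expect_false(verdict(cand))
    expect_equal(cand@reason, "mature_in_loop")

    # a hairpin above the MFE threshold fails on energy
    tr <- plantHairpins(generateGenome(1, 60000, seed = 2), nMirna = 1,
                        seed = 3)
    m <- plantedMirnas(tr)
    prec2 <- as.character(Biostrings::subseq(
        truthGenome(tr)[[1]], m$precStart[1] + 1, m$precEnd[1]))
    if (m$strand[1] == "-") prec2 <- rcChar(prec2)
    strict <- evaluateHairpin(
        list(window = prec2, chrom = m$chrom[1],
             winStart = m$precStart[1], winEnd = m$precEnd[1],
             strand = m$strand[1]),
        m$mature[1],
        thresholds = hairpinThresholds(mfeMax = -1000))
    expect_false(verdict(strict))
    expect_equal(strict@reason, "mfe")

    expect_error(evaluateHairpin(list(window = prec2, chrom = "c",
                                      winStart = 0,
                                      winEnd = nchar(prec2),
                                      strand = "+"),
                                 strrep("T", 24)),
                 "not found")
})

test_that("reported duplex statistics are reproducible from the dot-bracket", {
    tr <- plantHairpins(generateGenome(1, 60000, seed = 12), nMirna = 6,
                        seed = 13)
    m <- plantedMirnas(tr)
    for (i in seq_len(nrow(m))) {
        prec <- as.character(Biostrings::subseq(
            truthGenome(tr)[[1]], m$precStart[i] + 1, m$precEnd[i]))
        if (m$strand[i] == "-") prec <- rcChar(prec)
        cand <- evaluateHairpin(
            list(window = prec, chrom = m$chrom[i],
                 winStart = m$precStart[i], winEnd = m$precEnd[i],
                 strand = m$strand[i]), m$mature[i])
        off <- cand@matureStart + 1
        rc <- recountDuplex(dotBracket(cand@fold), off,
                            off + nchar(m$mature[i]) - 1)
        expect_equal(cand@duplexMismatches, rc$mismatches)
        expect_equal(cand@bulgedBases, rc$bulges)
    }
})

test_that("miRNA* evidence is found within the 2 nt tolerance only", {
    tr <- plantHairpins(generateGenome(1, 60000, seed = 22), nMirna = 1,
                        seed = 23)
    m <- plantedMirnas(tr)
    genome <- truthGenome(tr)
    mp <- mapToGenome(SmallRNATagSet(c(m$mature[1], m$star[1]),
                                     c(10L, 2L)), genome)
    wins <- excisePrecursors(mp$loci[mp$loci$sequence == m$mature[1], ],
                             genome)
    cands <- lapply(seq_len(nrow(wins)), function(i)
        evaluateHairpin(wins[i, ], m$mature[1]))
    cand <- cands[[which.min(vapply(cands, function(x) mfe(x@fold),
                                    numeric(1)))]]
    expect_true(verdict(cand))
    withStar <- findStar(cand, mp$loci)
    expect_true(withStar@hasStarRead)

    # remove the star tag: no support
    noStar <- findStar(cand,
                       mp$loci[mp$loci$sequence == m$mature[1], ])
    expect_false(noStar@hasStarRead)

    # shift the star locus by exactly 2 nt: still accepted; 3 nt: not
    starLoci <- mp$loci[mp$loci$sequence == m$star[1], ]
    shifted2 <- starLoci
    shifted2$start <- shifted2$start + 2L
    shifted2$end <- shifted2$end + 2L
    expect_true(findStar(cand, shifted2)@hasStarRead)
    shifted3 <- starLoci
    shifted3$start <- shifted3$start + 3L
    shifted3$end <- shifted3$end + 3L
    expect_false(findStar(cand, shifted3)@hasStarRead)
})

test_that("family clustering is greedy star-linkage at two substitutions", {
    base <- "ACGTACGTACGTACGTACGTA"
    sub1 <- paste0("T", substr(base, 2, 21))
    sub2 <- paste0("G", substr(base, 2, 21))
    fams <- clusterFamilies(data.frame(
        sequence = c(base, sub1, sub2), count = c(10L, 5L, 2L),
        stringsAsFactors = FALSE))
    expect_equal(length(unique(fams$family)), 1L)
    expect_equal(fams$family[1], "miRn001")
    expect_true(fams$is_seed[fams$sequence == base])

    far <- chartr("ACGTA", "TGACC", base)
    fams2 <- clusterFamilies(data.frame(
        sequence = c(base, far), count = c(1L, 1L),
        stringsAsFactors = FALSE))
    expect_equal(length(unique(fams2$family)), 2L)

    expect_equal(nrow(clusterFamilies(NULL)), 0L)

    # different lengths never merge
    fams3 <- clusterFamilies(data.frame(
        sequence = c(base, substr(base, 1, 20)), count = c(2L, 1L),
        stringsAsFactors = FALSE))
    expect_equal(length(unique(fams3$family)), 2L)
})

test_that("minus-strand discovery equals plus-strand discovery of the reverse complement", {
    tr <- plantHairpins(generateGenome(1, 40000, seed = 31), nMirna = 2,
                        seed = 32)
    m <- plantedMirnas(tr)
    genome <- truthGenome(tr)
    rcGenome <- Biostrings::reverseComplement(genome)
    names(rcGenome) <- names(genome)
    tags <- SmallRNATagSet(m$mature, rep(5L, nrow(m)))
    d1 <- discoverNovel(tags, genome, minCount = 1L)
    d2 <- discoverNovel(tags, rcGenome, minCount = 1L)
    c1 <- d1$candidates[order(d1$candidates$sequence), ]
    c2 <- d2$candidates[order(d2$candidates$sequence), ]
    expect_equal(c1$verdict, c2$verdict)
    expect_equal(c1$mfe, c2$mfe)
    expect_equal(c1$duplexMismatches, c2$duplexMismatches)
    # mirrored loci fall inside the same planted precursor: the best
    # window for a tag may sit on either duplex arm when MFEs tie, so
    # containment, not coordinate identity, is the invariant
    len <- Biostrings::width(genome)[1]
    for (i in seq_len(nrow(c2))) {
        mirStart <- len - c2$matureEnd[i]
        row <- m[m$mature == c2$sequence[i], ]
        expect_true(mirStart >= row$precStart - 3 &
                        mirStart <= row$precEnd + 3)
    }
})
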