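ADAPT <- "TGGAATTCTCGGGTGCCAAGG"

test_that("adapter trimming removes suffixes, flags dimers and tolerates mismatches", {
    insert <- "ACGTACGTACGTACGTACGT" # 20 nt
    rd <- fakeRead(paste0(insert, ADAPT))
    tr <- trimAdapter(rd, ADAPT)
    expect_equal(tr$sequence, insert)
    expect_equal(nchar(tr$quality), nchar(insert))
    expect_equal(tr$adapterFlag, "trimmed")

    dimer <- trimAdapter(fakeRead(ADAPT), ADAPT)
    expect_equal(dimer$adapterFlag, "dimer")

    # 10 nt adapter prefix with one substitution: allowed (1 per 7 nt)
    ap10 <- paste0(substr(ADAPT, 1, 4), "C", substr(ADAPT, 6, 10))
    expect_false(substr(ADAPT, 5, 5) == "C")
    tr1 <- trimAdapter(fakeRead(paste0(insert, ap10)), ADAPT)
    expect_equal(tr1$sequence, insert)

    # two substitutions in 10 nt: not trimmed
    ap2 <- paste0("AA", substr(ADAPT, 3, 10))
    tr2 <- trimAdapter(fakeRead(paste0(insert, ap2)), ADAPT)
    expect_equal(tr2$adapterFlag, "no_adapter")
    expect_equal(nchar(tr2$sequence), 30L)

    expect_error(trimAdapter(rd, ""), "adapter")
})

test_that("the whole-read quality filter sits exactly at the stated boundaries", {
    mk <- function(qs) {
        n <- length(qs)
        fakeRead(strrep("C", n), quality = intToUtf8(qs + 33L))
    }
    # 4 bases at Q9 and 6 at Q12, rest high: passes
    qs <- c(rep(9L, 4), rep(12L, 6), rep(35L, 10))
    expect_equal(qualityFilter(mk(qs)), "pass")
    # 5 bases at Q9: fails the Q10 rule
    expect_equal(qualityFilter(mk(c(rep(9L, 5), rep(35L, 15)))),
                 "low_quality_q10")
    # 7 bases at Q12: fails the Q13 rule
    expect_equal(qualityFilter(mk(c(rep(12L, 7), rep(35L, 13)))),
                 "low_quality_q13")
    # any N fails regardless of quality
    rd <- fakeRead(paste0("ACGTN", strrep("A", 15)), q = 40)
    expect_equal(qualityFilter(rd), "contains_N")
    # malformed record
    bad <- data.frame(id = "x", sequence = "ACGT", quality = "III")
    expect_error(qualityFilter(bad), "length")
})

test_that("the length window is inclusive at 16 and 30", {
    expect_equal(lengthFilter(strrep("A", c(15, 16, 30, 31))),
                 c(FALSE, TRUE, TRUE, FALSE))
})

test_that("collapsing conserves reads and orders tags by count then sequence", {
    reads <- c(rep("ACGTACGTACGTACGTA", 3), "TTTTGTTTTGTTTTGT")
    tags <- collapseTags(reads)
    expect_equal(length(tags), 2L)
    expect_equal(tagCount(tags), c(3L, 1L))
    expect_equal(tagSequence(tags)[1L], "ACGTACGTACGTACGTA")

    expect_equal(length(collapseTags(character(0))), 0L)

    # conservation against a brute-force dictionary count, and order
    # invariance of the tag multiset
    set.seed(1)
    pool <- vapply(1:30, function(i)
        paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""),
        character(1))
    rnd <- sample(pool, 500, replace = TRUE)
    tg <- collapseTags(rnd)
    expect_equal(sum(tagCount(tg)), length(rnd))
    dict <- table(rnd)
    expect_equal(tagCount(tg)[match(names(dict), tagSequence(tg))],
                 unname(as.integer(dict)))
    tg2 <- collapseTags(rev(rnd))
    expect_identical(as.data.frame(tg), as.data.frame(tg2))

    # idempotence: collapsing already-unique tags is the identity
    tg3 <- SmallRNATagSet(tagSequence(tg), tagCount(tg))
    expect_identical(as.data.frame(tg3), as.data.frame(tg))
})

test_that("runReadQc never loses or duplicates a read", {
    sim <- makeSim(nReads = 3000, errorRate = 0.002,
                   degradedFraction = 0.05, seed = 21)
    qc <- runReadQc(file.path(sim$dir, "reads.fastq"))
    rep <- qc$report
    expect_equal(rawReads(rep),
                 cleanReads(rep) + sum(rejectionTally(rep)))
    expect_equal(sum(lengthHistogram(rep)), cleanReads(rep))
    expect_equal(sum(tagCount(qc$tags)), cleanReads(rep))
    # degraded reads were planted, so some rejections must be observed
    expect_gt(sum(rejectionTally(rep)), 0L)
})
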