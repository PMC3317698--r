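test_that("site scoring matches the penalty scheme worked examples", {
    mir <- "ACGGAGCTAGCTAGCTAGGAT" # 21 nt
    perfect <- rcChar(mir)
    expect_equal(scoreSite(mir, perfect)$score, 0)

    # one G:U wobble at miRNA position 18 (outside the seed-weighted
    # region): site base T facing miRNA G scores 0.5
    s <- strsplit(perfect, "")[[1]]
    pos <- nchar(mir) - 18 + 1
    expect_equal(substr(mir, 18, 18), "G")
    s[pos] <- "T"
    expect_equal(scoreSite(mir, paste(s, collapse = ""))$score, 0.5)

    # one mismatch at miRNA position 5 (seed-weighted): 1.0 x 2
    s2 <- strsplit(perfect, "")[[1]]
    pos5 <- nchar(mir) - 5 + 1
    s2[pos5] <- chartr("ACGT", "GTAC", s2[pos5]) # breaks the pair
    expect_equal(scoreSite(mir, paste(s2, collapse = ""))$score, 2.0)

    expect_error(scoreSite(mir, substr(perfect, 1, 10)), "length")
})

test_that("transcript scanning reports rescorable non-overlapping hits", {
    set.seed(7)
    mir <- paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = "")
    bg <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
    tx <- paste0(substr(bg, 1, 200), rcChar(mir), substr(bg, 201, 500))
    hits <- scanTranscript(mir, tx)
    stopifnot(nrow(hits) >= 1)
    expect_equal(hits$score[1], 0)
    expect_equal(hits$start[1], 200)
    expect_equal(hits$end[1], 221)

    # every reported hit rescores exactly with the independent rescorer
    for (i in seq_len(nrow(hits))) {
        site <- substr(tx, hits$start[i] + 1, hits$end[i])
        expect_equal(rescoreSite(mir, site), hits$score[i])
        expect_lt(hits$score[i], 3.0)
    }

    # cutoff 0 never calls anything (scores are >= 0)
    expect_equal(nrow(scanTranscript(mir, bg, cutoff = 0)), 0L)

    # score is invariant to transcript coordinate offset
    padded <- paste0(strrep("A", 57), tx)
    h2 <- scanTranscript(mir, padded)
    expect_equal(h2$start[1], 257)
    expect_equal(h2$score[1], hits$score[1])
})

test_that("adding a mismatch never decreases the site score", {
    set.seed(9)
    mir <- paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = "")
    site <- rcChar(mir)
    sc <- scoreSite(mir, site)$score
    for (k in 1:21) {
        s <- strsplit(site, "")[[1]]
        s[k] <- setdiff(c("A", "C", "G", "T"), s[k])[1]
        worse <- scoreSite(mir, paste(s, collapse = ""))$score
        expect_gte(worse, sc)
    }
})

test_that("predictTargets recovers planted perfect sites and rolls up families", {
    set.seed(11)
    mirs <- setNames(vapply(1:5, function(i)
        paste(sample(c("A", "C", "G", "T"), 21, TRUE), collapse = ""),
        character(1)), paste0("mir", 1:5))
    txs <- setNames(vapply(1:2, function(i)
        paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""),
        character(1)), paste0("tx", 1:2))
    # plant each miRNA's perfect complement once in tx1
    planted <- txs
    insert <- paste(vapply(mirs, rcChar, character(1)), collapse = "")
    planted["tx1"] <- paste0(txs[["tx1"]], insert)
    res <- predictTargets(mirs, planted)
    perfectHits <- res$hits[res$hits$score == 0, ]
    expect_equal(sort(unique(perfectHits$mirna)), sort(names(mirs)))
    expect_equal(sum(res$families$hits), nrow(res$hits))

    expect_error(predictTargets(mirs, character(0)), "transcriptome")

    # short random transcripts essentially never score under 3
    rnd <- predictTargets(mirs["mir1"], txs["tx2"])
    expect_lte(nrow(rnd$hits), 1L)
})
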