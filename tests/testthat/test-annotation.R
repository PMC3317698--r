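test_that("poly-A artifacts are dropped by tail and composition rules", {
    expect_false(polyaFilter(strrep("A", 16)))
    expect_true(polyaFilter("ACGTACGTACGTACGT"))
    expect_false(polyaFilter(paste0("ACGTACGT", strrep("A", 10))))
    # 79% A without an 8-A tail is kept
    expect_true(polyaFilter("AAAAAAACAAAAAAGCT"))
})

test_that("ncRNA classification uses exact containment with class precedence", {
    shared <- "GGATCCGGTTAACCGGATCG"
    cat <- data.frame(
        class = c("tRNA", "rRNA"),
        name = c("trna1", "rrna1"),
        sequence = c(paste0("TTTT", shared, "CCCC"),
                     paste0("AAAA", shared, "GGGG")),
        stringsAsFactors = FALSE)
    # containment
    expect_equal(classifyNcrna(shared, cat), "rRNA") # precedence
    expect_equal(classifyNcrna(paste0("TTTT", shared), cat), "tRNA")
    # reverse complement also matches
    expect_equal(classifyNcrna(rcChar(shared), cat), "rRNA")
    # one mismatch breaks the exact-substring rule
    mm <- paste0(substr(shared, 1, 10), "G", substr(shared, 12, 20))
    expect_false(mm == shared)
    expect_true(is.na(classifyNcrna(mm, cat)))
    expect_error(classifyNcrna("ACGT", cat[0, ]), "empty")
})

test_that("catalog loaders validate headers and derive families", {
    p <- tempfile(fileext = ".fa")
    writeLines(c(">rRNA|r1", "ACGUACGUACGUACGUACGUACGU",
                 ">repeat|rep1", "GGGTTTGGGTTTGGGTTT"), p)
    cat <- loadNcrnaCatalog(p)
    expect_equal(cat$class, c("rRNA", "repeat"))
    expect_equal(cat$sequence[1], "ACGTACGTACGTACGTACGTACGT") # U -> T
    writeLines(c(">lncRNA|x", "ACGT"), p)
    expect_error(loadNcrnaCatalog(p), "unknown ncRNA class")

    expect_equal(mirnaFamily(c("hvu-miR156a", "hvu-miR156d-3p",
                               "osa-miR396", "miRn001")),
                 c("miR156", "miR156", "miR396", "miRn001"))
})

test_that("conserved matching is mismatch-bounded with deterministic ties", {
    cat <- data.frame(
        id = c("aaa-miR001a", "aaa-miR002a"),
        family = c("miR001", "miR002"),
        sequence = c("ACGTACGTACGTACGTACGTA", "TGCATGCATGCATGCATGCAT"),
        stringsAsFactors = FALSE)
    exact <- matchConserved("ACGTACGTACGTACGTACGTA", cat)
    expect_equal(exact$mirna_id, "aaa-miR001a")
    expect_equal(exact$mismatches, 0L)
    expect_equal(exact$match_type, "exact")

    two <- matchConserved("TTGTACGTACGTACGTACGTA", cat)
    expect_equal(two$mismatches, 2L)
    expect_equal(two$match_type, "variant")

    none <- matchConserved("TTTTACGTACGTACGTACGTA", cat)
    expect_equal(nrow(none), 0L)

    # equidistant from both entries: lexicographically smallest id wins
    cat2 <- data.frame(id = c("aaa-miR009a", "aaa-miR002a"),
                       family = c("miR009", "miR002"),
                       sequence = c("AAAAAAAAAACCCCCCCCCC",
                                    "AAAAAAAAAACCCCCCCCCC"),
                       stringsAsFactors = FALSE)
    cat2 <- cat2[order(cat2$id), ]
    tie <- matchConserved("AAAAAAAAAACCCCCCCCCG", cat2)
    expect_equal(tie$mirna_id, "aaa-miR002a")

    # a 2 nt length difference is absorbed as terminal overhang
    shift <- matchConserved(substr(cat$sequence[1], 1, 19), cat)
    expect_equal(shift$mirna_id, "aaa-miR001a")
    expect_equal(shift$mismatches, 0L)
})

test_that("family abundance sums member read counts", {
    calls <- data.frame(
        tag_id = c("t1", "t2"), sequence = c("A", "B"),
        count = c(2L, 165000L),
        mirna_id = c("hvu-miR167a", "hvu-miR167d"),
        family = "miR167", mismatches = 0L, match_type = "exact",
        stringsAsFactors = FALSE)
    fa <- familyAbundance(calls)
    expect_equal(fa$reads, 165002L)
    expect_equal(fa$members, 2L)
    expect_equal(nrow(familyAbundance(calls[0, ])), 0L)
    expect_equal(sum(fa$reads), sum(calls$count))
})

test_that("category percentages reproduce published-scale arithmetic", {
    u <- c(miRNA = 23239, rRNA = 83300, "repeat" = 23642, snRNA = 3020,
           snoRNA = 1872, tRNA = 16957, unannotated = 3893194)
    r <- c(miRNA = 625232, rRNA = 1006189, "repeat" = 90970,
           snRNA = 15180, snoRNA = 6711, tRNA = 1154444,
           unannotated = 6641836)
    tb <- categoryTable(u, r)
    pick <- function(cat, col) tb[tb$category == cat, col]
    expect_equal(pick("total", "unique_tags"), 4045224)
    expect_equal(pick("total", "total_reads"), 9540562)
    expect_equal(pick("miRNA", "unique_percent"), 0.57)
    expect_equal(pick("miRNA", "total_percent"), 6.55)
    expect_equal(pick("tRNA", "total_percent"), 12.10)
    expect_equal(pick("unannotated", "unique_percent"), 96.24)
    expect_equal(pick("unannotated", "total_percent"), 69.62)
})

test_that("buildCategoryTable partitions tags exactly once", {
    tags <- SmallRNATagSet(c(rep("ACGTACGTACGTACGTA", 3),
                             rep("GGGGCCCCGGGGCCCC", 2),
                             "TTTTGGGGTTTTGGGG"))
    ncls <- c(NA, "rRNA", NA)[match(tagSequence(tags),
        c("ACGTACGTACGTACGTA", "GGGGCCCCGGGGCCCC",
          "TTTTGGGGTTTTGGGG"))]
    calls <- data.frame(tag_id = tagId(tags)[1], sequence = "x",
                        count = 3L, mirna_id = "m", family = "f",
                        mismatches = 0L, match_type = "exact",
                        stringsAsFactors = FALSE)
    tb <- buildCategoryTable(tags, ncls, calls)
    body <- tb[tb$category != "total", ]
    expect_equal(sum(body$unique_tags),
                 tb$unique_tags[tb$category == "total"])
    expect_equal(sum(body$total_reads),
                 tb$total_reads[tb$category == "total"])
    expect_equal(tb$unique_tags[tb$category == "miRNA"], 1)
    expect_equal(tb$total_reads[tb$category == "rRNA"], 2)

    # single tag, single category
    one <- buildCategoryTable(SmallRNATagSet("ACGTACGTACGTACGTA"),
                              NA_character_,
                              calls[0, ])
    expect_equal(one$unique_percent[one$category == "unannotated"], 100)
    expect_equal(sum(one$unique_percent[!one$category %in%
                                            c("total", "unannotated")]), 0)

    # a conserved call on an ncRNA-classified tag is a consistency error
    expect_error(buildCategoryTable(tags, c("rRNA", "rRNA", NA), calls),
                 "consistency")
})
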