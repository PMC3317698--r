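test_that("generateGenome honours the size contract and is deterministic", {
    g <- generateGenome(1, 10000, gc = 0.5, seed = 42)
    expect_length(g, 1L)
    expect_equal(Biostrings::width(g), 10000L)
    expect_false(grepl("[^ACGT]", as.character(g[[1L]])))

    g1 <- generateGenome(2, 5000, gc = 0.5, seed = 42)
    g2 <- generateGenome(2, 5000, gc = 0.5, seed = 42)
    expect_identical(as.character(g1), as.character(g2))

    expect_error(generateGenome(0, 10000), "nChrom")
    expect_error(generateGenome(1, 10), "chromLen")
    expect_error(generateGenome(1, 10000, gc = 1.2), "gc")
})

test_that("generated GC content is within the binomial bound", {
    g <- generateGenome(1, 100000, gc = 0.44, seed = 7)
    fr <- Biostrings::letterFrequency(g[[1L]], "GC", as.prob = TRUE)
    expect_lt(abs(fr - 0.44), 0.02)
})

test_that("planted precursors satisfy the hairpin criteria by construction", {
    g <- generateGenome(1, 60000, gc = 0.44, seed = 5)
    tr <- plantHairpins(g, nMirna = 10, seed = 6)
    m <- plantedMirnas(tr)
    expect_equal(nrow(m), 10L)
    gen <- truthGenome(tr)
    for (i in seq_len(nrow(m))) {
        prec <- as.character(Biostrings::subseq(
            gen[[m$chrom[i]]], m$precStart[i] + 1L, m$precEnd[i]))
        if (m$strand[i] == "-") prec <- rcChar(prec)
        cand <- evaluateHairpin(
            list(window = prec, chrom = m$chrom[i],
                 winStart = m$precStart[i], winEnd = m$precEnd[i],
                 strand = m$strand[i]),
            m$mature[i])
        expect_true(verdict(cand), label = m$name[i])
        expect_identical(starSequence(cand), m$star[i])
    }
})

test_that("mature and star arms never overlap on the precursor", {
    tr <- plantHairpins(generateGenome(1, 60000, seed = 1),
                        nMirna = 10, seed = 2)
    m <- plantedMirnas(tr)
    expect_true(all(pmin(m$end, m$starEnd) <=
                        pmax(m$start, m$starStart)))
    expect_true(all(nchar(m$mature) >= 20 & nchar(m$mature) <= 24))
})

test_that("planting is deterministic and nMirna = 0 is a no-op", {
    g <- generateGenome(1, 60000, seed = 3)
    t1 <- plantHairpins(g, nMirna = 6, seed = 9)
    t2 <- plantHairpins(g, nMirna = 6, seed = 9)
    expect_identical(plantedMirnas(t1), plantedMirnas(t2))
    expect_identical(as.character(truthGenome(t1)),
                     as.character(truthGenome(t2)))

    t0 <- plantHairpins(g, nMirna = 0, seed = 9)
    expect_identical(as.character(truthGenome(t0)), as.character(g))
    expect_equal(nrow(plantedMirnas(t0)), 0L)

    expect_error(plantHairpins(generateGenome(1, 1000, seed = 1),
                               nMirna = 50),
                 "insufficient genome space")
})

test_that("simulateLibrary respects its contracts", {
    sim <- makeSim()
    tr <- sim$truth
    expect_error(simulateLibrary(tr, errorRate = 1.5), "errorRate")

    l0 <- simulateLibrary(tr, nReads = 0, seed = 1)
    expect_equal(nrow(libraryReads(l0)), 0L)

    # with no errors and no degradation, each miRNA read's insert is
    # exactly its source sequence
    r <- libraryReads(sim$lib)
    m <- plantedMirnas(tr)
    src <- ifelse(r$sourceType == "mature",
                  m$mature[match(r$sourceName, m$name)],
                  ifelse(r$sourceType == "star",
                         m$star[match(r$sourceName, m$name)], NA))
    sel <- !is.na(src)
    expect_true(all(substr(r$sequence[sel], 1L, r$insertLength[sel]) ==
                        src[sel]))
    expect_true(all(r$nErrors[sel] == 0L))
})

test_that("the ncRNA read fraction matches the requested fraction", {
    g <- generateGenome(1, 100000, gc = 0.44, seed = 42)
    tr <- plantHairpins(g, nMirna = 30, seed = 7)
    tr <- plantNcrnas(tr, nNcrna = 10, seed = 8)
    lib <- simulateLibrary(tr, nReads = 50000, ncrnaFraction = 0.3,
                           seed = 1)
    frac <- mean(libraryReads(lib)$sourceType == "ncrna")
    expect_lt(abs(frac - 0.3), 0.01)
})

test_that("identical seeds give byte-identical FASTQ output", {
    sim <- makeSim()
    lib2 <- simulateLibrary(sim$truth, nReads = 6000, errorRate = 0,
                            degradedFraction = 0, seed = 11 + 3)
    d2 <- file.path(tempdir(), "sim_rerun")
    writeSimulatedData(lib2, sim$truth, d2)
    expect_identical(unname(tools::md5sum(file.path(d2, "reads.fastq"))),
                     unname(tools::md5sum(file.path(sim$dir,
                                                    "reads.fastq"))))
})
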