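# The default benchmark simulation: 30 planted miRNA hairpins (15
# emitting miRNA* reads, 10 listed in the mature catalog as conserved),
# 10 ncRNA loci, 50,000 reads at error rate 0.001 with quality-degraded
# reads included. Built once per test run and cached.
.bigSimCache <- new.env(parent = emptyenv())

bigSim <- function() {
    if (!is.null(.bigSimCache$sim)) return(.bigSimCache$sim)
    dir <- file.path(tempdir(), "bigsim")
    g <- generateGenome(1, 100000, gc = 0.44, seed = 42)
    tr <- plantHairpins(g, nMirna = 30, nStar = 15, seed = 7)
    tr <- plantNcrnas(tr, nNcrna = 10, seed = 8)
    lib <- simulateLibrary(tr, nReads = 50000, ncrnaFraction = 0.3,
                           errorRate = 0.001, seed = 3)
    writeSimulatedData(lib, tr, dir)
    writeNcrnaCatalog(tr, file.path(dir, "ncrna.fa"))
    writeMatureCatalog(tr, file.path(dir, "mature.fa"),
                       nConserved = 10, seed = 4)
    cfg <- pipelineConfig(reads = file.path(dir, "reads.fastq"),
                          genome = file.path(dir, "genome.fa"),
                          ncrnaCatalog = file.path(dir, "ncrna.fa"),
                          matureCatalog = file.path(dir, "mature.fa"))
    res <- runPipeline(cfg)
    .bigSimCache$sim <- list(truth = tr, lib = lib, dir = dir,
                             cfg = cfg, result = res)
    .bigSimCache$sim
}
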