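# Pipeline orchestration: one reproducible run over all stages, plus
# the recovery scorecard against a synthetic truth ledger.

#' Pipeline configuration
#'
#' Flat configuration for [runPipeline()]. Every parameter defaults to
#' the package-wide stage defaults; paths may be NULL when a stage is
#' skipped (expression) or when objects are passed directly.
#'
#' @param reads FASTQ path (or data.frame from [readSmallRnaFastq()]).
#' @param genome genome FASTA path or [Biostrings::DNAStringSet].
#' @param ncrnaCatalog,matureCatalog catalog FASTA paths (or loaded
#'   data.frames).
#' @param transcripts optional transcript FASTA path or DNAStringSet
#'   for target prediction.
#' @param ctTable optional CT TSV path for the expression stage.
#' @param adapter,phredOffset read QC parameters.
#' @param flank,mfeMax,maxLoci,minCount hairpin discovery parameters.
#' @param cutoff target-call cutoff.
#' @param outDir optional output directory; when given, stage outputs
#'   and a manifest are written there.
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(reads, genome, ncrnaCatalog, matureCatalog,
                           transcripts = NULL, ctTable = NULL,
                           adapter = "TGGAATTCTCGGGTGCCAAGG",
                           phredOffset = 33L, flank = 150L, mfeMax = -18,
                           maxLoci = 20L, minCount = 2L, cutoff = 3.0,
                           outDir = NULL) {
    cfg <- list(reads = reads, genome = genome,
                ncrnaCatalog = ncrnaCatalog,
                matureCatalog = matureCatalog,
                transcripts = transcripts, ctTable = ctTable,
                adapter = adapter, phredOffset = as.integer(phredOffset),
                flank = as.integer(flank), mfeMax = mfeMax,
                maxLoci = as.integer(maxLoci),
                minCount = as.integer(minCount), cutoff = cutoff,
                outDir = outDir)
    required <- c("reads", "genome", "ncrnaCatalog", "matureCatalog")
    for (f in required)
        if (is.null(cfg[[f]]))
            stop("configuration error: required field '", f,
                 "' is missing")
    for (f in required) {
        v <- cfg[[f]]
        if (is.character(v) && length(v) == 1L && !file.exists(v))
            stop("configuration error: '", f, "' path does not exist: ",
                 v)
    }
    class(cfg) <- "PipelineConfig"
    cfg
}

.loadGenome <- function(x) {
    if (is(x, "DNAStringSet")) x else Biostrings::readDNAStringSet(x)
}

#' Run the full pipeline
#'
#' Executes read QC, poly-A removal, ncRNA classification, conserved
#' miRNA assignment, the category table, novel-miRNA discovery, and
#' (when inputs are configured) target prediction and the expression
#' summary. A manifest records parameter values, input checksums and
#' per-stage tag counts; a rerun with the same inputs and parameters is
#' bit-identical.
#'
#' @param config a [pipelineConfig()].
#' @param verbose log one line per stage.
#' @return list: qc, tags (post-filter [SmallRNATagSet-class]),
#'   ncrnaClass, conserved, conservedFamilies, categoryTable, novel,
#'   targets, expression, manifest.
#' @export
runPipeline <- function(config, verbose = FALSE) {
    stopifnot(inherits(config, "PipelineConfig"))
    say <- function(...) if (verbose) message(sprintf(...))
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    qc <- stage("qc", runReadQc(config$reads, adapter = config$adapter,
                                offset = config$phredOffset))
    say("qc: %d raw -> %d clean reads, %d tags",
        rawReads(qc$report), cleanReads(qc$report), length(qc$tags))
    tagsAll <- qc$tags
    keepPolya <- polyaFilter(tagSequence(tagsAll))
    tags <- tagsAll[which(keepPolya)]
    say("polya: %d tags dropped", sum(!keepPolya))
    ncCat <- stage("annotate", if (is.data.frame(config$ncrnaCatalog))
        config$ncrnaCatalog else loadNcrnaCatalog(config$ncrnaCatalog))
    matCat <- stage("annotate", if (is.data.frame(config$matureCatalog))
        config$matureCatalog else loadMatureCatalog(config$matureCatalog))
    ncClass <- stage("annotate", classifyNcrna(tagSequence(tags), ncCat))
    candIdx <- which(is.na(ncClass))
    conserved <- stage("annotate",
                       matchConserved(tags[candIdx], matCat))
    say("annotate: %d ncRNA tags, %d conserved calls",
        sum(!is.na(ncClass)), nrow(conserved))
    catTable <- buildCategoryTable(tags, ncClass, conserved)
    consFam <- familyAbundance(conserved)
    genome <- .loadGenome(config$genome)
    unannIdx <- setdiff(candIdx,
                        which(tagId(tags) %in% conserved$tag_id))
    consIdx <- which(tagId(tags) %in% conserved$tag_id)
    novel <- stage("discover", discoverNovel(
        tags[unannIdx], genome,
        thresholds = hairpinThresholds(mfeMax = config$mfeMax),
        flank = config$flank, maxLoci = config$maxLoci,
        minCount = config$minCount,
        extraStarTags = if (length(consIdx)) tags[consIdx] else NULL))
    say("discover: %d candidates, %d passing, %d families",
        nrow(novel$candidates), sum(novel$candidates$verdict),
        length(unique(novel$families$family)))
    targets <- NULL
    if (!is.null(config$transcripts)) {
        tx <- if (is(config$transcripts, "DNAStringSet"))
            config$transcripts else
                Biostrings::readDNAStringSet(config$transcripts)
        mirSet <- novel$candidates[novel$candidates$verdict, ,
                                   drop = FALSE]
        mirnas <- c(setNames(matCat$sequence, matCat$id),
                    setNames(mirSet$sequence, mirSet$tag_id))
        targets <- stage("targets", predictTargets(
            mirnas, tx, cutoff = config$cutoff))
        say("targets: %d hits", nrow(targets$hits))
    }
    expr <- NULL
    if (!is.null(config$ctTable)) {
        expr <- stage("expression",
                      summarizeExpression(readCtTable(config$ctTable)))
        say("expression: %d miRNA x sample cells",
            nrow(expr$perMirna))
    }
    manifest <- list(
        parameters = config[c("adapter", "phredOffset", "flank",
                              "mfeMax", "maxLoci", "minCount",
                              "cutoff")],
        inputs = .inputChecksums(config),
        counts = list(
            raw_reads = rawReads(qc$report),
            clean_reads = cleanReads(qc$report),
            unique_tags = length(tagsAll),
            polya_dropped = sum(!keepPolya),
            ncrna_tags = sum(!is.na(ncClass)),
            conserved_calls = nrow(conserved),
            novel_candidates = nrow(novel$candidates),
            novel_passing = sum(novel$candidates$verdict),
            novel_families = length(unique(novel$families$family))))
    res <- list(qc = qc$report, tags = tags, ncrnaClass = ncClass,
                conserved = conserved, conservedFamilies = consFam,
                categoryTable = catTable, novel = novel,
                targets = targets, expression = expr,
                manifest = manifest)
    if (!is.null(config$outDir)) .writeRun(res, config)
    res
}

.inputChecksums <- function(config) {
    paths <- Filter(function(x) is.character(x) && length(x) == 1L &&
                        file.exists(x),
                    config[c("reads", "genome", "ncrnaCatalog",
                             "matureCatalog", "transcripts", "ctTable")])
    if (length(paths) == 0L) return(list())
    as.list(md5sum(unlist(paths)))
}

.writeRun <- function(res, config) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$outDir, f)
    writeTagFasta(res$tags, p("tags.fa"))
    write.table(res$categoryTable, p("category_table.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(res$conserved, p("conserved_calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(res$conservedFamilies, p("conserved_families.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$novel$candidates, p("novel_candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    hist <- lengthHistogram(res$qc)
    write.table(data.frame(length = names(hist),
                           reads = as.integer(hist)),
                p("length_histogram.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    pass <- res$novel$candidates[res$novel$candidates$verdict, ,
                                 drop = FALSE]
    if (nrow(pass) > 0L) {
        fa <- unlist(lapply(seq_len(nrow(pass)), function(i) {
            cand <- res$novel$objects[[pass$tag_id[i]]]
            c(paste0(">", pass$tag_id[i], "_mature ", pass$family[i]),
              pass$sequence[i],
              if (!is.na(cand@starSeq))
                  c(paste0(">", pass$tag_id[i], "_star"), cand@starSeq),
              paste0(">", pass$tag_id[i], "_precursor"),
              cand@precursor)
        }))
        writeLines(fa, p("novel_mirnas.fa"))
        gr <- GenomicRanges::GRanges(
            seqnames = pass$chrom,
            ranges = IRanges::IRanges(start = pass$matureStart + 1L,
                                      end = pass$matureEnd),
            strand = pass$strand)
        S4Vectors::mcols(gr)$type <- "miRNA"
        S4Vectors::mcols(gr)$ID <- pass$tag_id
        rtracklayer::export(gr, p("novel_mirnas.gff3"), format = "gff3")
    }
    if (!is.null(res$targets))
        write.table(res$targets$hits, p("target_hits.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    if (!is.null(res$expression))
        write.table(res$expression$perMirna, p("expression.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    man <- res$manifest
    man$outputs <- as.list(md5sum(list.files(config$outDir,
                                             full.names = TRUE,
                                             pattern = "\\.(tsv|fa|gff3)$")))
    jsonlite::write_json(man, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    invisible(config$outDir)
}

#' Score pipeline recovery against a truth ledger
#'
#' Compares pipeline output with what the synthetic generator planted.
#' A planted miRNA counts as recovered when its mature is either called
#' conserved (any conserved call whose tag differs from the planted
#' mature by at most 2 substitutions) or yields a passing hairpin
#' candidate whose mature locus is within `tol` nt of the true locus. A
#' passing candidate is a true positive when it sits at a planted
#' mature or miRNA* locus (the star strand of a genuine duplex is a
#' genuine Dicer product); precision is scored over all passing
#' candidates. Star detection is the fraction of star-emitting planted
#' hairpins, among those that reached hairpin evaluation, whose best
#' candidate is flagged `hasStarRead`.
#'
#' @param result list from [runPipeline()].
#' @param truth the [TruthSet-class] the library was simulated from.
#' @param tol locus tolerance, nt.
#' @return list of counts and rates; `recallPct`, `precisionPct` and
#'   `starDetectionPct` are percentages (NA when undefined).
#' @export
recoveryReport <- function(result, truth, tol = 3L) {
    stopifnot(is(truth, "TruthSet"))
    m <- truth@mirnas
    cands <- result$novel$candidates
    pass <- cands[cands$verdict, , drop = FALSE]
    consSeqs <- result$conserved$sequence
    # a candidate matches a planted hairpin when its mature interval
    # sits within `tol` nt of the hairpin's mature or miRNA* interval;
    # strand is not compared because a perfect mature/star duplex makes
    # both sequences occur on both strands of the same locus, and either
    # assignment identifies the same planted hairpin
    matchesHairpin <- function(i, rows) {
        rows$chrom == m$chrom[i] &
            ((abs(rows$start - m$start[i]) <= tol &
                  abs(rows$end - m$end[i]) <= tol) |
                 (abs(rows$start - m$starStart[i]) <= tol &
                      abs(rows$end - m$starEnd[i]) <= tol))
    }
    passRows <- data.frame(chrom = pass$chrom, start = pass$matureStart,
                           end = pass$matureEnd)
    candRows <- data.frame(chrom = cands$chrom,
                           start = cands$matureStart,
                           end = cands$matureEnd)
    recovered <- vapply(seq_len(nrow(m)), function(i) {
        asCons <- length(consSeqs) > 0L &&
            any(vapply(consSeqs, function(s)
                nchar(s) == nchar(m$mature[i]) &&
                    sum(utf8ToInt(s) != utf8ToInt(m$mature[i])) <= 2L,
                logical(1)))
        asNovel <- nrow(pass) > 0L && any(matchesHairpin(i, passRows))
        asCons || asNovel
    }, logical(1))
    tp <- if (nrow(pass) > 0L)
        Reduce(`|`, lapply(seq_len(nrow(m)), matchesHairpin,
                           rows = passRows)) else logical(0)
    if (is.null(tp)) tp <- rep(FALSE, nrow(pass))
    # star detection over star-emitting hairpins that reached evaluation
    starEval <- vapply(which(m$emitsStar), function(i) {
        hit <- matchesHairpin(i, candRows)
        if (!any(hit)) NA else any(cands$hasStarRead[hit])
    }, logical(1))
    nStarEval <- sum(!is.na(starEval))
    list(nPlanted = nrow(m), nRecovered = sum(recovered),
         recallPct = if (nrow(m) > 0) 100 * mean(recovered) else NA_real_,
         nPassing = nrow(pass), nTruePositive = sum(tp),
         precisionPct = if (nrow(pass) > 0) 100 * mean(tp) else NA_real_,
         nStarEmitting = sum(m$emitsStar), nStarEvaluated = nStarEval,
         starDetectionPct = if (nStarEval > 0)
             100 * mean(starEval, na.rm = TRUE) else NA_real_)
}
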