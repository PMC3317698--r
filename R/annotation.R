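# Tag annotation: poly-A artifact removal, ncRNA classification against
# a class-annotated catalog, conserved-miRNA assignment against a mature
# catalog, family abundance and the category accounting table.

NCRNA_CLASSES <- c("rRNA", "tRNA", "snRNA", "snoRNA", "repeat")
CATEGORY_ORDER <- c("miRNA", "rRNA", "repeat", "snRNA", "snoRNA", "tRNA",
                    "unannotated")

#' Load an ncRNA contaminant catalog
#'
#' FASTA with the class encoded in the header as `>class|name`; classes
#' are restricted to rRNA, tRNA, snRNA, snoRNA and repeat. U is mapped
#' to T so all matching happens in the DNA alphabet.
#'
#' @param path FASTA path.
#' @return data.frame with columns class, name, sequence.
#' @export
loadNcrnaCatalog <- function(path) {
    # read as raw strings: catalogs may be in the RNA alphabet
    x <- Biostrings::readBStringSet(path)
    if (length(x) == 0L) stop("empty ncRNA catalog: ", path)
    hdr <- strsplit(names(x), "|", fixed = TRUE)
    cls <- vapply(hdr, `[`, character(1), 1L)
    nm <- vapply(hdr, function(h) paste(h[-1L], collapse = "|"),
                 character(1))
    if (!all(cls %in% NCRNA_CLASSES))
        stop("unknown ncRNA class in catalog header(s): ",
             paste(unique(setdiff(cls, NCRNA_CLASSES)), collapse = ", "))
    data.frame(class = cls, name = nm,
               sequence = normalizeDna(as.character(x)),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Load a mature miRNA catalog
#'
#' FASTA of mature miRNAs (19-25 nt). The family is derived from the id
#' miRBase-style: the species prefix, a trailing variant letter and any
#' `-number` / `.number` suffix are stripped, so `hvu-miR156a` and
#' `hvu-miR156d-3p` both belong to family `miR156`.
#'
#' @param path FASTA path.
#' @return data.frame with columns id, family, sequence, sorted by id.
#' @export
loadMatureCatalog <- function(path) {
    x <- Biostrings::readBStringSet(path)
    if (length(x) == 0L) stop("empty mature miRNA catalog: ", path)
    ids <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L)
    if (anyDuplicated(ids))
        stop("duplicate ids in mature catalog")
    seqs <- normalizeDna(as.character(x))
    w <- nchar(seqs)
    if (any(w < 19L | w > 25L))
        stop("mature catalog sequences must be 19-25 nt")
    df <- data.frame(id = ids, family = mirnaFamily(ids),
                     sequence = unname(seqs), stringsAsFactors = FALSE,
                     row.names = NULL)
    df[order(df$id), , drop = FALSE]
}

#' Derive the miRNA family from a mature miRNA id
#'
#' @param id character vector of miRBase-style ids.
#' @return character vector of family names.
#' @examples
#' mirnaFamily(c("hvu-miR156a", "hvu-miR156d-3p", "osa-miR396"))
#' @export
mirnaFamily <- function(id) {
    fam <- sub("^[a-z]{3,4}-", "", id)
    fam <- sub("[-.].*$", "", fam)
    sub("(?<=[0-9])[a-zA-Z]+$", "", fam, perl = TRUE)
}

#' Poly-A artifact filter
#'
#' Drops tags that end in 8 or more consecutive A, or whose overall
#' composition is at least 80% A (oligo-dT priming / poly-A tail
#' remnants).
#'
#' @param sequences tag sequences.
#' @return logical vector, TRUE = keep.
#' @export
polyaFilter <- function(sequences) {
    tailA <- grepl("A{8,}$", sequences)
    fracA <- vapply(sequences, function(s) {
        n <- nchar(s)
        (n - nchar(gsub("A", "", s, fixed = TRUE))) / n
    }, numeric(1), USE.NAMES = FALSE)
    !(tailA | fracA >= 0.8)
}

#' Classify tags against the ncRNA catalog
#'
#' A tag is assigned the class of the first catalog entry that contains
#' it (or its reverse complement) as an exact substring. Classes are
#' searched in the fixed precedence order rRNA, tRNA, snRNA, snoRNA,
#' repeat, so a tag matching entries of two classes always gets the
#' higher-precedence one, independent of catalog file order.
#'
#' @param sequences tag sequences.
#' @param catalog data.frame from [loadNcrnaCatalog()].
#' @return character vector of classes, NA for unmatched tags.
#' @export
classifyNcrna <- function(sequences, catalog) {
    if (is.null(catalog) || nrow(catalog) == 0L)
        stop("ncRNA catalog is empty")
    res <- rep(NA_character_, length(sequences))
    rc <- revComp(sequences)
    for (cls in NCRNA_CLASSES) {
        subj <- catalog$sequence[catalog$class == cls]
        if (length(subj) == 0L) next
        todo <- which(is.na(res))
        if (length(todo) == 0L) break
        hit <- vapply(todo, function(i) {
            any(grepl(sequences[i], subj, fixed = TRUE)) ||
                any(grepl(rc[i], subj, fixed = TRUE))
        }, logical(1))
        res[todo[hit]] <- cls
    }
    res
}

#' Assign conserved miRNAs by mismatch-bounded catalog matching
#'
#' Each tag is aligned end-to-end (ungapped) against every catalog
#' mature; length differences up to 2 nt are absorbed as a terminal
#' overhang and substitutions are counted over the shorter sequence.
#' The best hit with at most `maxMismatch` substitutions wins; ties go
#' to the fewest mismatches, then the lexicographically smallest id.
#' Exact hits are member-level calls (`match_type` "exact"); 1-2
#' mismatch hits are family-level variants (`match_type` "variant").
#'
#' @param tags a [SmallRNATagSet-class] (or character vector of
#'   sequences).
#' @param catalog data.frame from [loadMatureCatalog()].
#' @param maxMismatch maximum substitutions (default 2).
#' @return data.frame with one row per matched tag: tag_id, sequence,
#'   count, mirna_id, family, mismatches, match_type.
#' @export
matchConserved <- function(tags, catalog, maxMismatch = 2L) {
    if (is.character(tags)) tags <- SmallRNATagSet(tags)
    seqs <- tagSequence(tags)
    if (length(seqs) == 0L)
        return(data.frame(tag_id = character(0), sequence = character(0),
                          count = integer(0), mirna_id = character(0),
                          family = character(0), mismatches = integer(0),
                          match_type = character(0),
                          stringsAsFactors = FALSE))
    # catalog arrives sorted by id, so "earliest entry" ties == smallest id
    m <- match_catalog_cpp(seqs, catalog$sequence,
                           as.integer(maxMismatch), 2L)
    hit <- m[, 1L] > 0L
    idx <- m[hit, 1L]
    data.frame(tag_id = tagId(tags)[hit], sequence = seqs[hit],
               count = tagCount(tags)[hit],
               mirna_id = catalog$id[idx], family = catalog$family[idx],
               mismatches = m[hit, 2L],
               match_type = ifelse(m[hit, 2L] == 0L, "exact", "variant"),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Family abundance table
#'
#' Collapses conserved calls to families: distinct catalog members hit
#' and total read counts, ordered by descending reads. Read counts are
#' conserved exactly: the column sums reproduce the per-call totals.
#'
#' @param calls data.frame from [matchConserved()].
#' @return data.frame with columns family, members, reads.
#' @export
familyAbundance <- function(calls) {
    if (nrow(calls) == 0L)
        return(data.frame(family = character(0), members = integer(0),
                          reads = integer(0), stringsAsFactors = FALSE))
    reads <- rowsum(calls$count, calls$family)
    members <- vapply(split(calls$mirna_id, calls$family),
                      function(x) length(unique(x)), integer(1))
    df <- data.frame(family = rownames(reads),
                     members = as.integer(members[rownames(reads)]),
                     reads = as.integer(reads[, 1L]),
                     stringsAsFactors = FALSE, row.names = NULL)
    df[order(-df$reads, df$family), , drop = FALSE]
}

#' Category accounting table
#'
#' `categoryTable()` builds the standard small RNA category table (total,
#' miRNA, rRNA, repeat, snRNA, snoRNA, tRNA, unannotated) from named
#' per-category unique-tag and read counts; percentages are reported to
#' two decimals. `buildCategoryTable()` derives those counts from a tag
#' set plus its annotations: every tag must fall in exactly one category
#' (ncRNA class if any, else miRNA if a conserved call exists, else
#' unannotated), and the partition is verified.
#'
#' @param uniqueCounts,readCounts named integer vectors over the
#'   categories (missing categories count 0).
#' @return data.frame: category, unique_tags, unique_percent,
#'   total_reads, total_percent, with a leading "total" row.
#' @export
categoryTable <- function(uniqueCounts, readCounts) {
    u <- setNames(rep(0, length(CATEGORY_ORDER)), CATEGORY_ORDER)
    r <- u
    u[names(uniqueCounts)] <- uniqueCounts
    r[names(readCounts)] <- readCounts
    totU <- sum(u)
    totR <- sum(r)
    data.frame(category = c("total", CATEGORY_ORDER),
               unique_tags = c(totU, unname(u)),
               unique_percent = c(if (totU > 0) 100 else 0,
                                  unname(pct2(u, totU))),
               total_reads = c(totR, unname(r)),
               total_percent = c(if (totR > 0) 100 else 0,
                                 unname(pct2(r, totR))),
               stringsAsFactors = FALSE)
}

#' @param tags a [SmallRNATagSet-class] (after the poly-A filter).
#' @param ncrnaClass character vector parallel to `tags`, the
#'   [classifyNcrna()] class or NA.
#' @param conservedCalls data.frame from [matchConserved()].
#' @rdname categoryTable
#' @export
buildCategoryTable <- function(tags, ncrnaClass, conservedCalls) {
    stopifnot(length(ncrnaClass) == length(tags))
    cat <- ifelse(is.na(ncrnaClass), "unannotated", ncrnaClass)
    isMir <- tagId(tags) %in% conservedCalls$tag_id
    if (any(isMir & cat != "unannotated"))
        stop("internal consistency error: conserved call on an ",
             "ncRNA-classified tag")
    cat[isMir] <- "miRNA"
    f <- factor(cat, levels = CATEGORY_ORDER)
    u <- table(f)
    r <- vapply(split(tagCount(tags), f), sum, numeric(1))
    categoryTable(setNames(as.integer(u), names(u)),
                  setNames(as.integer(r), names(r)))
}
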