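# qRT-PCR delta-CT expression summaries. CT values arrive already
# called by the instrument; the reference gene (e.g. 18S rRNA) CT is
# carried per record.

#' Read a CT table
#'
#' TSV with columns mirna, sample, replicate, ct, reference_ct.
#'
#' @param path TSV path.
#' @return data.frame of CT records.
#' @export
readCtTable <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("mirna", "sample", "replicate", "ct", "reference_ct")
    if (!all(need %in% names(df)))
        stop("CT table must have columns: ", paste(need, collapse = ", "))
    if (any(!is.finite(df$ct)) || any(!is.finite(df$reference_ct)))
        stop("missing or non-finite CT values")
    df
}

#' Delta-CT
#'
#' `ct - ctRef`, in cycles. Lower delta-CT means higher expression
#' relative to the reference gene.
#'
#' @param ct,ctRef sample and reference threshold cycles.
#' @return delta-CT, cycles.
#' @examples
#' deltaCt(30.0, 25.2)
#' @export
deltaCt <- function(ct, ctRef) {
    if (any(!is.finite(ct)) || any(!is.finite(ctRef)))
        stop("CT values must be finite")
    ct - ctRef
}

#' Summarize delta-CT expression
#'
#' Replicate-averaged delta-CT (mean and sd; sd is NA with a single
#' replicate) per miRNA and sample, plus optional group means over
#' user-defined miRNA sets (the group mean averages the per-miRNA,
#' per-sample means of its members).
#'
#' @param records data.frame as from [readCtTable()].
#' @param groups optional named list of miRNA id vectors.
#' @return list: `perMirna` (data.frame mirna, sample, n, meanDeltaCt,
#'   sdDeltaCt, ordered by mirna then sample) and `groups` (data.frame
#'   group, meanDeltaCt; NULL when no groups given).
#' @export
summarizeExpression <- function(records, groups = NULL) {
    if (!"reference_ct" %in% names(records) ||
        any(!is.finite(records$reference_ct)))
        stop("missing reference CT")
    d <- deltaCt(records$ct, records$reference_ct)
    key <- interaction(records$mirna, records$sample, drop = TRUE,
                       sep = "\r")
    sp <- split(d, key)
    ks <- strsplit(names(sp), "\r", fixed = TRUE)
    per <- data.frame(
        mirna = vapply(ks, `[`, character(1), 1L),
        sample = vapply(ks, `[`, character(1), 2L),
        n = lengths(sp),
        meanDeltaCt = vapply(sp, mean, numeric(1)),
        sdDeltaCt = vapply(sp, function(x)
            if (length(x) > 1L) sd(x) else NA_real_, numeric(1)),
        stringsAsFactors = FALSE, row.names = NULL)
    per <- per[order(per$mirna, per$sample), , drop = FALSE]
    rownames(per) <- NULL
    grp <- NULL
    if (!is.null(groups)) {
        grp <- data.frame(
            group = names(groups),
            meanDeltaCt = vapply(groups, function(ids)
                mean(per$meanDeltaCt[per$mirna %in% ids]), numeric(1)),
            stringsAsFactors = FALSE, row.names = NULL)
    }
    list(perMirna = per, groups = grp)
}

#' Stress-response delta-delta-CT table
#'
#' For each miRNA and stress sample: `ddCt = meanDeltaCt(stress) -
#' meanDeltaCt(control)`, fold change `2^-ddCt`, and an up / down /
#' unchanged call at a configurable |ddCt| threshold. The fold change of
#' the control against itself is exactly 1.
#'
#' @param records data.frame as from [readCtTable()].
#' @param control control sample label.
#' @param stressLabels stress sample labels (default: all non-control
#'   samples).
#' @param threshold |ddCt| below which a miRNA is called unchanged.
#' @return data.frame: mirna, sample, ddCt, foldChange, direction.
#' @export
stressResponse <- function(records, control, stressLabels = NULL,
                           threshold = 1.0) {
    if (!control %in% records$sample)
        stop("control sample '", control, "' absent from the records")
    per <- summarizeExpression(records)$perMirna
    if (is.null(stressLabels))
        stressLabels <- setdiff(unique(per$sample), control)
    ctrl <- per[per$sample == control, , drop = FALSE]
    rows <- list()
    for (s in stressLabels) {
        st <- per[per$sample == s, , drop = FALSE]
        common <- intersect(st$mirna, ctrl$mirna)
        dd <- st$meanDeltaCt[match(common, st$mirna)] -
            ctrl$meanDeltaCt[match(common, ctrl$mirna)]
        rows[[s]] <- data.frame(
            mirna = common, sample = s, ddCt = dd,
            foldChange = 2^(-dd),
            direction = ifelse(abs(dd) < threshold, "unchanged",
                               ifelse(dd < 0, "up", "down")),
            stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
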