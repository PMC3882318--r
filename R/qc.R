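## Quality-control annotation tokens. They are appended to output rows,
## never alter intensities, and are stable strings a downstream parser can
## match on.
.qc_codes <- c("count_exceeds_formula", "duplicate_isotopologue",
               "malformed_row", "predicted_not_observed")

#' Quality-control annotation codes
#'
#' The stable tokens written to the annotation column of the output file:
#' `count_exceeds_formula` (a heavy-label count larger than the formula's
#' atom count for that element), `duplicate_isotopologue` (a second row
#' with an identical label-count tuple in one dataset; the first row in
#' file order wins), `malformed_row` (unparseable formula, count or
#' intensity; the row is echoed but excluded from correction), and
#' `predicted_not_observed` (a peak predicted above the inclusion threshold
#' but missing from the input).
#'
#' @return character vector of the four codes.
#' @export
qcCodes <- function() .qc_codes

#' Validate the peaks of one dataset
#'
#' Checks each peak row of a single molecule's dataset against its
#' molecular formula: a heavy-label count may not exceed the atom count of
#' the tracer's element (`count_exceeds_formula`), and each label-count
#' tuple may occur only once (`duplicate_isotopologue`; the first
#' occurrence in file order is kept, later ones are flagged). Annotations
#' never modify intensities; flagged rows are excluded from the dense
#' array but still echoed to the output.
#'
#' @param counts integer matrix, one row per peak, one column per tracer
#'   isotope (0-based heavy-label counts).
#' @param formula named integer vector from [parseFormula()].
#' @param isotopes list of [IsotopeSpec-class] matching the count columns.
#' @return `list(annotations = character, keep = logical)`, both of length
#'   `nrow(counts)`; `annotations` holds `";"`-joined codes (empty string
#'   when clean), `keep` marks rows that enter the array.
#' @export
validateDataset <- function(counts, formula, isotopes) {
    counts <- as.matrix(counts)
    stopifnot(ncol(counts) == length(isotopes))
    n <- nrow(counts)
    ann <- vector("list", n)
    maxima <- vapply(isotopes, function(iso) maxLabelCount(formula, iso),
                     integer(1))
    over <- rowSums(counts > matrix(maxima, n, length(maxima),
                                    byrow = TRUE)) > 0
    dup <- duplicated(as.data.frame(counts))
    for (r in seq_len(n)) {
        a <- character()
        if (over[r]) a <- c(a, "count_exceeds_formula")
        if (dup[r]) a <- c(a, "duplicate_isotopologue")
        ann[[r]] <- a
    }
    list(annotations = vapply(ann, paste, character(1), collapse = ";"),
         keep = !(over | dup))
}

#' Construct a predicted-peak inclusion threshold
#'
#' @param percent numeric(1), percentage of the chosen statistic (e.g. 10
#'   means 10%).
#' @param statistic `"minimum"`, `"maximum"` or `"average"` observed peak
#'   intensity.
#' @param scope `"collection"` (one threshold for the whole run) or
#'   `"dataset"` (per molecule dataset).
#' @param enabled logical(1); a disabled spec yields no predicted peaks.
#' @return A [ThresholdSpec-class].
#' @export
thresholdSpec <- function(percent = 0, statistic = "minimum",
                          scope = "collection", enabled = TRUE) {
    new("ThresholdSpec", percent = as.numeric(percent), statistic = statistic,
        scope = scope, enabled = enabled)
}

## Summary statistics of observed (nonzero) peak intensities.
.intensityStats <- function(x) {
    x <- x[is.finite(x) & x > 0]
    if (!length(x))
        return(list(minimum = NA_real_, maximum = NA_real_,
                    average = NA_real_))
    list(minimum = min(x), maximum = max(x), average = mean(x))
}

#' Resolve a threshold spec to an absolute intensity
#'
#' Statistics are computed over observed nonzero intensities (implicit
#' zeros from densification are not peaks). A disabled spec resolves to
#' `NA`; an enabled spec over empty data also resolves to `NA` with a
#' warning, and the predicted-peak step is skipped.
#'
#' @param spec a [ThresholdSpec-class].
#' @param collectionStats,datasetStats lists with elements `minimum`,
#'   `maximum`, `average` (see scope).
#' @return numeric(1) absolute intensity, or `NA_real_`.
#' @export
resolveThreshold <- function(spec, collectionStats = NULL,
                             datasetStats = NULL) {
    stopifnot(is(spec, "ThresholdSpec"))
    if (!spec@enabled) return(NA_real_)
    stats <- if (spec@scope == "collection") collectionStats else datasetStats
    if (is.null(stats)) stop(sprintf("no %s statistics supplied", spec@scope))
    v <- stats[[spec@statistic]]
    if (is.null(v) || !is.finite(v)) {
        warning("threshold undefined (no observed peaks); skipping predicted peaks")
        return(NA_real_)
    }
    spec@percent / 100 * v
}

#' Find peaks predicted above threshold but not observed
#'
#' Scans the re-contaminated reconstruction (`I_datacalc`) of a corrected
#' dataset for isotopologues whose predicted intensity is at or above the
#' threshold but that had no observed peak in the input. Observed peaks are
#' never re-added. Such peaks usually mean the upstream peak identification
#' missed real signals.
#'
#' @param reconstructed an [IsotopologueArray-class] (see
#'   [reconstructed()]).
#' @param observedMask logical array of the same shape, `TRUE` where an
#'   observed peak entered the dataset.
#' @param threshold numeric(1) absolute intensity (comparison is `>=`);
#'   `NA` yields no rows.
#' @return data.frame with one 0-based count column per tracer (named by
#'   isotope label), a `predicted` intensity column and an `annotation`
#'   column.
#' @export
findMissingPredicted <- function(reconstructed, observedMask, threshold) {
    stopifnot(is(reconstructed, "IsotopologueArray"))
    v <- reconstructed@values
    stopifnot(identical(dim(observedMask), dim(v)))
    labs <- vapply(reconstructed@isotopes, slot, character(1), "label")
    empty <- as.data.frame(matrix(integer(), 0, length(labs),
                                  dimnames = list(NULL, labs)))
    empty$predicted <- numeric(0)
    empty$annotation <- character(0)
    if (is.na(threshold)) return(empty)
    sel <- which(!observedMask & v >= threshold)
    if (!length(sel)) return(empty)
    idx <- arrayInd(sel, dim(v)) - 1L
    colnames(idx) <- labs
    out <- as.data.frame(idx)
    out$predicted <- v[sel]
    out$annotation <- "predicted_not_observed"
    out
}
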