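#' Construct a run configuration
#'
#' @param input,output character(1) paths of the delimited peak table and
#'   the corrected output file.
#' @param countColumns named character: names are tracer isotope labels
#'   (e.g. `"13C"`), values the columns holding the heavy-label counts.
#'   Their order defines the array dimension order.
#' @param formulaColumn,intensityColumn column names (defaults `"formula"`,
#'   `"intensity"`).
#' @param delimiter field separator (default `","`).
#' @param groupColumns character, further columns (sample, replicate, time
#'   point) that split rows sharing a formula into independent datasets.
#' @param abundances optional named numeric, natural-abundance overrides by
#'   isotope label.
#' @param threshold a [ThresholdSpec-class]; disabled by default.
#' @param cache logical(1), reuse P/S tables across datasets (default
#'   `TRUE`; disabling only recomputes, results are identical).
#' @return A [CollectionConfig-class].
#'
#' @examples
#' cfg <- collectionConfig("peaks.csv", "corrected.csv",
#'                         countColumns = c("13C" = "c13"))
#'
#' @export
collectionConfig <- function(input, output, countColumns,
                             formulaColumn = "formula",
                             intensityColumn = "intensity",
                             delimiter = ",", groupColumns = character(),
                             abundances = NULL,
                             threshold = thresholdSpec(enabled = FALSE),
                             cache = TRUE) {
    isotopes <- .resolveIsotopes(names(countColumns), abundances)
    new("CollectionConfig", input = input, output = output,
        delimiter = delimiter, formulaColumn = formulaColumn,
        intensityColumn = intensityColumn,
        countColumns = countColumns,
        groupColumns = as.character(groupColumns), isotopes = isotopes,
        threshold = threshold, cache = cache)
}

#' Read a run configuration from a YAML file
#'
#' Recognized keys: `input`, `output`, `delimiter`, `formula_column`,
#' `intensity_column`, `count_columns` (mapping isotope label to column
#' name), `group_columns` (list), `abundances` (mapping isotope label to
#' natural-abundance fraction), `threshold` (mapping with `percent`,
#' `statistic`, `scope`) and `cache` (logical). Only `input`, `output` and
#' `count_columns` are required.
#'
#' @param path character(1), YAML file.
#' @return A [CollectionConfig-class].
#' @export
readCollectionConfig <- function(path) {
    if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
    y <- yaml::read_yaml(path)
    for (key in c("input", "output", "count_columns"))
        if (is.null(y[[key]]))
            stop(sprintf("config is missing required key '%s'", key))
    thr <- if (is.null(y$threshold)) thresholdSpec(enabled = FALSE)
           else thresholdSpec(
               percent = y$threshold$percent,
               statistic = if (is.null(y$threshold$statistic)) "minimum"
                           else y$threshold$statistic,
               scope = if (is.null(y$threshold$scope)) "collection"
                       else y$threshold$scope)
    collectionConfig(
        input = y$input, output = y$output,
        countColumns = unlist(y$count_columns),
        formulaColumn = if (is.null(y$formula_column)) "formula"
                        else y$formula_column,
        intensityColumn = if (is.null(y$intensity_column)) "intensity"
                          else y$intensity_column,
        delimiter = if (is.null(y$delimiter)) "," else y$delimiter,
        groupColumns = if (is.null(y$group_columns)) character()
                       else unlist(y$group_columns),
        abundances = if (is.null(y$abundances)) NULL else unlist(y$abundances),
        threshold = thr,
        cache = if (is.null(y$cache)) TRUE else isTRUE(y$cache))
}

#' Read a peak collection and split it into per-molecule datasets
#'
#' Reads the delimited file named by the configuration (all fields as
#' character, so pass-through columns survive unchanged), verifies the
#' configured columns exist, parses formulas, counts and intensities, and
#' groups rows into datasets by molecular formula plus any grouping
#' columns. Within a dataset, rows keep their file order. Rows whose
#' formula, counts or intensity cannot be parsed are annotated
#' `malformed_row` and excluded from the dense array, but remain in the
#' raw table for echoing.
#'
#' @param config a [CollectionConfig-class].
#' @return A [PeakCollection-class].
#' @export
readCollection <- function(config) {
    stopifnot(is(config, "CollectionConfig"))
    if (!file.exists(config@input))
        stop(sprintf("input file '%s' not found", config@input))
    raw <- data.table::fread(config@input, sep = config@delimiter,
                             header = TRUE, colClasses = "character",
                             data.table = FALSE, keepLeadingZeros = TRUE)
    needed <- c(config@formulaColumn, config@intensityColumn,
                unname(config@countColumns), config@groupColumns)
    missing <- setdiff(needed, names(raw))
    if (length(missing))
        stop(sprintf("configured column(s) not in input header: %s",
                     paste(missing, collapse = ", ")))
    n <- nrow(raw)
    datasets <- list()
    if (n > 0) {
        keyParts <- c(list(raw[[config@formulaColumn]]),
                      lapply(config@groupColumns, function(g) raw[[g]]))
        key <- do.call(paste, c(keyParts, sep = "\r"))
        groups <- split(seq_len(n), factor(key, levels = unique(key)))
        datasets <- lapply(groups, function(rows) {
            ftext <- raw[[config@formulaColumn]][rows[1]]
            formula <- tryCatch(parseFormula(ftext), error = function(e) NULL)
            counts <- vapply(unname(config@countColumns), function(cc)
                suppressWarnings(as.integer(raw[[cc]][rows])),
                integer(length(rows)))
            counts <- matrix(counts, nrow = length(rows),
                             dimnames = list(NULL, names(config@countColumns)))
            intensity <- suppressWarnings(
                as.numeric(raw[[config@intensityColumn]][rows]))
            badCount <- rowSums(is.na(counts) | counts < 0) > 0
            badInt <- !is.finite(intensity) | intensity < 0
            malformed <- badCount | badInt | is.null(formula)
            list(rows = rows, formulaText = ftext, formula = formula,
                 counts = counts, intensity = intensity,
                 malformed = malformed,
                 group = if (length(config@groupColumns))
                     vapply(config@groupColumns, function(g)
                         raw[[g]][rows[1]], character(1))
                 else character())
        })
        names(datasets) <- NULL
    }
    new("PeakCollection", raw = raw, datasets = datasets, config = config)
}

## Format numbers at full double precision for the output table.
.fmtNum <- function(x) {
    out <- rep("", length(x))
    ok <- !is.na(x)
    out[ok] <- sprintf("%.17g", x[ok])
    out
}

#' Write the corrected, annotated collection
#'
#' Echoes every input row with all original columns unchanged, appends a
#' `corrected_intensity` column (full double precision; empty for rows that
#' were excluded from the correction) and a `correction_note` column with
#' the `";"`-joined quality-control codes of [qcCodes()]. Predicted-but-
#' unobserved peaks, when a threshold is enabled, are appended after the
#' input rows, dataset by dataset, carrying their formula, group values and
#' label counts, the predicted intensity in `corrected_intensity`, and the
#' `predicted_not_observed` marker.
#'
#' @param collection a [PeakCollection-class].
#' @param results list parallel to `collection@datasets`, each with
#'   elements `corrected` (numeric per row, `NA` for excluded rows),
#'   `annotations` (character per row) and `predicted` (data.frame from
#'   [findMissingPredicted()]).
#' @param config a [CollectionConfig-class].
#' @return The output path, invisibly.
#' @export
writeCollection <- function(collection, results, config) {
    raw <- collection@raw
    for (col in c("corrected_intensity", "correction_note"))
        if (col %in% names(raw))
            stop(sprintf("input already has a '%s' column", col))
    n <- nrow(raw)
    correctedCol <- rep(NA_real_, n)
    noteCol <- rep("", n)
    predRows <- list()
    for (d in seq_along(collection@datasets)) {
        ds <- collection@datasets[[d]]
        res <- results[[d]]
        correctedCol[ds$rows] <- res$corrected
        noteCol[ds$rows] <- res$annotations
        if (!is.null(res$predicted) && nrow(res$predicted)) {
            p <- res$predicted
            block <- as.data.frame(matrix("", nrow(p), ncol(raw),
                                          dimnames = list(NULL, names(raw))),
                                   stringsAsFactors = FALSE)
            block[[config@formulaColumn]] <- ds$formulaText
            for (g in seq_along(config@groupColumns))
                block[[config@groupColumns[g]]] <- ds$group[[g]]
            for (lab in names(config@countColumns))
                block[[config@countColumns[[lab]]]] <- as.character(p[[lab]])
            block$corrected_intensity <- .fmtNum(p$predicted)
            block$correction_note <- p$annotation
            predRows[[length(predRows) + 1L]] <- block
        }
    }
    out <- raw
    out$corrected_intensity <- .fmtNum(correctedCol)
    out$correction_note <- noteCol
    if (length(predRows))
        out <- rbind(out, do.call(rbind, predRows))
    data.table::fwrite(out, config@output, sep = config@delimiter,
                       quote = "auto")
    invisible(config@output)
}
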