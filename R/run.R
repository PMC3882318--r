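#' Correct a whole peak collection
#'
#' End-to-end run: read the input table, split it into per-molecule
#' datasets, quality-check every peak, build (or fetch from cache) the P/S
#' correction tables, correct each dataset with [correctNA()], optionally
#' report predicted-but-unobserved peaks, and write the annotated output.
#' Dataset corrections are independent of each other, so results do not
#' depend on processing order; output rows follow input order, with
#' predicted peaks appended.
#'
#' @param config a [CollectionConfig-class] or the path of a YAML
#'   configuration file (see [readCollectionConfig()]).
#' @param verbose logical(1), log per-dataset iterations and cache usage to
#'   the message stream.
#' @return A [RunReport-class]; the corrected file is written as a side
#'   effect.
#'
#' @examples
#' \dontrun{
#' tmp <- tempfile(fileext = ".csv")
#' out <- tempfile(fileext = ".csv")
#' makeCollectionFile(tmp, nMolecules = 5, isotopes = "13C", seed = 7)
#' correctCollection(syntheticConfig(tmp, out))
#' }
#'
#' @export
correctCollection <- function(config, verbose = FALSE) {
    t0 <- proc.time()[["elapsed"]]
    if (is.character(config)) config <- readCollectionConfig(config)
    stopifnot(is(config, "CollectionConfig"))
    collection <- readCollection(config)
    cache <- if (config@cache) newTableCache() else NULL

    # collection-wide intensity statistics over well-formed observed peaks
    allInt <- unlist(lapply(collection@datasets, function(ds)
        ds$intensity[!ds$malformed]))
    collStats <- .intensityStats(allInt)

    flagged <- stats::setNames(integer(length(.qc_codes)), .qc_codes)
    iterCounts <- integer(0)
    nPredicted <- 0L
    results <- vector("list", length(collection@datasets))

    for (d in seq_along(collection@datasets)) {
        ds <- collection@datasets[[d]]
        nrows <- length(ds$rows)
        ann <- rep("", nrows)
        ann[ds$malformed] <- "malformed_row"
        keep <- !ds$malformed
        if (!is.null(ds$formula) && any(keep)) {
            v <- validateDataset(ds$counts[keep, , drop = FALSE],
                                 ds$formula, config@isotopes)
            ann[keep] <- v$annotations
            keep[keep] <- v$keep
        }
        for (code in .qc_codes)
            flagged[code] <- flagged[code] + sum(grepl(code, ann, fixed = TRUE))

        correctedRow <- rep(NA_real_, nrows)
        predicted <- NULL
        if (!is.null(ds$formula) && any(keep)) {
            maxima <- vapply(config@isotopes, function(iso)
                maxLabelCount(ds$formula, iso), integer(1))
            values <- array(0, dim = maxima + 1L)
            mask <- array(FALSE, dim = maxima + 1L)
            cellIdx <- ds$counts[keep, , drop = FALSE] + 1L
            values[cellIdx] <- ds$intensity[keep]
            mask[cellIdx] <- TRUE
            arr <- new("IsotopologueArray", values = values,
                       isotopes = config@isotopes)
            res <- correctNA(arr, cache = cache)
            correctedRow[keep] <- intensities(corrected(res))[cellIdx]
            key <- paste(c(ds$formulaText, ds$group), collapse = "/")
            iterCounts[key] <- iterations(res)
            if (verbose)
                message(sprintf("dataset %s: %d iteration(s), residual %g",
                                key, iterations(res), residual(res)))
            thr <- resolveThreshold(config@threshold,
                                    collectionStats = collStats,
                                    datasetStats = .intensityStats(
                                        ds$intensity[keep]))
            predicted <- findMissingPredicted(reconstructed(res), mask, thr)
            nPredicted <- nPredicted + nrow(predicted)
        }
        results[[d]] <- list(corrected = correctedRow, annotations = ann,
                             predicted = predicted)
    }

    writeCollection(collection, results, config)
    if (verbose && !is.null(cache)) {
        s <- cacheStats(cache)
        message(sprintf("table cache: %d entries, %d hits, %d misses",
                        s["entries"], s["hits"], s["misses"]))
    }
    new("RunReport",
        datasets = length(collection@datasets),
        peaks = nrow(collection@raw),
        flagged = flagged,
        predicted = nPredicted,
        iterations = iterCounts,
        elapsed = proc.time()[["elapsed"]] - t0,
        output = config@output)
}
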