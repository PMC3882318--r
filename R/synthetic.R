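## Run `expr` under a fixed RNG seed without disturbing the caller's RNG
## stream; seed = NULL uses the current stream.
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Reference simulated single-tracer distributions
#'
#' Two fixed, normalized single-isotope isotopologue distributions used
#' throughout the validation suite: a 9-carbon molecule with 13C intensity
#' `(0.5, 0, 0, 0.15, 0.1, 0, 0, 0, 0, 0.25)` at counts 0..9, and a
#' 6-nitrogen molecule with 15N intensity `(0.5, 0, 0, 0.1, 0, 0, 0.4)` at
#' counts 0..6. Their forward contaminations and the outer-product
#' two-tracer dataset built from them exercise every part of the multi-
#' isotope correction.
#'
#' @return An [IsotopologueArray-class].
#' @export
simulatedCarbonVector <- function() {
    isotopologueArray(c(0.5, 0, 0, 0.15, 0.1, 0, 0, 0, 0, 0.25), "13C")
}

#' @rdname simulatedCarbonVector
#' @export
simulatedNitrogenVector <- function() {
    isotopologueArray(c(0.5, 0, 0, 0.1, 0, 0, 0.4), "15N")
}

#' Generate a sparse clean isotopologue array
#'
#' Draws a random tracer-only (clean) distribution: each isotopologue is
#' nonzero with probability `sparsity`, nonzero intensities are long-tailed
#' log-normal draws, and at least one isotopologue is always populated.
#' With `normalize = TRUE` the array sums to 1.
#'
#' @param maxima integer vector of per-dimension maximum label counts
#'   `N_e` (the array spans `0..N_e` per dimension).
#' @param isotopes isotope labels or list of [IsotopeSpec-class], one per
#'   dimension.
#' @param sparsity numeric(1) in (0, 1], expected fraction of nonzero
#'   isotopologues (default 0.3, mimicking the sparsity of real
#'   isotopologue sets).
#' @param normalize logical(1), scale to total intensity 1.
#' @param seed optional integer; when given, the draw is reproducible and
#'   the caller's RNG stream is left untouched.
#' @return An [IsotopologueArray-class].
#' @export
makeCleanArray <- function(maxima, isotopes, sparsity = 0.3,
                           normalize = TRUE, seed = NULL) {
    stopifnot(all(maxima >= 0), sparsity > 0, sparsity <= 1)
    .withSeed(seed, {
        ncell <- prod(maxima + 1)
        nz <- runif(ncell) < sparsity
        if (!any(nz)) nz[sample.int(ncell, 1L)] <- TRUE
        v <- numeric(ncell)
        v[nz] <- rlnorm(sum(nz), meanlog = 0, sdlog = 1.5)
        if (normalize) v <- v / sum(v)
        isotopologueArray(array(v, dim = maxima + 1), isotopes)
    })
}

#' Outer product of single-tracer datasets
#'
#' Combines one-dimensional isotopologue arrays (one per tracer) into the
#' multi-tracer array whose `(x1, .., xn)` entry is the product of the
#' per-dimension entries — the standard construction of a multi-isotope
#' validation dataset from independently simulated single-isotope ones.
#' Because [addNA()] factorizes over dimensions, the outer product of
#' contaminated vectors equals the contamination of the outer product of
#' the clean vectors.
#'
#' @param arrays list of one-dimensional [IsotopologueArray-class]s with
#'   distinct tracer elements.
#' @return An [IsotopologueArray-class] of dimension `length(arrays)`.
#'
#' @examples
#' m <- outerDataset(list(simulatedCarbonVector(), simulatedNitrogenVector()))
#' sum(intensities(m))  # 1: product of unit sums
#'
#' @export
outerDataset <- function(arrays) {
    stopifnot(is.list(arrays), length(arrays) >= 1L)
    for (a in arrays)
        stopifnot(is(a, "IsotopologueArray"),
                  length(dim(a@values)) == 1L)
    values <- Reduce(function(x, y) outer(x, y),
                     lapply(arrays, function(a) as.vector(a@values)))
    if (is.null(dim(values))) values <- array(values, dim = length(values))
    isotopes <- unlist(lapply(arrays, labelOrder), recursive = FALSE)
    isotopologueArray(values, isotopes)
}

#' Write a synthetic collection-scale peak table
#'
#' Generates a deterministic (per seed) CSV emulating a real peak
#' collection: random small-molecule formulas, clean sparse isotopologue
#' distributions contaminated with natural abundance, realistic total
#' intensities, and optional injected quality-control defects. Column
#' layout: `molecule`, `sample`, `formula`, one `<label>_count` column per
#' tracer, `intensity`. The file is read back with a [collectionConfig()]
#' mapping those columns.
#'
#' @param path character(1) output file.
#' @param nMolecules integer(1) number of molecules (datasets).
#' @param isotopes character vector of tracer labels (1-3).
#' @param seed integer(1); the file bytes are a pure function of the
#'   arguments and this seed.
#' @param sparsity passed to [makeCleanArray()].
#' @param duplicates,overflowCounts integers: number of injected duplicate
#'   rows (same label-count tuple twice) and overflow rows (count one above
#'   the formula's atom count), for exercising quality control.
#' @param abundances optional named numeric abundance overrides.
#' @return The path, invisibly.
#' @export
makeCollectionFile <- function(path, nMolecules = 10, isotopes = "13C",
                               seed = 1, sparsity = 0.3, duplicates = 0,
                               overflowCounts = 0, abundances = NULL) {
    stopifnot(nMolecules >= 1)
    specs <- .resolveIsotopes(isotopes, abundances)
    elements <- vapply(specs, slot, character(1), "element")
    labs <- vapply(specs, slot, character(1), "label")
    rows <- .withSeed(seed, {
        out <- vector("list", nMolecules)
        for (m in seq_len(nMolecules)) {
            # formula with guaranteed atoms for every tracer element
            f <- c(C = sample(3:30, 1), H = sample(4:40, 1),
                   N = sample(0:6, 1), O = sample(0:12, 1),
                   P = sample(0:3, 1))
            for (el in elements) f[el] <- max(f[el], sample(1:6, 1))
            f <- f[f > 0]
            maxima <- vapply(specs, function(s) as.integer(f[s@element]),
                             integer(1))
            clean <- makeCleanArray(maxima, specs, sparsity = sparsity)
            total <- 10^runif(1, 4, 7)
            contaminated <- intensities(addNA(clean)) * total
            # observed = every peak carrying a meaningful share of signal
            sel <- which(contaminated >= 1e-4 * max(contaminated))
            idx <- arrayInd(sel, dim(contaminated)) - 1L
            df <- data.frame(
                molecule = sprintf("M%04d", m),
                sample = "s1",
                formula = formatFormula(f),
                stringsAsFactors = FALSE)
            df <- df[rep(1L, length(sel)), , drop = FALSE]
            for (e in seq_along(labs))
                df[[paste0(labs[e], "_count")]] <- idx[, e]
            df$intensity <- sprintf("%.8g", contaminated[sel])
            out[[m]] <- df
        }
        tab <- do.call(rbind, out)
        rownames(tab) <- NULL
        if (duplicates > 0) {
            pick <- sample.int(nrow(tab), min(duplicates, nrow(tab)))
            extra <- tab[pick, , drop = FALSE]
            extra$intensity <- sprintf("%.8g",
                                       as.numeric(extra$intensity) * 0.5)
            tab <- rbind(tab, extra)
        }
        if (overflowCounts > 0) {
            # one overflow row per molecule, so injected tuples stay unique
            firsts <- match(unique(tab$molecule), tab$molecule)
            pick <- sample(firsts, min(overflowCounts, length(firsts)))
            extra <- tab[pick, , drop = FALSE]
            for (r in seq_len(nrow(extra))) {
                f <- parseFormula(extra$formula[r])
                e <- 1L  # overflow the first tracer dimension
                extra[[paste0(labs[e], "_count")]][r] <-
                    maxLabelCount(f, specs[[e]]) + 1L
            }
            extra$intensity <- sprintf("%.8g",
                                       as.numeric(extra$intensity) * 0.01)
            tab <- rbind(tab, extra)
        }
        tab
    })
    data.table::fwrite(rows, path, sep = ",")
    invisible(path)
}

#' Configuration matching [makeCollectionFile()] output
#'
#' Convenience constructor for correcting a synthetic collection: maps the
#' generator's column layout onto a [CollectionConfig-class].
#'
#' @param input path written by [makeCollectionFile()].
#' @param output path for the corrected file.
#' @param isotopes the tracer labels the file was generated with.
#' @param ... further arguments to [collectionConfig()].
#' @return A [CollectionConfig-class].
#' @export
syntheticConfig <- function(input, output, isotopes = "13C", ...) {
    collectionConfig(input, output,
                     countColumns = stats::setNames(
                         paste0(isotopes, "_count"), isotopes),
                     formulaColumn = "formula",
                     intensityColumn = "intensity", ...)
}
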