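## Periodic-table symbols accepted in molecular formulas.
.element_symbols <- c(
    "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
    "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn",
    "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb",
    "Sr", "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In",
    "Sn", "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm",
    "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta",
    "W", "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At",
    "Rn", "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk",
    "Cf", "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt",
    "Ds", "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og")

#' Tracer isotope description
#'
#' An `IsotopeSpec` names one tracer isotope: its label in mass-number +
#' element style (`"13C"`, `"15N"`, `"2H"`), the element it belongs to, and
#' the natural-abundance fraction of the heavy isotope (dimensionless, in
#' `[0, 1)`). Natural abundances drive every correction term, so they are
#' carried on the spec rather than looked up implicitly; see
#' [defaultIsotopes()] for the built-in values and [isotopeSpec()] for
#' user-defined isotopes or abundance overrides.
#'
#' @slot label character(1), isotope name, e.g. `"13C"`.
#' @slot element character(1), periodic-table symbol, e.g. `"C"`.
#' @slot abundance numeric(1), natural-abundance fraction of the heavy
#'   isotope, `0 <= abundance < 1`.
#'
#' @export
setClass("IsotopeSpec",
    representation(label = "character", element = "character",
                   abundance = "numeric"))

setValidity("IsotopeSpec", function(object) {
    msg <- character()
    if (length(object@label) != 1L || !nzchar(object@label))
        msg <- c(msg, "'label' must be a single non-empty string")
    if (length(object@element) != 1L ||
        !(object@element %in% .element_symbols))
        msg <- c(msg, sprintf("'element' must be a periodic-table symbol, got '%s'",
                              paste(object@element, collapse = ",")))
    if (length(object@abundance) != 1L || !is.finite(object@abundance) ||
        object@abundance < 0 || object@abundance >= 1)
        msg <- c(msg, "'abundance' must be a single value in [0, 1)")
    if (length(msg)) msg else TRUE
})

setMethod("show", "IsotopeSpec", function(object) {
    cat(sprintf("IsotopeSpec %s (element %s, natural abundance %g)\n",
                object@label, object@element, object@abundance))
})

#' Dense n-dimensional isotopologue intensity array
#'
#' The central data container: a dense array of nonnegative peak
#' intensities indexed by heavy-label counts, one dimension per tracer
#' isotope. Entry `(x1, .., xn)` (0-based counts) holds the intensity of
#' the isotopologue carrying `x_e` heavy atoms of tracer `e`; unobserved
#' isotopologues are stored as 0. The array always spans the full index
#' space `0..N_e` per dimension, where `N_e` is the maximum label count
#' (the atom count of the tracer's element in the molecular formula).
#'
#' @slot values numeric array, nonnegative and finite; `dim(values)` is
#'   `labelMaxima + 1` per dimension.
#' @slot isotopes list of [IsotopeSpec-class], one per array dimension, in
#'   dimension order; at most three (single, double and triple labeling).
#'
#' @seealso [isotopologueArray()], [addNA()], [correctNA()]
#' @export
setClass("IsotopologueArray",
    representation(values = "array", isotopes = "list"))

setValidity("IsotopologueArray", function(object) {
    msg <- character()
    v <- object@values
    if (!is.numeric(v)) msg <- c(msg, "'values' must be numeric")
    else if (any(!is.finite(v))) msg <- c(msg, "'values' must be finite")
    else if (any(v < 0)) msg <- c(msg, "'values' must be nonnegative")
    nd <- length(dim(v))
    if (nd < 1L || nd > 3L)
        msg <- c(msg, "1 to 3 label dimensions are supported")
    if (length(object@isotopes) != nd)
        msg <- c(msg, "one IsotopeSpec is required per array dimension")
    else {
        ok <- vapply(object@isotopes, is, logical(1), "IsotopeSpec")
        if (!all(ok)) msg <- c(msg, "'isotopes' must contain IsotopeSpec objects")
        else {
            el <- vapply(object@isotopes, slot, character(1), "element")
            if (anyDuplicated(el))
                msg <- c(msg, "tracer isotopes must belong to distinct elements")
        }
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "IsotopologueArray", function(object) {
    labs <- vapply(object@isotopes, slot, character(1), "label")
    cat(sprintf("IsotopologueArray: %s | shape (%s) | total intensity %g\n",
                paste(labs, collapse = " x "),
                paste(dim(object@values), collapse = ","),
                sum(object@values)))
})

#' Binomial P correction lookup table
#'
#' Entry `entries[n+1, k+1] = C(n,k) p^k (1-p)^(n-k)` for `0 <= k <= n <=
#' nmax`: the probability that exactly `k` of `n` unlabeled atoms carry a
#' heavy isotope through natural abundance. Entries above the diagonal are
#' zero. Each defined row is a binomial distribution and sums to 1.
#'
#' @slot entries numeric matrix `(nmax+1) x (nmax+1)`.
#' @slot p numeric(1), natural-abundance fraction used to build the table.
#' @slot nmax integer(1), largest `n` covered.
#'
#' @seealso [buildPTable()]
#' @export
setClass("PTable",
    representation(entries = "matrix", p = "numeric", nmax = "integer"))

setValidity("PTable", function(object) {
    e <- object@entries
    if (nrow(e) != object@nmax + 1L || ncol(e) != object@nmax + 1L)
        return("'entries' must be (nmax+1) x (nmax+1)")
    if (any(e < 0) || any(e > 1)) return("entries must lie in [0, 1]")
    if (max(abs(rowSums(e) - 1)) > 1e-12)
        return("each row must sum to 1 within 1e-12")
    TRUE
})

setMethod("show", "PTable", function(object) {
    cat(sprintf("PTable: nmax = %d, p = %g\n", object@nmax, object@p))
})

#' Survival (S) correction lookup table
#'
#' Entry `entries[x+1] = (1-p)^(N-x)` for `0 <= x <= N`: the probability
#' that none of the `N - x` unlabeled atoms of a molecule with `x` labeled
#' atoms is heavy by natural abundance, i.e. the fraction of a corrected
#' isotopologue's intensity that survives at its own peak. Entries increase
#' with `x` and `entries[N+1] = 1`.
#'
#' @slot entries numeric vector of length `natoms + 1`.
#' @slot p numeric(1), natural-abundance fraction.
#' @slot natoms integer(1), atom count `N` of the tracer element.
#'
#' @seealso [buildSTable()]
#' @export
setClass("STable",
    representation(entries = "numeric", p = "numeric", natoms = "integer"))

setValidity("STable", function(object) {
    e <- object@entries
    if (length(e) != object@natoms + 1L)
        return("'entries' must have natoms + 1 values")
    if (any(e <= 0) || any(e > 1)) return("entries must lie in (0, 1]")
    if (is.unsorted(e)) return("entries must be nondecreasing in x")
    if (abs(e[length(e)] - 1) > 0) return("entry at x = N must equal 1")
    TRUE
})

setMethod("show", "STable", function(object) {
    cat(sprintf("STable: natoms = %d, p = %g\n", object@natoms, object@p))
})

#' Cache of P and S correction tables
#'
#' Correction tables depend only on the tracer isotope (element and
#' abundance) and the element's atom count, not on the molecule itself, so
#' one table pair serves every molecule sharing those. The cache is keyed
#' by `(label, abundance, atom count)`; a hit returns tables bit-identical
#' to a fresh build. Hit/miss counters are kept for reporting.
#'
#' @slot env environment holding the store and counters.
#'
#' @seealso [newTableCache()], [getOrBuildTables()], [cacheStats()]
#' @export
setClass("TableCache", representation(env = "environment"))

setMethod("show", "TableCache", function(object) {
    s <- cacheStats(object)
    cat(sprintf("TableCache: %d entries, %d hits, %d misses\n",
                s["entries"], s["hits"], s["misses"]))
})

#' Result of an iterative natural-abundance correction
#'
#' Holds the corrected intensities, the re-contaminated reconstruction used
#' for convergence monitoring (`reconstructed = addNA(corrected)`), the
#' number of refinement cycles run, and the final residual
#' `sum(abs(observed - reconstructed))` — the minimum over all visited
#' iterates, in the units of the input intensities.
#'
#' @slot corrected [IsotopologueArray-class] of corrected intensities.
#' @slot reconstructed [IsotopologueArray-class], forward contamination of
#'   `corrected`.
#' @slot iterations integer(1), refinement cycles executed (>= 1).
#' @slot residual numeric(1), sum of absolute reconstruction errors.
#'
#' @seealso [correctNA()]
#' @export
setClass("CorrectionResult",
    representation(corrected = "IsotopologueArray",
                   reconstructed = "IsotopologueArray",
                   iterations = "integer", residual = "numeric"))

setValidity("CorrectionResult", function(object) {
    msg <- character()
    if (!identical(dim(object@corrected@values),
                   dim(object@reconstructed@values)))
        msg <- c(msg, "corrected and reconstructed must share a shape")
    if (length(object@iterations) != 1L || object@iterations < 1L)
        msg <- c(msg, "'iterations' must be a single count >= 1")
    if (length(object@residual) != 1L || !is.finite(object@residual) ||
        object@residual < 0)
        msg <- c(msg, "'residual' must be a single nonnegative value")
    if (length(msg)) msg else TRUE
})

setMethod("show", "CorrectionResult", function(object) {
    cat(sprintf("CorrectionResult: %d iteration(s), residual %g\n",
                object@iterations, object@residual))
    show(object@corrected)
})

#' Predicted-peak inclusion threshold
#'
#' Defines the intensity threshold above which an isotopologue predicted by
#' the reconstruction, but absent from the input, is reported: a percentage
#' of the minimum, maximum or average observed peak intensity, taken over
#' the whole collection or per dataset. A disabled spec suppresses
#' predicted-peak output entirely.
#'
#' @slot percent numeric(1), percentage (>= 0) of the chosen statistic.
#' @slot statistic `"minimum"`, `"maximum"` or `"average"`.
#' @slot scope `"collection"` or `"dataset"`.
#' @slot enabled logical(1).
#'
#' @seealso [thresholdSpec()], [resolveThreshold()]
#' @export
setClass("ThresholdSpec",
    representation(percent = "numeric", statistic = "character",
                   scope = "character", enabled = "logical"))

setValidity("ThresholdSpec", function(object) {
    msg <- character()
    if (length(object@percent) != 1L || !is.finite(object@percent) ||
        object@percent < 0)
        msg <- c(msg, "'percent' must be a single nonnegative value")
    if (!object@statistic %in% c("minimum", "maximum", "average"))
        msg <- c(msg, "'statistic' must be minimum, maximum or average")
    if (!object@scope %in% c("collection", "dataset"))
        msg <- c(msg, "'scope' must be collection or dataset")
    if (length(object@enabled) != 1L || is.na(object@enabled))
        msg <- c(msg, "'enabled' must be TRUE or FALSE")
    if (length(msg)) msg else TRUE
})

#' Configuration of a collection-scale correction run
#'
#' Maps the columns of a delimited peak table (molecular formula, peak
#' intensity, one heavy-label count column per tracer isotope, optional
#' grouping columns such as sample or time point), names the input and
#' output files, and carries the run options: tracer isotopes with their
#' natural abundances, predicted-peak threshold, and table caching.
#'
#' @slot input,output character(1) file paths.
#' @slot delimiter character(1) field separator (default `","`).
#' @slot formulaColumn,intensityColumn character(1) column names.
#' @slot countColumns named character; names are isotope labels, values the
#'   corresponding count column names. Order defines the array dimensions.
#' @slot groupColumns character, extra columns whose values split rows of
#'   one formula into independent datasets (replicates, time points).
#' @slot isotopes list of [IsotopeSpec-class] in `countColumns` order.
#' @slot threshold [ThresholdSpec-class].
#' @slot cache logical(1), reuse P/S tables across datasets.
#'
#' @seealso [collectionConfig()], [readCollectionConfig()],
#'   [correctCollection()]
#' @export
setClass("CollectionConfig",
    representation(input = "character", output = "character",
                   delimiter = "character", formulaColumn = "character",
                   intensityColumn = "character", countColumns = "character",
                   groupColumns = "character", isotopes = "list",
                   threshold = "ThresholdSpec", cache = "logical"))

setValidity("CollectionConfig", function(object) {
    msg <- character()
    for (s in c("input", "output", "delimiter", "formulaColumn",
                "intensityColumn"))
        if (length(slot(object, s)) != 1L || !nzchar(slot(object, s)))
            msg <- c(msg, sprintf("'%s' must be a single non-empty string", s))
    n <- length(object@countColumns)
    if (n < 1L || n > 3L || is.null(names(object@countColumns)) ||
        any(!nzchar(names(object@countColumns))))
        msg <- c(msg, "'countColumns' must be 1-3 columns named by isotope label")
    if (length(object@isotopes) != n)
        msg <- c(msg, "one IsotopeSpec is required per count column")
    if (length(msg)) msg else TRUE
})

setMethod("show", "CollectionConfig", function(object) {
    cat("CollectionConfig\n")
    cat(sprintf("  input:  %s\n  output: %s\n", object@input, object@output))
    cat(sprintf("  tracers: %s\n",
                paste(sprintf("%s (col '%s', p=%g)",
                              names(object@countColumns), object@countColumns,
                              vapply(object@isotopes, slot, numeric(1),
                                     "abundance")),
                      collapse = ", ")))
    cat(sprintf("  cache: %s, threshold: %s\n", object@cache,
                if (object@threshold@enabled)
                    sprintf("%g%% of %s %s", object@threshold@percent,
                            object@threshold@scope, object@threshold@statistic)
                else "disabled"))
})

#' Peak collection read from a delimited file
#'
#' The raw rows of the input table (all fields kept as character so
#' pass-through columns survive byte-for-byte) together with the parsed
#' per-molecule datasets: for each group key, the parsed formula, the
#' heavy-label count tuples, intensities, and row-level quality
#' annotations.
#'
#' @slot raw data.frame of the input rows, all columns character.
#' @slot datasets list; one entry per (formula, grouping) dataset.
#' @slot config the [CollectionConfig-class] used to read the file.
#'
#' @seealso [readCollection()]
#' @export
setClass("PeakCollection",
    representation(raw = "data.frame", datasets = "list",
                   config = "CollectionConfig"))

setMethod("show", "PeakCollection", function(object) {
    cat(sprintf("PeakCollection: %d rows, %d datasets\n",
                nrow(object@raw), length(object@datasets)))
})

#' Summary of a collection-scale correction run
#'
#' @slot datasets integer(1), datasets processed.
#' @slot peaks integer(1), input peak rows.
#' @slot flagged named integer, rows flagged per quality-control code.
#' @slot predicted integer(1), predicted-but-unobserved peaks appended.
#' @slot iterations named integer, refinement cycles per dataset.
#' @slot elapsed numeric(1), wall-clock seconds.
#' @slot output character(1), path of the written file.
#'
#' @seealso [correctCollection()]
#' @export
setClass("RunReport",
    representation(datasets = "integer", peaks = "integer",
                   flagged = "integer", predicted = "integer",
                   iterations = "integer", elapsed = "numeric",
                   output = "character"))

setMethod("show", "RunReport", function(object) {
    cat("Natural abundance correction run\n")
    cat(sprintf("  datasets: %d, peaks: %d, predicted peaks added: %d\n",
                object@datasets, object@peaks, object@predicted))
    if (length(object@flagged) && any(object@flagged > 0)) {
        f <- object@flagged[object@flagged > 0]
        cat(sprintf("  flagged: %s\n",
                    paste(sprintf("%s=%d", names(f), f), collapse = ", ")))
    }
    if (length(object@iterations))
        cat(sprintf("  iterations per dataset: median %g, max %d\n",
                    stats::median(object@iterations), max(object@iterations)))
    cat(sprintf("  output: %s (%.2f s)\n", object@output, object@elapsed))
})
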