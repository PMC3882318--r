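## Built-in natural-abundance fractions of the supported tracer isotopes.
## User configurations may override any of these or add further isotopes.
.default_isotopes <- list(
    "13C" = list(element = "C", abundance = 0.01109),
    "15N" = list(element = "N", abundance = 0.0037),
    "2H"  = list(element = "H", abundance = 0.00015)
)

#' Built-in tracer isotopes
#'
#' Returns the registry of tracer isotopes known by default: 13C
#' (p = 0.01109), 15N (p = 0.0037) and 2H (p = 0.00015), where p is the
#' natural-abundance fraction of the heavy isotope. All values can be
#' overridden per run (see [isotopeSpec()] and [collectionConfig()]).
#'
#' @return Named list of [IsotopeSpec-class] objects.
#' @export
defaultIsotopes <- function() {
    lapply(stats::setNames(names(.default_isotopes),
                           names(.default_isotopes)), isotopeSpec)
}

#' Construct a tracer isotope specification
#'
#' For the built-in labels (`"13C"`, `"15N"`, `"2H"`) the element and
#' abundance default to the registry values; either can be overridden. For
#' any other label in mass-number + element style (e.g. `"18O"`), the
#' element is inferred from the label and the abundance must be supplied.
#'
#' @param label character(1) isotope name, e.g. `"13C"`.
#' @param element character(1) element symbol; inferred when omitted.
#' @param abundance numeric(1) natural-abundance fraction in `[0, 1)`.
#' @return An [IsotopeSpec-class].
#'
#' @examples
#' isotopeSpec("13C")
#' isotopeSpec("13C", abundance = 0.011)   # override
#' isotopeSpec("18O", abundance = 0.00205)
#'
#' @export
isotopeSpec <- function(label, element = NULL, abundance = NULL) {
    stopifnot(is.character(label), length(label) == 1L)
    reg <- .default_isotopes[[label]]
    if (is.null(element))
        element <- if (!is.null(reg)) reg$element
                   else sub("^[0-9]+", "", label)
    if (is.null(abundance)) {
        if (is.null(reg))
            stop(sprintf("isotope '%s' is not built in; supply its natural abundance",
                         label))
        abundance <- reg$abundance
    }
    new("IsotopeSpec", label = label, element = element,
        abundance = as.numeric(abundance))
}

## Resolve labels + optional named abundance overrides into IsotopeSpec list.
.resolveIsotopes <- function(labels, abundances = NULL) {
    lapply(labels, function(l) {
        ab <- if (!is.null(abundances) && l %in% names(abundances))
                  abundances[[l]] else NULL
        isotopeSpec(l, abundance = ab)
    })
}

#' Binomial P correction term
#'
#' Evaluates `P(n, k; p) = C(n,k) p^k (1-p)^(n-k)`, the probability that
#' exactly `k` of `n` atoms carry a heavy isotope of natural-abundance
#' fraction `p`. Five numerically distinct implementations are provided for
#' cross-checking at large `n` and very small `p`, where the binomial
#' coefficient is huge while the powers underflow:
#'
#' * `"org"` — interleaved product: coefficient factors `(n-k+j)/j` are
#'   alternated with `p` and `(1-p)` factors so intermediates stay near the
#'   final magnitude (the default; used for all correction tables),
#' * `"choose"` — exact arbitrary-precision integer factorials,
#' * `"comb"` — exact arbitrary-precision multiplicative coefficient,
#' * `"comb2"` — log-gamma evaluation,
#' * `"logReal"` — base-10 logarithmic version of the interleaving.
#'
#' @param n,k integer vectors (recycled), `0 <= k <= n`.
#' @param p numeric(1), natural-abundance fraction in `[0, 1)`.
#' @param method one of `"org"`, `"choose"`, `"comb"`, `"comb2"`,
#'   `"logReal"`.
#' @return numeric vector of probabilities.
#'
#' @examples
#' binomialPTerm(12, 1, 0.01109)             # ~0.1177
#' binomialPTerm(500, 3, 0.00015, "choose")
#'
#' @seealso [buildPTable()], [pTermMatrix()]
#' @export
binomialPTerm <- function(n, k, p,
                          method = c("org", "choose", "comb", "comb2",
                                     "logReal")) {
    method <- match.arg(method)
    stopifnot(length(p) == 1L, is.finite(p))
    if (p < 0 || p >= 1) stop("require 0 <= p < 1")
    n <- as.integer(n); k <- as.integer(k)
    if (anyNA(n) || anyNA(k) || any(k < 0) || any(n < 0) || any(k > n))
        stop("require integer 0 <= k <= n")
    r <- mapply(function(ni, ki) cpp_p_term(ni, ki, p, method), n, k)
    as.numeric(r)
}

#' Full P-term matrix for one method
#'
#' Builds the matrix of all `P(n, k; p)` for `0 <= k <= n <= nmax`
#' (entries above the diagonal are zero) with a chosen implementation.
#' Mainly used to benchmark the implementations against each other over
#' the full index range.
#'
#' @inheritParams binomialPTerm
#' @param nmax integer(1), largest `n`.
#' @return numeric `(nmax+1) x (nmax+1)` matrix, row `n+1` / column `k+1`.
#' @export
pTermMatrix <- function(nmax, p, method = c("org", "choose", "comb", "comb2",
                                            "logReal")) {
    method <- match.arg(method)
    stopifnot(length(nmax) == 1L, nmax >= 0, length(p) == 1L)
    if (p < 0 || p >= 1) stop("require 0 <= p < 1")
    cpp_p_matrix(as.integer(nmax), p, method)
}

#' Build a P correction table
#'
#' P tables are built with the interleaved (`"org"`) evaluation; see
#' [binomialPTerm()] for the numerics.
#'
#' @param nmax integer(1), largest number of unlabeled atoms covered
#'   (typically the tracer element's atom count in the molecule).
#' @param p numeric(1), natural-abundance fraction.
#' @return A [PTable-class].
#' @export
buildPTable <- function(nmax, p) {
    new("PTable", entries = pTermMatrix(nmax, p, "org"), p = p,
        nmax = as.integer(nmax))
}

#' Build an S correction table
#'
#' `S[x] = (1-p)^(N-x)` is the probability that none of the `N - x`
#' unlabeled atoms of an isotopologue with `x` labeled atoms is heavy by
#' natural abundance — the fraction of its corrected intensity that
#' survives at its own peak. The correction divides by this survival
#' factor; e.g. for a 17-carbon molecule an isotopologue with 5 labeled
#' carbons keeps `(1-p)^12 ~ 0.8747` of its intensity at its own peak.
#'
#' @param natoms integer(1), atom count `N` of the tracer element.
#' @param p numeric(1), natural-abundance fraction.
#' @return An [STable-class].
#' @export
buildSTable <- function(natoms, p) {
    stopifnot(length(natoms) == 1L, natoms >= 0, length(p) == 1L)
    if (p < 0 || p >= 1) stop("require 0 <= p < 1")
    x <- 0:natoms
    new("STable", entries = (1 - p)^(natoms - x), p = p,
        natoms = as.integer(natoms))
}

#' Create an empty P/S table cache
#'
#' @return A [TableCache-class] with no entries.
#' @export
newTableCache <- function() {
    e <- new.env(parent = emptyenv())
    e$store <- list()
    e$hits <- 0L
    e$misses <- 0L
    new("TableCache", env = e)
}

#' Cache statistics
#'
#' @param cache a [TableCache-class].
#' @return Named integer vector with `entries`, `hits` and `misses`.
#' @export
cacheStats <- function(cache) {
    stopifnot(is(cache, "TableCache"))
    c(entries = length(cache@env$store), hits = cache@env$hits,
      misses = cache@env$misses)
}

#' Fetch or build the P/S tables for one tracer dimension
#'
#' Tables depend only on the tracer isotope and the tracer element's atom
#' count, so they are shared across all molecules (and replicates) with the
#' same count. The cache key includes the abundance, so overridden
#' abundances never collide with the defaults. With `cache = NULL` the
#' tables are always rebuilt; cached and fresh tables are bit-identical.
#'
#' @param cache a [TableCache-class], or `NULL` to disable caching.
#' @param isotope an [IsotopeSpec-class].
#' @param size integer(1), the tracer element's atom count `N`.
#' @return `list(p = PTable, s = STable)`.
#' @export
getOrBuildTables <- function(cache, isotope, size) {
    stopifnot(is(isotope, "IsotopeSpec"), length(size) == 1L, size >= 0)
    size <- as.integer(size)
    build <- function() list(p = buildPTable(size, isotope@abundance),
                             s = buildSTable(size, isotope@abundance))
    if (is.null(cache)) return(build())
    stopifnot(is(cache, "TableCache"))
    key <- paste(isotope@label,
                 sprintf("%.17g", isotope@abundance), size, sep = "|")
    hit <- cache@env$store[[key]]
    if (!is.null(hit)) {
        cache@env$hits <- cache@env$hits + 1L
        return(hit)
    }
    cache@env$misses <- cache@env$misses + 1L
    tabs <- build()
    cache@env$store[[key]] <- tabs
    tabs
}
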