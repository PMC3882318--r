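#' Parse a molecular formula string
#'
#' Parses plain element/count formulas as they appear in peak-table cells,
#' e.g. `"C17H27N3O17P2"` (UDP-GlcNAc). An element symbol is an uppercase
#' letter optionally followed by one lowercase letter; a missing count means
#' 1; repeated symbols are summed. Parenthesized groups, hydrates, adducts
#' and charge states are rejected — peak identification upstream is expected
#' to supply neutral elemental formulas.
#'
#' @param text character(1), the formula string.
#'
#' @return A named integer vector mapping element symbol to atom count
#'   (every count >= 1; absent elements are simply absent, i.e. count 0).
#'
#' @examples
#' parseFormula("C17H27N3O17P2")
#' parseFormula("CO")
#'
#' @seealso [formatFormula()], [maxLabelCount()]
#' @export
parseFormula <- function(text) {
    if (!is.character(text) || length(text) != 1L || is.na(text) ||
        !nzchar(text))
        stop("formula must be a single non-empty string")
    m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
    tokens <- regmatches(text, list(m))[[1]]
    covered <- sum(attr(m, "match.length"))
    if (m[1] == -1L || covered != nchar(text)) {
        # locate the first character not covered by any token
        hit <- rep(FALSE, nchar(text))
        for (i in seq_along(tokens))
            hit[seq(m[i], length.out = attr(m, "match.length")[i])] <- TRUE
        bad <- which(!hit)[1]
        if (is.na(bad)) bad <- 1L
        stop(sprintf("cannot parse formula '%s': unexpected '%s' at position %d",
                     text, substr(text, bad, bad), bad))
    }
    sym <- sub("[0-9]*$", "", tokens)
    cnt <- sub("^[A-Z][a-z]?", "", tokens)
    unknown <- setdiff(sym, .element_symbols)
    if (length(unknown))
        stop(sprintf("unknown element symbol '%s' in formula '%s'",
                     unknown[1], text))
    n <- ifelse(nzchar(cnt), suppressWarnings(as.integer(cnt)), 1L)
    if (anyNA(n))
        stop(sprintf("invalid atom count in formula '%s'", text))
    if (any(n == 0L))
        stop(sprintf("zero atom count for element '%s' in formula '%s'",
                     sym[which(n == 0L)[1]], text))
    counts <- vapply(split(n, factor(sym, levels = unique(sym))), sum,
                     integer(1))
    counts
}

#' Serialize a parsed formula back to a string
#'
#' Inverse of [parseFormula()] up to element order: `parseFormula(
#' formatFormula(f))` reproduces the element/count mapping.
#'
#' @param counts named integer vector as returned by [parseFormula()].
#' @return character(1) formula string; counts of 1 are implicit.
#' @export
formatFormula <- function(counts) {
    stopifnot(is.numeric(counts), !is.null(names(counts)), all(counts >= 1))
    paste0(names(counts), ifelse(counts > 1, as.character(counts), ""),
           collapse = "")
}

#' Maximum heavy-label count of a tracer in a molecule
#'
#' The number of heavy atoms of a tracer isotope a molecule can carry is
#' bounded by the atom count of the tracer's element in its formula (the
#' per-element C_Max). This bound sizes the isotopologue array dimension
#' and the P/S correction tables, and any observed count above it is a
#' quality-control failure.
#'
#' @param counts named integer vector from [parseFormula()].
#' @param isotope an [IsotopeSpec-class], or an isotope label known to
#'   [defaultIsotopes()].
#' @return integer(1): the element's atom count, 0 if absent.
#'
#' @examples
#' f <- parseFormula("C17H27N3O17P2")
#' maxLabelCount(f, "13C")  # 17
#' maxLabelCount(f, "15N")  # 3
#'
#' @export
maxLabelCount <- function(counts, isotope) {
    iso <- if (is(isotope, "IsotopeSpec")) isotope else isotopeSpec(isotope)
    n <- counts[iso@element]
    if (is.na(n)) 0L else as.integer(n)
}
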