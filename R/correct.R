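#' Construct an isotopologue intensity array
#'
#' @param values numeric vector (single tracer), matrix or array of
#'   nonnegative intensities; entry `(x1, .., xn)` is the intensity of the
#'   isotopologue with `x_e` heavy atoms of tracer `e` (0-based counts).
#'   The array must span the full `0..N_e` range per dimension; unobserved
#'   isotopologues are zeros.
#' @param isotopes isotope labels (character) or list of
#'   [IsotopeSpec-class], one per dimension, in dimension order.
#' @param abundances optional named numeric, natural-abundance overrides by
#'   isotope label.
#' @return An [IsotopologueArray-class].
#'
#' @examples
#' # a 9-carbon molecule, intensities at 13C counts 0..9
#' isotopologueArray(c(0.5, 0, 0, 0.15, 0.1, 0, 0, 0, 0, 0.25), "13C")
#'
#' @export
isotopologueArray <- function(values, isotopes, abundances = NULL) {
    if (is.null(dim(values)))
        values <- array(as.numeric(values), dim = length(values))
    if (is.character(isotopes))
        isotopes <- .resolveIsotopes(isotopes, abundances)
    if (is(isotopes, "IsotopeSpec")) isotopes <- list(isotopes)
    storage.mode(values) <- "double"
    labs <- vapply(isotopes, slot, character(1), "label")
    dimnames(values) <- stats::setNames(
        lapply(dim(values), function(d) as.character(seq_len(d) - 1L)), labs)
    new("IsotopologueArray", values = values, isotopes = isotopes)
}

#' @describeIn IsotopologueArray-class the dense intensity array.
#' @param x an `IsotopologueArray`.
#' @export
setMethod("intensities", "IsotopologueArray", function(x) x@values)

#' @describeIn IsotopologueArray-class the tracer isotopes, one per
#'   dimension.
#' @export
setMethod("labelOrder", "IsotopologueArray", function(x) x@isotopes)

#' @describeIn IsotopologueArray-class named integer of per-dimension
#'   maximum label counts `N_e`.
#' @export
setMethod("labelMaxima", "IsotopologueArray", function(x) {
    stats::setNames(as.integer(dim(x@values)) - 1L,
                    vapply(x@isotopes, slot, character(1), "label"))
})

#' Enumerate the index tuples dominated by a bound
#'
#' Streams every tuple `i` with `0 <= i_e <= x_e` componentwise —
#' the "ultimate" set when `inclusive = TRUE`, or the "penultimate" set
#' (excluding `x` itself) when `inclusive = FALSE`. These sets are the
#' summation domains of the correction: the forward contamination of peak
#' `x` sums over the ultimate set, while the subtraction sweep removes the
#' already-corrected contributions of the penultimate set. For
#' one-dimensional data the sets reduce to plain integer ranges.
#'
#' @param x integer vector, the bounding index tuple (0-based counts).
#' @param inclusive logical(1), include `x` itself.
#' @return Integer matrix, one tuple per row, in ascending lexicographic
#'   order (last component fastest).
#'
#' @examples
#' iterateUpto(c(1, 1))                    # (0,0) (0,1) (1,0)
#' iterateUpto(c(1, 1), inclusive = TRUE)  # ... and (1,1)
#' iterateUpto(5)                          # 0..4 as a one-column matrix
#'
#' @export
iterateUpto <- function(x, inclusive = FALSE) {
    x <- as.integer(x)
    stopifnot(length(x) >= 1L, all(x >= 0))
    grids <- rev(lapply(x, function(xi) 0:xi))
    g <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
    g <- g[, rev(seq_len(ncol(g))), drop = FALSE]
    dimnames(g) <- NULL
    if (!inclusive) g <- g[-nrow(g), , drop = FALSE]
    g
}

#' Natural-abundance transition kernel between two isotopologues
#'
#' `K(x, i) = prod_e P_e[N_e - i_e, x_e - i_e]`: the probability that a
#' molecule carrying `i_e` tracer-labeled atoms per element acquires
#' exactly `x_e - i_e` further heavy atoms per element through natural
#' abundance, so that it is observed at peak `x`. The diagonal
#' `K(x, x) = prod_e (1-p_e)^(N_e - x_e)` equals the product of the
#' S-table entries at `x`.
#'
#' @param x,i integer index tuples (0-based counts), `i <= x`
#'   componentwise and `x <= N` per dimension.
#' @param ptables list of [PTable-class], one per dimension, built with
#'   `nmax = N_e`.
#' @return numeric(1) probability.
#' @export
naKernel <- function(x, i, ptables) {
    if (is(ptables, "PTable")) ptables <- list(ptables)
    x <- as.integer(x); i <- as.integer(i)
    stopifnot(length(x) == length(i), length(x) == length(ptables))
    if (any(i < 0) || any(i > x)) stop("require 0 <= i <= x componentwise")
    k <- 1
    for (e in seq_along(ptables)) {
        N <- ptables[[e]]@nmax
        if (x[e] > N) stop("index exceeds the table's atom count")
        k <- k * ptables[[e]]@entries[N - i[e] + 1L, x[e] - i[e] + 1L]
    }
    k
}

## ---- internal sweep machinery --------------------------------------------
## Per dimension e, kernel column for target coordinate xe:
##   kc[[e]][[xe+1]][i+1] = P_e[N_e - i, xe - i],  i = 0..xe.
.kernelCols <- function(ptab, N) {
    lapply(0:N, function(xe) {
        i <- 0:xe
        ptab[cbind(N - i + 1L, xe - i + 1L)]
    })
}

.kernelColsFor <- function(isotopes, maxima, cache = NULL) {
    lapply(seq_along(isotopes), function(e) {
        tabs <- getOrBuildTables(cache, isotopes[[e]], maxima[e])
        .kernelCols(tabs$p@entries, maxima[e])
    })
}

## Forward contamination: out[x] = sum_{i <= x} clean[i] * K(x, i).
.addNAValues <- function(clean, kc, fast = TRUE) {
    dims <- dim(clean)
    if (length(dims) == 1L && fast) {
        N <- dims[1L] - 1L
        out <- array(0, dims)
        for (x in 0:N)
            out[x + 1L] <- sum(clean[seq_len(x + 1L)] * kc[[1L]][[x + 1L]])
        return(out)
    }
    out <- array(0, dims)
    nd <- length(dims)
    for (l in seq_len(prod(dims))) {
        tup <- arrayInd(l, dims)[1L, ]
        kern <- kc[[1L]][[tup[1L]]]
        if (nd > 1L)
            for (e in 2:nd) kern <- outer(kern, kc[[e]][[tup[e]]])
        sub <- do.call(`[`, c(list(clean), lapply(tup, seq_len),
                              list(drop = FALSE)))
        out[l] <- sum(sub * kern)
    }
    out
}

## Ascending triangular sweep:
##   corr[x] = (data[x] - sum_{i < x} corr[i] K(x, i)) / K(x, x),
## clamped at zero when `clamp`. Ascending linear order is a topological
## order for componentwise dominance, so lower entries are final when used.
.sweepValues <- function(data, kc, clamp = TRUE, fast = TRUE) {
    dims <- dim(data)
    if (length(dims) == 1L && fast) {
        N <- dims[1L] - 1L
        corr <- array(0, dims)
        for (x in 0:N) {
            kern <- kc[[1L]][[x + 1L]]
            s <- if (x > 0) sum(corr[seq_len(x)] * kern[seq_len(x)]) else 0
            v <- (data[x + 1L] - s) / kern[x + 1L]
            corr[x + 1L] <- if (clamp) max(v, 0) else v
        }
        return(corr)
    }
    corr <- array(0, dims)
    nd <- length(dims)
    for (l in seq_len(prod(dims))) {
        tup <- arrayInd(l, dims)[1L, ]
        kern <- kc[[1L]][[tup[1L]]]
        if (nd > 1L)
            for (e in 2:nd) kern <- outer(kern, kc[[e]][[tup[e]]])
        sub <- do.call(`[`, c(list(corr), lapply(tup, seq_len),
                              list(drop = FALSE)))
        klast <- kern[length(kern)]
        s <- sum(sub * kern)  # corr[l] is still 0: penultimate sum
        v <- (data[l] - s) / klast
        corr[l] <- if (clamp) max(v, 0) else v
    }
    corr
}

## Iterative refinement, see correctNA() for the contract.
.correctCore <- function(data, kc, maxIterations = 100L, fast = TRUE) {
    corr <- .sweepValues(data, kc, clamp = TRUE, fast = fast)
    calc <- .addNAValues(corr, kc, fast = fast)
    best_e <- sum(abs(data - calc))
    best <- corr; best_calc <- calc
    iters <- 1L
    while (iters < maxIterations) {
        delta <- .sweepValues(data - calc, kc, clamp = FALSE, fast = fast)
        cand <- pmax(corr + delta, 0)
        cand_calc <- .addNAValues(cand, kc, fast = fast)
        e <- sum(abs(data - cand_calc))
        if (!(e < best_e)) break
        corr <- cand; calc <- cand_calc
        best <- cand; best_calc <- cand_calc; best_e <- e
        iters <- iters + 1L
    }
    list(corrected = best, reconstructed = best_calc, iterations = iters,
         residual = best_e)
}

.rewrap <- function(template, values) {
    dimnames(values) <- dimnames(template@values)
    new("IsotopologueArray", values = values, isotopes = template@isotopes)
}

#' Forward natural-abundance contamination (addNA)
#'
#' Applies the forward model to a clean (tracer-only) isotopologue
#' distribution: `contaminated(x) = sum_{i <= x} clean(i) * K(x, i)`, with
#' the transition kernel of [naKernel()]. Because the array spans the full
#' `0..N_e` index range in every dimension, total intensity is conserved.
#' This is the operation whose inverse the correction computes; it is also
#' used to re-contaminate corrected intensities for convergence checking
#' and predicted-peak reporting.
#'
#' @param x an [IsotopologueArray-class].
#' @param cache optional [TableCache-class] for the P tables.
#' @param ... unused.
#' @return An [IsotopologueArray-class] of contaminated intensities.
#'
#' @examples
#' clean <- isotopologueArray(c(0.5, 0, 0, 0.15, 0.1, 0, 0, 0, 0, 0.25), "13C")
#' round(intensities(addNA(clean)), 4)
#'
#' @export
setMethod("addNA", "IsotopologueArray", function(x, cache = NULL, ...) {
    kc <- .kernelColsFor(x@isotopes, labelMaxima(x), cache)
    .rewrap(x, .addNAValues(x@values, kc))
})

#' Single clamped subtraction sweep (subtractNA)
#'
#' One ascending pass over the index space in lexicographic order:
#' `corr(x) = max(0, (data(x) - sum_{i < x} corr(i) K(x, i)) / K(x, x))`,
#' where the sum runs over the penultimate set of `x` and uses
#' already-updated lower entries. This is the exact triangular inverse of
#' [addNA()] whenever no clamp triggers, and the initial estimate of the
#' iterative [correctNA()].
#'
#' @inheritParams addNA,IsotopologueArray-method
#' @return An [IsotopologueArray-class] of corrected intensities.
#' @export
setMethod("solvePass", "IsotopologueArray", function(x, cache = NULL, ...) {
    kc <- .kernelColsFor(x@isotopes, labelMaxima(x), cache)
    .rewrap(x, .sweepValues(x@values, kc, clamp = TRUE))
})

#' Iterative natural-abundance correction
#'
#' Removes the natural-abundance contribution from observed isotopologue
#' intensities by iterative refinement. The initial estimate is the clamped
#' triangular sweep of [solvePass()]. Each cycle re-contaminates the
#' current estimate with [addNA()], forms the residual
#' `observed - reconstructed` and its error `sum(abs(residual))`, and stops
#' when the error no longer strictly decreases (or `maxIterations` is
#' reached), returning the best iterate seen. Otherwise the estimate is
#' updated by an unclamped sweep of the residual, clamping the combined
#' estimate at zero. The procedure is deterministic. On noise-free input
#' the first sweep is already exact and a single cycle is performed.
#'
#' @param x an [IsotopologueArray-class] of observed intensities.
#' @param maxIterations integer(1), refinement-cycle cap (default 100).
#' @param cache optional [TableCache-class].
#' @param ... unused.
#' @return A [CorrectionResult-class].
#'
#' @examples
#' obs <- numeric(18)
#' obs[6:17] <- c(187.9, 60.5, 109.8, 418.4, 23.1, 165, 1438, 1215.9,
#'                4235.8, 1562.5, 1253.9, 175.8)
#' res <- correctNA(isotopologueArray(obs, "13C"))
#' round(intensities(corrected(res)), 2)
#'
#' @export
setMethod("correctNA", "IsotopologueArray",
          function(x, maxIterations = 100L, cache = NULL, ...) {
    stopifnot(length(maxIterations) == 1L, maxIterations >= 1L)
    kc <- .kernelColsFor(x@isotopes, labelMaxima(x), cache)
    r <- .correctCore(x@values, kc, as.integer(maxIterations))
    new("CorrectionResult",
        corrected = .rewrap(x, r$corrected),
        reconstructed = .rewrap(x, r$reconstructed),
        iterations = r$iterations, residual = r$residual)
})

#' @describeIn CorrectionResult-class the corrected intensities.
#' @param x a `CorrectionResult`.
#' @export
setMethod("corrected", "CorrectionResult", function(x) x@corrected)

#' @describeIn CorrectionResult-class the re-contaminated reconstruction.
#' @export
setMethod("reconstructed", "CorrectionResult", function(x) x@reconstructed)

#' @describeIn CorrectionResult-class refinement cycles executed.
#' @export
setMethod("iterations", "CorrectionResult", function(x) x@iterations)

#' @describeIn CorrectionResult-class final sum of absolute reconstruction
#'   errors, in intensity units.
#' @export
setMethod("residual", "CorrectionResult", function(x) x@residual)
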