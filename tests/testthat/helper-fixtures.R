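# Shared fixtures and independent oracles.

# Observed 13C isotopologue intensities of UDP-GlcNAc (C17H27N3O17P2):
# counts 5..16 carry signal, all other counts are unobserved (zero).
udpObserved <- function() {
    obs <- numeric(18)
    obs[(5:16) + 1] <- c(187.9, 60.5, 109.8, 418.4, 23.1, 165, 1438,
                         1215.9, 4235.8, 1562.5, 1253.9, 175.8)
    obs
}

# Published corrected intensities for the same vector (counts 5..16),
# reported to 2 decimals; count 9 clamps to exactly 0.
udpCorrectedReference <- function() {
    c(214.81, 39.81, 116.15, 449.36, 0, 176.39, 1523.77, 1183.78,
      4360.57, 1420.73, 1231.68, 149.9)
}

# Independent oracle for the binomial P term: direct factorial evaluation,
# valid for small n only (factorial() overflows beyond n = 170).
oraclePTerm <- function(n, k, p) {
    factorial(n) / (factorial(k) * factorial(n - k)) * p^k * (1 - p)^(n - k)
}

# Independent brute-force contamination matrix over the flattened index
# space: M[x, i] = prod_e C(N_e - i_e, x_e - i_e) p_e^(x_e-i_e)
# (1-p_e)^(N_e-x_e), built from base R choose() with explicit loops.
oracleKernelMatrix <- function(maxima, ps) {
    dims <- maxima + 1L
    ncell <- prod(dims)
    tuples <- arrayInd(seq_len(ncell), dims) - 1L
    M <- matrix(0, ncell, ncell)
    for (xl in seq_len(ncell)) {
        for (il in seq_len(ncell)) {
            x <- tuples[xl, ]; i <- tuples[il, ]
            if (all(i <= x)) {
                k <- 1
                for (e in seq_along(maxima)) {
                    n <- maxima[e] - i[e]; kk <- x[e] - i[e]; p <- ps[e]
                    k <- k * choose(n, kk) * p^kk * (1 - p)^(n - kk)
                }
                M[xl, il] <- k
            }
        }
    }
    M
}

# Oracle correction: generic dense linear solve of M corr = data (no
# clamping; valid when the true solution is nonnegative).
oracleCorrect <- function(data, maxima, ps) {
    M <- oracleKernelMatrix(maxima, ps)
    array(solve(M, as.vector(data)), dim = maxima + 1L)
}

relErr <- function(got, want) sum(abs(got - want)) / max(sum(abs(want)), 1e-300)
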