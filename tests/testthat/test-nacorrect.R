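test_that("iterateUpto enumerates the dominated index sets", {
    expect_identical(iterateUpto(c(1, 1)),
                     rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L)))
    expect_identical(iterateUpto(c(1, 1), inclusive = TRUE),
                     rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L)))
    expect_identical(iterateUpto(5), matrix(0:4, ncol = 1))
    expect_identical(nrow(iterateUpto(c(2, 3, 1), inclusive = TRUE)),
                     3L * 4L * 2L)
})

test_that("the transition kernel factorizes and matches the binomial", {
    p <- 0.01109
    pt <- buildPTable(17, p)
    # one extra heavy atom on a 5-labeled 17-carbon molecule
    expect_equal(naKernel(6, 5, list(pt)), 12 * p * (1 - p)^11,
                 tolerance = 1e-12)
    # diagonal equals the S-table product
    st <- buildSTable(17, p)
    for (x in c(0L, 5L, 17L))
        expect_equal(naKernel(x, x, list(pt)), st@entries[x + 1])
    # 2-D kernel is the product of the 1-D kernels
    ptN <- buildPTable(6, 0.0037)
    expect_equal(naKernel(c(4, 3), c(2, 1), list(pt, ptN)),
                 naKernel(4, 2, list(pt)) * naKernel(3, 1, list(ptN)))
    expect_error(naKernel(2, 3, list(pt)), "i <= x")
})

test_that("forward contamination reproduces the reference simulated rows", {
    aC <- intensities(addNA(simulatedCarbonVector()))
    expect_equal(round(aC[1:6], 4),
                 c(0.4523, 0.0456, 0.0020, 0.1403, 0.1040, 0.0056),
                 ignore_attr = TRUE)
    expect_equal(unname(aC[10]), 0.25)  # the fully labeled peak cannot gain mass
    aN <- intensities(addNA(simulatedNitrogenVector()))
    expect_equal(round(aN[1:5], 4),
                 c(0.4890, 0.0109, 0.0001, 0.0989, 0.0011),
                 ignore_attr = TRUE)
    expect_equal(unname(aN[7]), 0.4)
})

test_that("contamination conserves total intensity and p=0 is the identity", {
    set.seed(301)
    for (i in 1:10) {
        maxima <- sample(3:14, sample(1:2, 1))
        iso <- list(isotopeSpec("13C"), isotopeSpec("15N"))[seq_along(maxima)]
        clean <- makeCleanArray(maxima, iso, normalize = FALSE)
        cont <- addNA(clean)
        expect_lt(abs(sum(intensities(cont)) - sum(intensities(clean))) /
                  sum(intensities(clean)), 1e-12)
        expect_true(all(intensities(cont) >= 0))
    }
    v <- isotopologueArray(c(1, 2, 3), list(isotopeSpec("13C", abundance = 0)))
    expect_equal(intensities(addNA(v)), intensities(v))
})

test_that("a single clamped sweep inverts contamination and clamps negatives", {
    obs <- isotopologueArray(udpObserved(), "13C")
    corr <- intensities(solvePass(obs))
    expect_equal(round(unname(corr[6]), 2), 214.81)   # 187.9 / (1-p)^12
    expect_equal(unname(corr[10]), 0)                 # count 9 goes negative, clamps
    # exact triangular inverse when nothing clamps
    set.seed(99)
    v <- isotopologueArray(rlnorm(13), "13C")
    round_trip <- solvePass(addNA(v))
    expect_lt(relErr(intensities(round_trip), intensities(v)), 1e-10)
})

test_that("iterative correction reproduces the published single-label result", {
    res <- correctNA(isotopologueArray(udpObserved(), "13C"))
    got <- intensities(corrected(res))[(5:16) + 1]
    expect_lt(max(abs(got - udpCorrectedReference())), 0.02)
    expect_identical(unname(got[5]), 0)       # exact clamp at count 9
    expect_true(all(intensities(corrected(res)) >= 0))
    expect_equal(intensities(reconstructed(res)),
                 intensities(addNA(corrected(res))))
    expect_gte(residual(res), 0)
})

test_that("correction equals a brute-force dense triangular solve", {
    # 1-D
    set.seed(17)
    clean <- rlnorm(13)  # strictly positive: no clamping in the solution
    p <- 0.01109
    data <- intensities(addNA(isotopologueArray(clean, "13C")))
    want <- oracleCorrect(data, 12L, p)
    got <- intensities(corrected(correctNA(isotopologueArray(data, "13C"))))
    expect_lt(relErr(got, want), 1e-9)
    # 2-D
    cleanM <- matrix(rlnorm(30), 5, 6)
    arr <- isotopologueArray(cleanM, c("13C", "15N"))
    dataM <- intensities(addNA(arr))
    want2 <- oracleCorrect(dataM, c(4L, 5L), c(0.01109, 0.0037))
    got2 <- intensities(corrected(correctNA(
        isotopologueArray(dataM, c("13C", "15N")))))
    expect_lt(relErr(got2, want2), 1e-9)
})

test_that("contaminate-then-correct recovers random clean arrays", {
    set.seed(2024)
    for (i in 1:8) {
        nd <- sample(1:3, 1)
        maxima <- sample(2:9, nd)
        iso <- list(isotopeSpec("13C"), isotopeSpec("15N"),
                    isotopeSpec("2H"))[seq_len(nd)]
        clean <- makeCleanArray(maxima, iso)
        res <- correctNA(addNA(clean))
        expect_lt(relErr(intensities(corrected(res)), intensities(clean)),
                  1e-8)
    }
})

test_that("dimension order is a pure relabeling", {
    set.seed(5)
    m <- matrix(rlnorm(24), 4, 6)   # (13C up to 3) x (15N up to 5)
    a <- correctNA(isotopologueArray(m, c("13C", "15N")))
    b <- correctNA(isotopologueArray(t(m), c("15N", "13C")))
    expect_equal(intensities(corrected(a)),
                 t(intensities(corrected(b))), ignore_attr = TRUE)
})

test_that("the 1-D fast path and the generic n-D path agree exactly", {
    set.seed(12)
    data <- array(rlnorm(15), dim = 15)
    kc <- NAcorrectR:::.kernelColsFor(list(isotopeSpec("13C")), 14L)
    expect_identical(NAcorrectR:::.addNAValues(data, kc, fast = TRUE),
                     NAcorrectR:::.addNAValues(data, kc, fast = FALSE))
    expect_identical(NAcorrectR:::.sweepValues(data, kc, fast = TRUE),
                     NAcorrectR:::.sweepValues(data, kc, fast = FALSE))
})

test_that("zero-abundance tracers make the correction the identity", {
    iso <- list(isotopeSpec("13C", abundance = 0),
                isotopeSpec("15N", abundance = 0))
    m <- isotopologueArray(matrix(1:12, 3, 4), iso)
    res <- correctNA(m)
    expect_equal(intensities(corrected(res)), intensities(m))
    expect_identical(iterations(res), 1L)
    expect_equal(residual(res), 0)
})

test_that("non-finite and negative inputs are rejected", {
    expect_error(isotopologueArray(c(1, NA, 2), "13C"), "finite")
    expect_error(isotopologueArray(c(1, -1, 2), "13C"), "nonnegative")
    expect_error(isotopologueArray(matrix(1, 2, 2), c("13C", "13C")),
                 "distinct")
})
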