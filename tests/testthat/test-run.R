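test_that("a collection run reconciles its report with the output file", {
    tmp <- tempfile(fileext = ".csv"); out <- tempfile(fileext = ".csv")
    makeCollectionFile(tmp, nMolecules = 6, isotopes = c("13C", "15N"),
                       seed = 21, duplicates = 1, overflowCounts = 1)
    cfg <- syntheticConfig(tmp, out, isotopes = c("13C", "15N"),
                           groupColumns = "molecule")
    rep <- correctCollection(cfg)
    r <- read.csv(out, colClasses = "character")
    expect_equal(rep@peaks, nrow(read.csv(tmp)))
    expect_equal(rep@datasets, 6L)
    expect_equal(nrow(r), rep@peaks + rep@predicted)
    expect_equal(sum(grepl("duplicate_isotopologue", r$correction_note)),
                 unname(rep@flagged["duplicate_isotopologue"]))
    expect_equal(sum(grepl("count_exceeds_formula", r$correction_note)),
                 unname(rep@flagged["count_exceeds_formula"]))
    expect_length(rep@iterations, 6L)
    # flagged rows carry no corrected value, clean rows always do
    flaggedRows <- r$correction_note != ""
    expect_true(all(r$corrected_intensity[flaggedRows] == ""))
    expect_true(all(r$corrected_intensity[!flaggedRows] != ""))
})

test_that("caching is transparent: identical output bytes with and without", {
    tmp <- tempfile(fileext = ".csv")
    makeCollectionFile(tmp, nMolecules = 10, isotopes = c("13C", "15N"),
                       seed = 33)
    outA <- tempfile(fileext = ".csv"); outB <- tempfile(fileext = ".csv")
    correctCollection(syntheticConfig(tmp, outA, isotopes = c("13C", "15N"),
                                      cache = TRUE))
    correctCollection(syntheticConfig(tmp, outB, isotopes = c("13C", "15N"),
                                      cache = FALSE))
    expect_identical(readLines(outA), readLines(outB))
})

test_that("dataset results are independent of processing order", {
    # corrections are per-dataset, so correcting each molecule alone must
    # reproduce the collection run, whatever order datasets are handled in
    tmp <- tempfile(fileext = ".csv"); out <- tempfile(fileext = ".csv")
    makeCollectionFile(tmp, nMolecules = 4, isotopes = "13C", seed = 55)
    full <- syntheticConfig(tmp, out, groupColumns = "molecule")
    correctCollection(full)
    whole <- read.csv(out, colClasses = "character")
    raw <- read.csv(tmp, colClasses = "character", check.names = FALSE)
    for (m in rev(unique(raw$molecule))) {
        sub <- tempfile(fileext = ".csv"); subOut <- tempfile(fileext = ".csv")
        write.csv(raw[raw$molecule == m, ], sub, row.names = FALSE,
                  quote = FALSE)
        correctCollection(syntheticConfig(sub, subOut,
                                          groupColumns = "molecule"))
        got <- read.csv(subOut, colClasses = "character")
        expect_equal(got$corrected_intensity,
                     whole$corrected_intensity[whole$molecule == m])
    }
})

test_that("an empty collection yields an empty output and a zero report", {
    tmp <- tempfile(fileext = ".csv"); out <- tempfile(fileext = ".csv")
    writeLines("formula,c13,intensity", tmp)
    rep <- correctCollection(collectionConfig(tmp, out, c("13C" = "c13")))
    expect_equal(rep@peaks, 0L)
    expect_equal(rep@datasets, 0L)
    r <- read.csv(out, colClasses = "character")
    expect_equal(nrow(r), 0L)
    expect_true(all(c("corrected_intensity", "correction_note") %in% names(r)))
})

test_that("the command-line wrapper runs end to end", {
    script <- file.path(system.file(package = "NAcorrectR"), "exec",
                        "nacorrect")
    expect_true(file.exists(script))
    tmp <- tempfile(fileext = ".csv"); out <- tempfile(fileext = ".csv")
    cfgFile <- tempfile(fileext = ".yml")
    status <- system2("Rscript",
                      c(script, "synthesize", "--out", tmp,
                        "--molecules", "3", "--seed", "4"),
                      stdout = TRUE, stderr = TRUE)
    expect_true(file.exists(tmp))
    writeLines(c(sprintf("input: %s", tmp), sprintf("output: %s", out),
                 "count_columns:", "  13C: 13C_count"), cfgFile)
    res <- suppressWarnings(
        system2("Rscript", c(script, "correct", "--config", cfgFile),
                stdout = TRUE, stderr = TRUE))
    expect_null(attr(res, "status"))
    expect_true(file.exists(out))
    expect_true(any(grepl("datasets: 3", res)))
    # bad config exits nonzero
    bad <- suppressWarnings(
        system2("Rscript", c(script, "correct", "--config", "missing.yml"),
                stdout = TRUE, stderr = TRUE))
    expect_equal(attr(bad, "status"), 1L)
})
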