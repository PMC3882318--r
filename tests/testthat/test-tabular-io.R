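writeUdpFixture <- function(path) {
    obs <- udpObserved()
    counts <- which(obs > 0) - 1L
    writeLines(c("id,formula,c13,intensity,note_col",
                 sprintf("p%02d,C17H27N3O17P2,%d,%s,meta %d",
                         seq_along(counts), counts,
                         format(obs[counts + 1], trim = TRUE),
                         seq_along(counts))),
               path)
    path
}

test_that("collections are read, grouped and densified per molecule", {
    tmp <- tempfile(fileext = ".csv")
    writeLines(c("formula,c13,intensity,sample",
                 "C6H12O6,0,100,a", "C6H12O6,1,50,a", "C6H12O6,2,20,a",
                 "C3H8O3,0,10,a", "C3H8O3,1,5,a", "C3H8O3,2,2,a"), tmp)
    cfg <- collectionConfig(tmp, tempfile(), c("13C" = "c13"))
    coll <- readCollection(cfg)
    expect_s4_class(coll, "PeakCollection")
    expect_length(coll@datasets, 2L)
    expect_equal(vapply(coll@datasets, function(d) length(d$rows), integer(1)),
                 c(3L, 3L))
    expect_equal(coll@datasets[[1]]$formulaText, "C6H12O6")
    # grouping columns split a formula into independent datasets
    cfgG <- collectionConfig(tmp, tempfile(), c("13C" = "c13"),
                             groupColumns = "sample")
    expect_length(readCollection(cfgG)@datasets, 2L)
})

test_that("rows observed only at high counts densify over the full 0..N range", {
    tmp <- tempfile(fileext = ".csv")
    writeUdpFixture(tmp)
    out <- tempfile(fileext = ".csv")
    cfg <- collectionConfig(tmp, out, c("13C" = "c13"))
    coll <- readCollection(cfg)
    expect_length(coll@datasets, 1L)
    expect_equal(nrow(coll@datasets[[1]]$counts), 12L)
    # the correction sees a dense length-18 vector: results match the
    # published corrected intensities
    correctCollection(cfg)
    got <- as.numeric(read.csv(out)$corrected_intensity)
    expect_lt(max(abs(got - udpCorrectedReference())), 0.02)
})

test_that("unparseable rows are annotated malformed and excluded", {
    tmp <- tempfile(fileext = ".csv"); out <- tempfile(fileext = ".csv")
    writeLines(c("formula,c13,intensity",
                 "C6H12O6,0,1000", "C6H12O6,1,abc", "C6H12O6,x,10",
                 "C6H12O6,2,-5", "NotAFormula!,0,3"), tmp)
    cfg <- collectionConfig(tmp, out, c("13C" = "c13"))
    rep <- correctCollection(cfg)
    r <- read.csv(out, colClasses = "character")
    expect_equal(nrow(r), 5L)
    expect_equal(r$correction_note,
                 c("", "malformed_row", "malformed_row", "malformed_row",
                   "malformed_row"))
    expect_equal(r$intensity, c("1000", "abc", "10", "-5", "3"))
    expect_equal(unname(rep@flagged["malformed_row"]), 4L)
})

test_that("missing files and columns are fatal configuration errors", {
    expect_error(readCollection(collectionConfig("does-not-exist.csv",
                                                 tempfile(),
                                                 c("13C" = "c13"))),
                 "not found")
    tmp <- tempfile(fileext = ".csv")
    writeLines(c("formula,c13,intensity", "C2H4,0,1"), tmp)
    cfg <- collectionConfig(tmp, tempfile(), c("13C" = "wrong_col"))
    expect_error(readCollection(cfg), "wrong_col")
})

test_that("pass-through columns survive a read/correct/write round trip", {
    tmp <- tempfile(fileext = ".csv"); out <- tempfile(fileext = ".csv")
    writeUdpFixture(tmp)
    cfg <- collectionConfig(tmp, out, c("13C" = "c13"))
    correctCollection(cfg)
    orig <- read.csv(tmp, colClasses = "character")
    got <- read.csv(out, colClasses = "character")
    expect_equal(got[names(orig)], orig)
    expect_equal(names(got),
                 c(names(orig), "corrected_intensity", "correction_note"))
})

test_that("zero-abundance correction reproduces the input intensities", {
    tmp <- tempfile(fileext = ".csv"); out <- tempfile(fileext = ".csv")
    writeUdpFixture(tmp)
    cfg <- collectionConfig(tmp, out, c("13C" = "c13"),
                            abundances = c("13C" = 0))
    correctCollection(cfg)
    r <- read.csv(out)
    expect_equal(as.numeric(r$corrected_intensity), as.numeric(r$intensity))
})

test_that("predicted peaks append rows; disabled threshold keeps row count", {
    tmp <- tempfile(fileext = ".csv"); out <- tempfile(fileext = ".csv")
    # strong peak at count 0 predicts NA satellites at counts 1..2 that are
    # "missing" from the input
    writeLines(c("formula,c13,intensity",
                 "C20H30O5,0,100000", "C20H30O5,5,200"), tmp)
    cfg <- collectionConfig(tmp, out, c("13C" = "c13"),
                            threshold = thresholdSpec(1, "maximum", "dataset"))
    rep <- correctCollection(cfg)
    r <- read.csv(out, colClasses = "character")
    expect_gt(nrow(r), 2L)
    added <- r[-(1:2), ]
    expect_true(all(added$correction_note == "predicted_not_observed"))
    expect_true(all(added$formula == "C20H30O5"))
    expect_equal(rep@predicted, nrow(r) - 2L)
    # same input, threshold disabled: row counts match
    cfg0 <- collectionConfig(tmp, tempfile(fileext = ".csv"),
                             c("13C" = "c13"))
    rep0 <- correctCollection(cfg0)
    expect_equal(rep0@predicted, 0L)
    expect_equal(nrow(read.csv(cfg0@output)), 2L)
})

test_that("YAML configurations map onto CollectionConfig", {
    tmp <- tempfile(fileext = ".yml")
    writeLines(c("input: in.csv", "output: out.csv",
                 "formula_column: mf", "intensity_column: area",
                 "count_columns:", "  13C: c13", "  15N: n15",
                 "group_columns: [sample, time]",
                 "abundances:", "  13C: 0.011",
                 "threshold:", "  percent: 5", "  statistic: average",
                 "  scope: dataset",
                 "cache: false"), tmp)
    cfg <- readCollectionConfig(tmp)
    expect_equal(cfg@input, "in.csv")
    expect_equal(cfg@formulaColumn, "mf")
    expect_equal(unname(cfg@countColumns), c("c13", "n15"))
    expect_equal(names(cfg@countColumns), c("13C", "15N"))
    expect_equal(cfg@groupColumns, c("sample", "time"))
    expect_equal(cfg@isotopes[[1]]@abundance, 0.011)
    expect_equal(cfg@isotopes[[2]]@abundance, 0.0037)
    expect_true(cfg@threshold@enabled)
    expect_equal(cfg@threshold@percent, 5)
    expect_false(cfg@cache)
    # a missing required key names itself
    bad <- tempfile(fileext = ".yml")
    writeLines("input: in.csv", bad)
    expect_error(readCollectionConfig(bad), "output")
})
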