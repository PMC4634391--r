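test_that("the catalog enumerates 4 signals x 14 parameters per measurement", {
    cat <- featureCatalog()
    expect_identical(nrow(cat), 112L)
    expect_identical(sum(cat$measurement == "ECG"), 56L)
    expect_identical(sum(cat$measurement == "TEB"), 56L)
    expect_identical(anyDuplicated(cat$name), 0L)
    expect_identical(sum(cat$sortBased), 4L * 8L)
})

test_that("constant windows collapse every location statistic to the constant", {
    x <- rep(5, 120)
    for (p in c("mean", "median", "max", "min", "geometric_mean",
                "harmonic_mean", "trimmed_mean_25", "p25", "p75")) {
        expect_equal(computeParameter(x, p), 5)
    }
    expect_equal(computeParameter(x, "std"), 0)
    expect_equal(computeParameter(x, "mean_abs_dev"), 0)
})

test_that("symmetric windows have zero skewness", {
    x <- c(seq(-3, 3, by = 0.01))
    expect_equal(computeParameter(x, "skewness"), 0, tolerance = 1e-9)
})

test_that("window statistics match brute-force oracles on random windows", {
    set.seed(7)
    pars <- setdiff(physiostress:::PARAMETER_NAMES, "baseline")
    for (rep in 1:300) {
        n <- sample(10:500, 1)
        x <- rnorm(n, mean = runif(1, -2, 10), sd = runif(1, 0.1, 5))
        orc <- oracleParams(x)
        got <- vapply(pars, function(p) computeParameter(x, p), numeric(1))
        for (p in pars) {
            if (is.na(orc[[p]])) {
                expect_true(is.na(got[[p]]))
            } else {
                expect_equal(got[[p]], orc[[p]], tolerance = 1e-9,
                             label = paste0(p, " (n=", n, ")"))
            }
        }
        ## rank statistics agree with the full-sort oracle exactly, and the
        ## percentiles also agree with the established library definition
        for (p in c("trimmed_mean_25", "p25", "p75")) {
            expect_identical(got[[p]], orc[[p]])
        }
        expect_equal(got[["p25"]],
                     unname(quantile(x, 0.25, type = 7)), tolerance = 1e-12)
    }
})

test_that("statistics transform correctly under affine maps", {
    set.seed(11)
    x <- rnorm(400, 3, 2)
    a <- 2.5; b <- -7
    y <- a * x + b
    for (p in c("mean", "median", "p25", "p75", "max", "min",
                "trimmed_mean_25")) {
        expect_equal(computeParameter(y, p),
                     a * computeParameter(x, p) + b, tolerance = 1e-9)
    }
    for (p in c("std", "mean_abs_dev")) {
        expect_equal(computeParameter(y, p), a * computeParameter(x, p),
                     tolerance = 1e-9)
    }
    for (p in c("skewness", "kurtosis")) {
        expect_equal(computeParameter(y, p), computeParameter(x, p),
                     tolerance = 1e-9)
    }
})

test_that("geometric and harmonic means are undefined on non-positive windows", {
    x <- c(-1, 1, 2, 3)
    expect_true(is.na(computeParameter(x, "geometric_mean")))
    expect_true(is.na(computeParameter(x, "harmonic_mean")))
})

test_that("the baseline tracker follows its closed forms", {
    expect_equal(baselineTracker(rep(4.2, 50), 0.01), rep(4.2, 50))
    alpha <- 0.03
    n <- 200
    step <- baselineTracker(c(0, rep(1, n)), alpha)
    ## b[0]=0 then unit input: b[k] = 1 - (1-alpha)^k
    expect_equal(step[-1], 1 - (1 - alpha)^(1:n), tolerance = 1e-12)
    x <- rnorm(20)
    expect_equal(baselineTracker(x, 1), x)
    expect_error(baselineTracker(x, 0), "alpha")
    ## independent loop oracle
    set.seed(3)
    x <- rnorm(100)
    b <- numeric(100); b[1] <- x[1]
    for (i in 2:100) b[i] <- (1 - alpha) * b[i - 1] + alpha * x[i]
    expect_equal(baselineTracker(x, alpha), b, tolerance = 1e-12)
})

test_that("window counts follow floor((T - 60)/10) + 1 across a duration scan", {
    for (T in c(60, 75, 100, 137, 280)) {
        ifs <- fakeIFSignals(T)
        se <- extractFeatures(ifs, selection = "ECG.ECF.mean")
        expect_identical(ncol(se), as.integer(floor((T - 60) / 10) + 1),
                         info = paste("T =", T))
    }
    expect_warning(extractFeatures(fakeIFSignals(50)), "no complete")
})

test_that("windows carry subject, label and time metadata", {
    ifs <- fakeIFSignals(120, label = "mental")
    se <- extractFeatures(ifs)
    cd <- SummarizedExperiment::colData(se)
    expect_identical(nrow(se), 112L)
    expect_true(all(cd$label == "mental"))
    expect_true(all(cd$subject == "F1"))
    expect_equal(cd$tEnd - cd$tStart, rep(60, ncol(se)))
    expect_false(anyNA(SummarizedExperiment::assay(se)))
})

test_that("windows straddling class boundaries are dropped by the majority rule", {
    ifs <- fakeIFSignals(130)
    ifs@labels <- data.frame(start = c(0, 65), end = c(65, 130),
                             label = c("a", "b"), stringsAsFactors = FALSE)
    se <- extractFeatures(ifs, selection = "ECG.ECF.mean")
    cd <- SummarizedExperiment::colData(se)
    ## every kept window is >= 90% one class
    for (i in seq_len(ncol(se))) {
        lab <- cd$label[i]
        ovl <- if (lab == "a") min(cd$tEnd[i], 65) - cd$tStart[i] else
            cd$tEnd[i] - max(cd$tStart[i], 65)
        expect_gte(ovl / 60, 0.9)
    }
})

test_that("feature matrices round-trip to delimited text", {
    dir <- withr::local_tempdir()
    se <- extractFeatures(fakeIFSignals(100))
    p <- file.path(dir, "features.tsv")
    writeFeatures(se, p)
    df <- read.delim(p, check.names = FALSE)
    expect_identical(nrow(df), ncol(se))
    expect_true(all(featureCatalog()$name %in% names(df)))
    expect_equal(df[["ECG.ECF.mean"]],
                 unname(SummarizedExperiment::assay(se)["ECG.ECF.mean", ]))
})
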