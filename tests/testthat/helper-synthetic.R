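suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(S4Vectors)
})

## independent brute-force definitions of the 13 window statistics
oracleParams <- function(x, trim = 0.25) {
    n <- length(x)
    s <- sort(x)
    m <- sum(x) / n
    m2 <- sum((x - m)^2) / n
    pctl <- function(p) {
        h <- (n - 1) * p
        lo <- floor(h)
        s[lo + 1] + (h - lo) * (s[min(lo + 2, n)] - s[lo + 1])
    }
    k <- floor(n * trim / 2)
    c(mean = m,
      std = sqrt(sum((x - m)^2) / (n - 1)),
      trimmed_mean_25 = mean(s[(k + 1):(n - k)]),
      median = if (n %% 2) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2,
      skewness = if (m2 > 0) (sum((x - m)^3) / n) / m2^1.5 else 0,
      kurtosis = if (m2 > 0) (sum((x - m)^4) / n) / m2^2 else 0,
      max = s[n], min = s[1],
      p25 = pctl(0.25), p75 = pctl(0.75),
      geometric_mean = if (all(x > 0)) exp(sum(log(x)) / n) else NA_real_,
      harmonic_mean = if (all(x > 0)) n / sum(1 / x) else NA_real_,
      mean_abs_dev = sum(abs(x - m)) / n)
}

## mean of one IF signal over the warm-up-free span
validSignalMean <- function(rec, column) {
    ifs <- assembleIFSignals(rec)
    vr <- validRange(ifs)
    i <- seq(floor(vr[1] * ifRate(ifs)) + 1, floor(vr[2] * ifRate(ifs)))
    mean(ifSignals(ifs)[i, column])
}

## a single-class schedule built on a default condition row
singleClassSchedule <- function(duration, hr = NULL, rr = NULL) {
    cond <- classConditions("activity")[1, ]
    if (!is.null(hr)) cond$hr <- hr
    if (!is.null(rr)) cond$rr <- rr
    cbind(duration = duration, cond)
}

## feature SummarizedExperiment with planted informative features: feature
## `info[k]` equals 1 on class k plus noise, all others pure noise
plantedFeatureSE <- function(seed, nSubjects = 8, perSubject = 40,
                             nClasses = 4, info = c(5, 40, 99),
                             noiseSd = 0.25) {
    set.seed(seed)
    n <- nSubjects * perSubject
    subj <- rep(sprintf("S%02d", seq_len(nSubjects)), each = perSubject)
    y <- rep_len(LETTERS[seq_len(nClasses)], n)
    X <- matrix(rnorm(n * 112), n, 112)
    for (k in seq_along(info)) {
        X[, info[k]] <- (y == LETTERS[k]) + rnorm(n, 0, noiseSd)
    }
    cat <- featureCatalog()
    se <- SummarizedExperiment(
        assays = list(features = t(X)),
        rowData = DataFrame(cat),
        colData = DataFrame(subject = subj, label = y))
    rownames(se) <- cat$name
    list(se = se, informative = cat$name[info])
}

## bare feature SE from an explicit matrix (windows x features)
featureSE <- function(X, label, subject,
                      names = paste0("f", seq_len(ncol(X)))) {
    se <- SummarizedExperiment(
        assays = list(features = t(X)),
        colData = DataFrame(subject = subject, label = label))
    rownames(se) <- names
    se
}

## IFSignalSet with arbitrary content, for window-arithmetic tests
fakeIFSignals <- function(duration, ifRate = 50, label = "a",
                          validStart = 0, seed = 1) {
    set.seed(seed)
    n <- floor(duration * ifRate)
    m <- matrix(abs(rnorm(n * 8)) + 1, n, 8,
                dimnames = list(NULL, c("ECF", "ERT", "ERD", "EPPM",
                                        "ZCF", "ZRT", "ZRD", "ZPPM")))
    new("IFSignalSet", signals = m, ifRate = ifRate,
        validStart = validStart, validEnd = duration - validStart,
        subjectId = "F1",
        labels = data.frame(start = 0, end = duration, label = label,
                            stringsAsFactors = FALSE))
}
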