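## Step 3: the 14 statistical/descriptive window parameters per IF signal,
## the 112-feature catalog, and sliding-window feature extraction.

PARAMETER_NAMES <- c("mean", "std", "trimmed_mean_25", "median", "skewness",
                     "kurtosis", "max", "min", "p25", "p75",
                     "geometric_mean", "harmonic_mean", "mean_abs_dev",
                     "baseline")

## printed per-parameter operation counts (operations per second)
PARAMETER_COSTS <- c(
    mean = 300, std = 1201, trimmed_mean_25 = 27805, median = 27580,
    skewness = 2101, kurtosis = 2710, max = 300, min = 300,
    p25 = 27580, p75 = 27580, geometric_mean = 3901, harmonic_mean = 3301,
    mean_abs_dev = 1200, baseline = 550
)
SORT_BASED <- c("trimmed_mean_25", "median", "p25", "p75")

#' The 112-feature catalog
#'
#' Enumerates every (measurement, signal, parameter) triple: 2 measurements
#' (ECG, TEB) x 4 derived signals each x 14 window parameters = 112
#' features, 56 per measurement. Feature names follow the
#' `measurement.signal.parameter` convention (e.g. `ECG.ECF.mean`,
#' `TEB.ZRD.kurtosis`). `paramCost` is the per-parameter operations-per-
#' second count; `sortBased` marks rank statistics that share one sort per
#' signal (see [totalNop()]).
#'
#' @return A `data.frame` with columns `name`, `measurement`, `signal`,
#'   `parameter`, `paramCost`, `sortBased`.
#' @examples
#' nrow(featureCatalog())                    # 112
#' sum(featureCatalog()$measurement == "ECG")  # 56
#' @export
featureCatalog <- function() {
    sig <- data.frame(
        measurement = rep(c("ECG", "TEB"), each = 4L),
        signal = IF_SIGNAL_NAMES,
        stringsAsFactors = FALSE
    )
    cat <- merge(sig, data.frame(parameter = PARAMETER_NAMES,
                                 stringsAsFactors = FALSE))
    cat <- cat[order(match(cat$signal, IF_SIGNAL_NAMES),
                     match(cat$parameter, PARAMETER_NAMES)), ]
    cat$name <- paste(cat$measurement, cat$signal, cat$parameter, sep = ".")
    cat$paramCost <- unname(PARAMETER_COSTS[cat$parameter])
    cat$sortBased <- cat$parameter %in% SORT_BASED
    rownames(cat) <- NULL
    cat[, c("name", "measurement", "signal", "parameter", "paramCost",
            "sortBased")]
}

#' Compute one window parameter
#'
#' Standard definitions: `std` is the sample standard deviation; skewness
#' and kurtosis use population moments (`m3/m2^1.5`, `m4/m2^2`; kurtosis is
#' non-excess, 3 for a normal); `trimmed_mean_25` discards 12.5\% of the
#' sorted samples at each extreme (25\% total); percentiles use linear
#' interpolation between order statistics (type 7). Geometric and harmonic
#' means require strictly positive samples and return `NA` otherwise (the
#' window is then unusable for those features). `baseline` is not a window
#' statistic -- see [baselineTracker()].
#'
#' @param x numeric window samples (at least 2, finite).
#' @param parameter one of the 13 window statistics in
#'   `featureCatalog()$parameter` (all but `baseline`).
#' @param trim total trimmed fraction for `trimmed_mean_25`.
#' @return A single numeric value (possibly `NA`).
#' @examples
#' computeParameter(rep(5, 100), "std")       # 0
#' computeParameter(1:100, "p25")
#' @export
computeParameter <- function(x, parameter, trim = 0.25) {
    stopifnot2(length(x) >= 2L && all(is.finite(x)),
               "window must hold at least 2 finite samples")
    parameter <- match.arg(parameter, setdiff(PARAMETER_NAMES, "baseline"))
    windowParameters(x, trim = trim)[[parameter]]
}

## all 13 window statistics with a single shared sort
windowParameters <- function(x, trim = 0.25) {
    n <- length(x)
    s <- sort(x)
    mu <- mean(x)
    dev <- x - mu
    m2 <- mean(dev^2)
    k <- floor(n * trim / 2)
    trimmed <- mean(s[(k + 1L):(n - k)])
    ## order statistics with linear interpolation (quantile type 7), read
    ## directly off the single shared sort
    pctl <- function(p) {
        h <- (n - 1) * p
        lo <- floor(h)
        v <- s[lo + 1L]
        v + (h - lo) * (s[min(lo + 2L, n)] - v)
    }
    qs <- c(pctl(0.25), pctl(0.5), pctl(0.75))
    pos <- s[1L] > 0
    c(mean = mu,
      std = sd(x),
      trimmed_mean_25 = trimmed,
      median = qs[2L],
      skewness = if (m2 > 0) mean(dev^3) / m2^1.5 else 0,
      kurtosis = if (m2 > 0) mean(dev^4) / m2^2 else 0,
      max = s[n],
      min = s[1L],
      p25 = qs[1L],
      p75 = qs[3L],
      geometric_mean = if (pos) exp(mean(log(x))) else NA_real_,
      harmonic_mean = if (pos) 1 / mean(1 / x) else NA_real_,
      mean_abs_dev = mean(abs(dev)))
}

#' Long-term baseline via a first-order low-pass IIR filter
#'
#' Tracks the long-term mean of a signal with the one-pole recursion
#' `b[n] = (1 - alpha) * b[n-1] + alpha * x[n]`, initialized at `b[1] =
#' x[1]`. The default `alpha` corresponds to a 300 s time constant at the
#' 50 Hz intermediate rate, matching the several-minute resting intervals
#' between task stages that the baseline is meant to average over.
#'
#' @param x numeric signal.
#' @param alpha smoothing coefficient in (0, 1].
#' @return Numeric vector of baseline values, same length as `x`.
#' @examples
#' baselineTracker(rep(3, 10), 0.1)  # all 3
#' @export
baselineTracker <- function(x, alpha = 1 / (300 * 50)) {
    stopifnot2(alpha > 0 && alpha <= 1, "'alpha' must lie in (0, 1]")
    if (alpha == 1) return(x)
    as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive",
                             init = x[1L]))
}

## label of each IF sample from the interval table (NA outside intervals)
labelAtSamples <- function(labels, n, ifRate) {
    t <- (seq_len(n) - 1L) / ifRate
    out <- rep(NA_character_, n)
    for (j in seq_len(nrow(labels))) {
        sel <- t >= labels$start[j] & t < labels$end[j]
        out[sel] <- labels$label[j]
    }
    out
}

#' Sliding-window feature extraction
#'
#' Computes the selected features over 60 s windows advancing by 10 s across
#' the warm-up-free span of an [IFSignalSet-class]. For a valid span of `T`
#' seconds this yields `floor((T - window)/stride) + 1` windows. Each window
#' is labelled by the majority class of its samples; windows whose majority
#' share falls below `majorityMin` (class-boundary stragglers) are dropped.
#' Rank-based statistics share one sort per (signal, window). The baseline
#' feature is the baseline tracker's value at the window's last sample.
#'
#' @param ifs an [IFSignalSet-class].
#' @param selection character vector of feature names (default: the full
#'   112-feature catalog).
#' @param window,stride window length and advance, seconds.
#' @param majorityMin minimum majority-label share to keep a window.
#' @param baselineAlpha smoothing coefficient of [baselineTracker()].
#' @param trim total trimmed fraction of the trimmed mean.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `features` (features x windows), `rowData` = the catalog rows, and
#'   `colData` columns `subject`, `label`, `tStart`, `tEnd`. Zero columns
#'   (with a warning) if no complete window fits.
#' @export
extractFeatures <- function(ifs, selection = NULL, window = 60, stride = 10,
                            majorityMin = 0.9,
                            baselineAlpha = 1 / (300 * 50), trim = 0.25) {
    stopifnot(is(ifs, "IFSignalSet"))
    cat <- featureCatalog()
    if (is.null(selection)) selection <- cat$name
    unknown <- setdiff(selection, cat$name)
    stopifnot2(length(unknown) == 0L,
               paste("unknown feature(s):", paste(unknown, collapse = ", ")))
    cat <- cat[match(selection, cat$name), , drop = FALSE]

    fsIf <- ifs@ifRate
    sig <- ifs@signals
    n <- nrow(sig)
    i0 <- as.integer(floor(ifs@validStart * fsIf)) + 1L
    i1 <- min(n, as.integer(floor(ifs@validEnd * fsIf)))
    wN <- as.integer(round(window * fsIf))
    sN <- as.integer(round(stride * fsIf))
    starts <- seq.int(i0, by = sN,
                      length.out = max(0L, (i1 - i0 + 1L - wN) %/% sN + 1L))
    emptySE <- function() {
        warning("no complete feature window in the valid span")
        SummarizedExperiment::SummarizedExperiment(
            assays = list(features = matrix(numeric(0), nrow = nrow(cat),
                                            dimnames = list(cat$name, NULL))),
            rowData = S4Vectors::DataFrame(cat))
    }
    if (length(starts) == 0L) return(emptySE())

    labels <- labelAtSamples(ifs@labels, n, fsIf)
    sigNeeded <- unique(cat$signal)
    baselines <- lapply(setNames(sigNeeded, sigNeeded), function(s) {
        v <- sig[, s]
        if (anyNA(v)) rep(NA_real_, n) else baselineTracker(v, baselineAlpha)
    })

    vals <- matrix(NA_real_, nrow = nrow(cat), ncol = length(starts),
                   dimnames = list(cat$name, NULL))
    winLabel <- character(length(starts))
    keep <- logical(length(starts))
    for (w in seq_along(starts)) {
        idx <- starts[w]:(starts[w] + wN - 1L)
        lab <- labels[idx]
        tab <- table(lab, useNA = "no")
        if (length(tab) == 0L) next
        best <- which.max(tab)
        if (tab[best] / length(idx) < majorityMin) next
        winLabel[w] <- names(tab)[best]
        keep[w] <- TRUE
        for (s in sigNeeded) {
            v <- sig[idx, s]
            rows <- which(cat$signal == s)
            if (anyNA(v)) next
            pars <- windowParameters(v, trim = trim)
            pars <- c(pars, baseline = baselines[[s]][idx[wN]])
            vals[rows, w] <- pars[cat$parameter[rows]]
        }
    }
    if (!any(keep)) return(emptySE())
    tStart <- (starts[keep] - 1L) / fsIf
    SummarizedExperiment::SummarizedExperiment(
        assays = list(features = vals[, keep, drop = FALSE]),
        rowData = S4Vectors::DataFrame(cat),
        colData = S4Vectors::DataFrame(
            subject = rep(ifs@subjectId, sum(keep)),
            label = winLabel[keep],
            tStart = tStart,
            tEnd = tStart + window)
    )
}

#' Extract and pool features across a cohort
#'
#' Convenience wrapper: assembles the IF signals of every recording and
#' column-binds the per-subject feature windows into one
#' SummarizedExperiment.
#'
#' @param cohort list of [RawRecording-class] (see [generateCohort()]).
#' @param ... passed to [extractFeatures()].
#' @return A SummarizedExperiment of pooled feature windows.
#' @export
cohortFeatures <- function(cohort, ...) {
    ses <- lapply(cohort, function(rec) {
        extractFeatures(assembleIFSignals(rec), ...)
    })
    ses <- ses[vapply(ses, ncol, integer(1)) > 0L]
    stopifnot2(length(ses) > 0L, "no recording yielded feature windows")
    do.call(BiocGenerics::cbind, unname(ses))
}

#' Write a feature matrix as delimited text
#'
#' Transposed layout: one row per window with `subject`, `label`, `tStart`,
#' `tEnd` columns followed by one column per feature (named as in the
#' catalog).
#'
#' @param se feature SummarizedExperiment from [extractFeatures()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeFeatures <- function(se, path) {
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    m <- t(SummarizedExperiment::assay(se, "features"))
    utils::write.table(cbind(cd, as.data.frame(m, check.names = FALSE)),
                       path, sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(path)
}
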