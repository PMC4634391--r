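#' @import methods
NULL

## ---------------------------------------------------------------------------
## FilterSpec
## ---------------------------------------------------------------------------

#' Specification of a linear-phase FIR or interpolated-FIR (IFIR) stage
#'
#' A `FilterSpec` describes one filtering stage of the ECG or TEB feature
#' extraction chain: a plain linear-phase FIR low-pass, or a narrow-band IFIR
#' low-pass/band-pass realized as a prototype whose coefficients are spaced
#' `stretch` samples apart and whose spectral images are suppressed by the
#' preceding anti-aliasing low-pass.
#'
#' The operations-per-second cost of a stage follows directly from the spec:
#' `order * fs` for a plain FIR and `order * fs / stretch` for an IFIR stage
#' (see [stageCost()]).
#'
#' @slot kind character; one of `"fir_lowpass"`, `"ifir_lowpass"`,
#'   `"ifir_bandpass"`.
#' @slot order integer; number of filter taps minus one (`N1` or `N2`).
#' @slot cutoffs numeric; cutoff frequency or band edges in Hz.
#' @slot fs numeric; sampling rate of the signal the stage runs on, Hz.
#' @slot stretch numeric; stretch factor `SF` (1 for a plain FIR).
#'
#' @seealso [filterSpec()], [designFilter()], [stageCost()]
#' @export
setClass("FilterSpec",
    representation(
        kind = "character",
        order = "integer",
        cutoffs = "numeric",
        fs = "numeric",
        stretch = "numeric"
    )
)

setValidity("FilterSpec", function(object) {
    msg <- character()
    kinds <- c("fir_lowpass", "ifir_lowpass", "ifir_bandpass")
    if (length(object@kind) != 1L || !object@kind %in% kinds) {
        msg <- c(msg, sprintf(
            "'kind' must be one of %s",
            paste(sQuote(kinds), collapse = ", ")
        ))
    }
    if (length(object@order) != 1L || is.na(object@order) || object@order <= 0L) {
        msg <- c(msg, "'order' must be a positive integer")
    }
    if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0) {
        msg <- c(msg, "'fs' must be a positive sampling rate in Hz")
    }
    if (length(object@stretch) != 1L || object@stretch < 1) {
        msg <- c(msg, "'stretch' must be >= 1")
    }
    nband <- if (identical(object@kind, "ifir_bandpass")) 2L else 1L
    if (length(object@cutoffs) != nband) {
        msg <- c(msg, sprintf("'cutoffs' must have length %d for kind '%s'",
                              nband, object@kind))
    } else if (any(object@cutoffs <= 0) || any(object@cutoffs >= object@fs / 2)) {
        msg <- c(msg, "'cutoffs' must lie strictly inside (0, fs/2)")
    } else if (nband == 2L && diff(object@cutoffs) <= 0) {
        msg <- c(msg, "band edges must be increasing")
    }
    ## an IFIR prototype runs on the stretch-decimated grid: the passband must
    ## fit under the prototype Nyquist fs/(2*stretch)
    if (length(msg) == 0L && object@stretch > 1 &&
        any(object@cutoffs >= object@fs / (2 * object@stretch))) {
        msg <- c(msg, "IFIR cutoffs must lie below fs / (2 * stretch)")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a FilterSpec
#'
#' @param kind stage kind: `"fir_lowpass"`, `"ifir_lowpass"` or
#'   `"ifir_bandpass"`.
#' @param order filter order (taps minus one).
#' @param cutoffs cutoff frequency (Hz), or two band edges for a band-pass.
#' @param fs sampling rate of the stage input, Hz.
#' @param stretch IFIR stretch factor `SF`; 1 for a plain FIR.
#' @return A [FilterSpec-class] object.
#' @examples
#' filterSpec("fir_lowpass", order = 100, cutoffs = 0.5, fs = 250)
#' filterSpec("ifir_lowpass", order = 1150, cutoffs = 0.1, fs = 250, stretch = 25)
#' @export
filterSpec <- function(kind, order, cutoffs, fs, stretch = 1) {
    new("FilterSpec",
        kind = as.character(kind), order = as.integer(order),
        cutoffs = as.numeric(cutoffs), fs = as.numeric(fs),
        stretch = as.numeric(stretch))
}

setMethod("show", "FilterSpec", function(object) {
    cat(sprintf("FilterSpec: %s, order %d, cutoffs %s Hz, fs %g Hz, SF %g\n",
                object@kind, object@order,
                paste(object@cutoffs, collapse = "-"),
                object@fs, object@stretch))
})

## ---------------------------------------------------------------------------
## FilteredSignals
## ---------------------------------------------------------------------------

#' Output of one measurement chain's filtering step
#'
#' Holds the three band-limited signals produced by an ECG or TEB filterbank,
#' time-aligned to the raw input (each branch is shifted left by its total
#' group delay). `fe1` is the slow "continuous" component (below 0.1 Hz),
#' `fe2` the respiration band (0.1--0.5 Hz) and `fe3` the pulse-bearing
#' branch (wideband for ECG, narrow pulse band for TEB). The first and last
#' `warmup` samples of each branch are contaminated by filter transients and
#' should not feed feature windows.
#'
#' @slot fe1,fe2,fe3 numeric vectors, same length as the chain input.
#' @slot fs numeric; native sampling rate, Hz.
#' @slot warmup integer; number of edge samples to treat as invalid.
#' @export
setClass("FilteredSignals",
    representation(
        fe1 = "numeric", fe2 = "numeric", fe3 = "numeric",
        fs = "numeric", warmup = "integer"
    )
)

setValidity("FilteredSignals", function(object) {
    n <- length(object@fe1)
    if (length(object@fe2) != n || length(object@fe3) != n) {
        return("fe1, fe2 and fe3 must have equal length")
    }
    if (object@warmup < 0L) return("'warmup' must be non-negative")
    TRUE
})

setMethod("show", "FilteredSignals", function(object) {
    cat(sprintf(
        "FilteredSignals: %d samples @ %g Hz (%.1f s), warmup %d samples/side\n",
        length(object@fe1), object@fs, length(object@fe1) / object@fs,
        object@warmup))
})

## ---------------------------------------------------------------------------
## RawRecording
## ---------------------------------------------------------------------------

#' A labelled two-channel subject recording
#'
#' Container for one subject's raw ECG (250 Hz) and thoracic bioimpedance
#' (100 Hz) streams together with per-interval class labels and -- for
#' synthetic recordings -- the generator's ground-truth rate traces.
#'
#' @slot ecg numeric; ECG samples.
#' @slot teb numeric; TEB samples.
#' @slot fsEcg,fsTeb numeric; channel sampling rates, Hz.
#' @slot subjectId character scalar.
#' @slot labels data.frame with columns `start`, `end` (seconds) and `label`.
#' @slot truth list; for synthetic data, piecewise-constant ground truth with
#'   elements `time`, `hr`, `rr` (and the per-subject condition table).
#' @seealso [generateRecording()], [generateCohort()]
#' @export
setClass("RawRecording",
    representation(
        ecg = "numeric", teb = "numeric",
        fsEcg = "numeric", fsTeb = "numeric",
        subjectId = "character",
        labels = "data.frame",
        truth = "list"
    )
)

setValidity("RawRecording", function(object) {
    msg <- character()
    dEcg <- length(object@ecg) / object@fsEcg
    dTeb <- length(object@teb) / object@fsTeb
    if (abs(dEcg - dTeb) > 1 / min(object@fsEcg, object@fsTeb) + 1e-9) {
        msg <- c(msg, "ECG and TEB durations differ by more than one sample period")
    }
    lb <- object@labels
    if (nrow(lb)) {
        if (!all(c("start", "end", "label") %in% names(lb))) {
            msg <- c(msg, "labels must have columns start, end, label")
        } else {
            if (any(lb$end <= lb$start)) msg <- c(msg, "label intervals must have end > start")
            o <- order(lb$start)
            if (any(lb$start[o][-1] < lb$end[o][-nrow(lb)] - 1e-9)) {
                msg <- c(msg, "label intervals must not overlap")
            }
            if (max(lb$end) > dEcg + 1e-6) {
                msg <- c(msg, "label intervals must lie within the recording")
            }
        }
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "RawRecording", function(object) {
    cat(sprintf(
        "RawRecording '%s': %.1f s (ECG %d @ %g Hz, TEB %d @ %g Hz), %d label interval(s)\n",
        object@subjectId, length(object@ecg) / object@fsEcg,
        length(object@ecg), object@fsEcg,
        length(object@teb), object@fsTeb, nrow(object@labels)))
    if (nrow(object@labels)) {
        cat("  classes:", paste(unique(object@labels$label), collapse = ", "), "\n")
    }
})

#' @describeIn RawRecording-class recording duration in seconds.
#' @param x a `RawRecording`.
#' @export
recordingDuration <- function(x) length(x@ecg) / x@fsEcg

#' @describeIn RawRecording-class subject identifier.
#' @export
subjectId <- function(x) x@subjectId

#' @describeIn RawRecording-class label interval table.
#' @export
labelIntervals <- function(x) x@labels

#' @describeIn RawRecording-class generator ground truth (synthetic data).
#' @export
groundTruth <- function(x) x@truth

## ---------------------------------------------------------------------------
## IFSignalSet
## ---------------------------------------------------------------------------

#' The eight intermediate-frequency physiological signals
#'
#' All eight derived signals of a recording, on a common 50 Hz grid:
#' `ECF`/`ZCF` (slow component of ECG/TEB), `ERT`/`ZRT` (respiration rate,
#' breaths/min), `ERD`/`ZRD` (respiration depth, amplitude units) and
#' `EPPM`/`ZPPM` (pulse rate, beats/min). Samples outside
#' `[validStart, validEnd]` seconds are affected by filter warm-up and are
#' excluded from feature windows. A detector that found no cycles leaves its
#' column as `NA` (the recording is then unusable for features that need it).
#'
#' @slot signals numeric matrix, one column per signal (named).
#' @slot ifRate numeric; the common intermediate rate, Hz.
#' @slot validStart,validEnd numeric; valid span in seconds.
#' @slot subjectId character scalar.
#' @slot labels data.frame of label intervals (seconds).
#' @seealso [assembleIFSignals()], [extractFeatures()]
#' @export
setClass("IFSignalSet",
    representation(
        signals = "matrix",
        ifRate = "numeric",
        validStart = "numeric",
        validEnd = "numeric",
        subjectId = "character",
        labels = "data.frame"
    )
)

IF_SIGNAL_NAMES <- c("ECF", "ERT", "ERD", "EPPM", "ZCF", "ZRT", "ZRD", "ZPPM")

setValidity("IFSignalSet", function(object) {
    msg <- character()
    if (!identical(colnames(object@signals), IF_SIGNAL_NAMES)) {
        msg <- c(msg, sprintf("signal columns must be %s",
                              paste(IF_SIGNAL_NAMES, collapse = ", ")))
    }
    if (object@validEnd < object@validStart) {
        msg <- c(msg, "validEnd must be >= validStart")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "IFSignalSet", function(object) {
    cat(sprintf(
        "IFSignalSet '%s': %d samples @ %g Hz, valid %.1f-%.1f s\n",
        object@subjectId, nrow(object@signals), object@ifRate,
        object@validStart, object@validEnd))
    ok <- colSums(is.na(object@signals)) == 0
    if (!all(ok)) cat("  undetected (NA):", paste(names(ok)[!ok], collapse = ", "), "\n")
})

#' @describeIn IFSignalSet-class the n x 8 signal matrix.
#' @param x an `IFSignalSet`.
#' @export
ifSignals <- function(x) x@signals

#' @describeIn IFSignalSet-class the common intermediate rate in Hz.
#' @export
ifRate <- function(x) x@ifRate

#' @describeIn IFSignalSet-class valid span (seconds) unaffected by warm-up.
#' @export
validRange <- function(x) c(start = x@validStart, end = x@validEnd)

## ---------------------------------------------------------------------------
## CVResult
## ---------------------------------------------------------------------------

#' Result of a leave-one-subject-out evaluation
#'
#' @slot confusion integer matrix of counts, rows = true class.
#' @slot perClassError numeric; per-class error probability, percent.
#' @slot averageError numeric; unweighted mean of the per-class errors, percent.
#' @slot folds list; one entry per fold with the held-out subject, selected
#'   feature names, their operations-per-second cost and the fold error.
#' @slot analysis character; free-form description of the task.
#' @seealso [runAnalysis()], [errorMetrics()]
#' @export
setClass("CVResult",
    representation(
        confusion = "matrix",
        perClassError = "numeric",
        averageError = "numeric",
        folds = "list",
        analysis = "character"
    )
)

setValidity("CVResult", function(object) {
    cm <- object@confusion
    if (nrow(cm) != ncol(cm)) return("confusion matrix must be square")
    if (any(cm < 0)) return("confusion counts must be non-negative")
    TRUE
})

setMethod("show", "CVResult", function(object) {
    cat(sprintf("CVResult (%s): %d classes, %d fold(s)\n",
                object@analysis, nrow(object@confusion), length(object@folds)))
    print(object@confusion)
    err <- sprintf("%.2f%%", object@perClassError)
    cat("  per-class error:", paste(err, collapse = ", "), "\n")
    cat(sprintf("  average error: %.2f%%\n", object@averageError))
})

#' @describeIn CVResult-class pooled confusion matrix (rows = true class).
#' @param x a `CVResult`.
#' @export
confusionMatrix <- function(x) x@confusion

#' @describeIn CVResult-class unweighted average error probability in percent.
#' @export
averageError <- function(x) x@averageError

#' @describeIn CVResult-class per-class error probabilities in percent.
#' @export
perClassError <- function(x) x@perClassError
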