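## Step 1 of both feature-extraction chains: linear-phase FIR low-pass blocks
## plus narrow-band IFIR stages, and decimation to the 50 Hz intermediate rate.
##
## The IFIR stages are realized as a long prototype whose coefficients are
## spaced `stretch` samples apart on the native grid. The preceding low-pass
## acts as the anti-aliasing / image-suppressing filter: the stretched
## prototype's spectral images sit at multiples of fs/SF (10 Hz for both
## chains) where that low-pass is already deep in its stopband.

#' Design a linear-phase FIR / IFIR stage
#'
#' Windowed-sinc (Hamming) design via [signal::fir1]. For IFIR kinds the
#' prototype is designed at the reduced rate `fs / stretch`, so its band edges
#' are `cutoffs * stretch` relative to the native rate, and its coefficients
#' are applied with spacing `stretch`.
#'
#' @param spec a [FilterSpec-class].
#' @return A list with elements `spec`, `coef` (prototype coefficients),
#'   `stretch`, and `delay` -- the group delay in native samples
#'   (`order * stretch / 2` plus nothing else; the design is exactly
#'   linear-phase).
#' @examples
#' lf <- designFilter(filterSpec("fir_lowpass", 100, 0.5, fs = 250))
#' lf$delay   # 50 samples
#' @export
designFilter <- function(spec) {
    stopifnot(is(spec, "FilterSpec"))
    validObject(spec)
    ## normalized edges on the grid the prototype actually runs on
    nyq <- spec@fs / (2 * spec@stretch)
    w <- spec@cutoffs / nyq
    type <- if (identical(spec@kind, "ifir_bandpass")) "pass" else "low"
    h <- signal::fir1(spec@order, w, type = type)
    list(
        spec = spec,
        coef = as.numeric(h),
        stretch = spec@stretch,
        delay = as.integer(round(spec@order * spec@stretch / 2))
    )
}

## Apply a designed stage to a signal, compensating the group delay so the
## output is time-aligned with the input (same length; edges are transient).
applyFilter <- function(filt, x) {
    n <- length(x)
    g <- filt$coef
    sf <- filt$stretch
    if (sf > 1) {
        kern <- numeric((length(g) - 1L) * sf + 1L)
        kern[seq(1L, length(kern), by = sf)] <- g
    } else {
        kern <- g
    }
    y <- convolve(x, rev(kern), type = "open")
    d <- filt$delay
    y[(d + 1L):(d + n)]
}

#' Magnitude response of a designed stage
#'
#' Evaluates `|H(f)|` of the (possibly stretched) stage directly from its
#' coefficients.
#'
#' @param filt result of [designFilter()].
#' @param f frequencies in Hz.
#' @return numeric vector of magnitudes.
#' @export
filterResponse <- function(filt, f) {
    k <- (seq_along(filt$coef) - 1) * filt$stretch
    fs <- filt$spec@fs
    vapply(f, function(fi) Mod(sum(filt$coef * exp(-2i * pi * fi * k / fs))),
           numeric(1))
}

## Default stage specifications for the two chains.
ecgFilterSpecs <- function(fs = 250) {
    list(
        lf = filterSpec("fir_lowpass", 100L, 0.5, fs),
        mf = filterSpec("fir_lowpass", 100L, 30, fs),
        cf = filterSpec("ifir_lowpass", 1150L, 0.1, fs, stretch = 25),
        rf = filterSpec("ifir_bandpass", 1150L, c(0.1, 0.5), fs, stretch = 25)
    )
}

tebFilterSpecs <- function(fs = 100) {
    list(
        lf = filterSpec("fir_lowpass", 100L, 4, fs),
        cf = filterSpec("ifir_lowpass", 400L, 0.1, fs, stretch = 10),
        rf = filterSpec("ifir_bandpass", 400L, c(0.1, 0.8), fs, stretch = 10),
        pulse = filterSpec("ifir_bandpass", 400L, c(0.8, 3), fs, stretch = 10)
    )
}

runChain <- function(x, fs, specs, pulseOnRaw) {
    minLen <- max(vapply(specs, function(s) s@order * s@stretch, numeric(1)))
    if (length(x) <= minLen) {
        stop(sprintf("input too short: need > %d samples for filter warm-up",
                     as.integer(minLen)))
    }
    filts <- lapply(specs, designFilter)
    lfOut <- applyFilter(filts$lf, x)
    fe1 <- applyFilter(filts$cf, lfOut)
    fe2 <- applyFilter(filts$rf, lfOut)
    fe3 <- if (pulseOnRaw) {
        applyFilter(filts$mf, x)
    } else {
        applyFilter(filts$pulse, lfOut)
    }
    narrowDelay <- max(vapply(filts[names(filts) != "lf"], `[[`, integer(1), "delay"))
    warmup <- filts$lf$delay + narrowDelay
    new("FilteredSignals", fe1 = fe1, fe2 = fe2, fe3 = fe3,
        fs = fs, warmup = as.integer(warmup))
}

#' ECG filterbank (Step 1 of the ECG chain)
#'
#' Splits the raw 250 Hz ECG into three branches: the 0.5 Hz anti-aliasing
#' low-pass (`LF`, order 100) feeds two order-1150, stretch-25 IFIR stages --
#' a 0.1 Hz low-pass (`CF`) yielding `fe1` and a 0.1--0.5 Hz band-pass (`RF`)
#' yielding `fe2` -- while a parallel 30 Hz low-pass (`MF`, order 100) applied
#' to the raw input yields the pulse-bearing `fe3`. All outputs are aligned by
#' group-delay compensation.
#'
#' @param ecg numeric ECG samples.
#' @param fs sampling rate, Hz (default 250).
#' @return A [FilteredSignals-class].
#' @export
ecgFilterChain <- function(ecg, fs = 250) {
    runChain(ecg, fs, ecgFilterSpecs(fs), pulseOnRaw = TRUE)
}

#' TEB filterbank (Step 1 of the bioimpedance chain)
#'
#' Same topology at 100 Hz with order `N2 = 400`, stretch 10: an anti-aliasing
#' low-pass (cutoff 4 Hz, order 100) feeds three IFIR stages -- 0.1 Hz
#' low-pass (`fe1`), a 0.1--0.8 Hz respiration band-pass (`fe2`, covering
#' 6--48 breaths/min) and a 0.8--3 Hz pulse band-pass (`fe3`, 48--180
#' beats/min) from which the TEB pulse rate is derived.
#'
#' @param teb numeric TEB samples.
#' @param fs sampling rate, Hz (default 100).
#' @return A [FilteredSignals-class].
#' @export
tebFilterChain <- function(teb, fs = 100) {
    runChain(teb, fs, tebFilterSpecs(fs), pulseOnRaw = FALSE)
}

#' Decimate a band-limited signal to the intermediate rate
#'
#' Keeps every `(fs/targetIF)`-th sample starting at the first (phase 0). The
#' input must already be band-limited below `targetIF / 2` by the preceding
#' filter stage; no additional filtering is applied.
#'
#' @param x numeric samples.
#' @param fs input rate, Hz; must be an integer multiple of `targetIF`.
#' @param targetIF target rate, Hz (default 50).
#' @return numeric vector of length `floor(length(x) * targetIF / fs)`.
#' @examples
#' length(decimateToIF(sin(seq_len(3000)), fs = 250))  # 600
#' @export
decimateToIF <- function(x, fs, targetIF = 50) {
    m <- fs / targetIF
    if (abs(m - round(m)) > 1e-9) {
        stop("'fs' must be an integer multiple of 'targetIF'")
    }
    m <- as.integer(round(m))
    nOut <- floor(length(x) / m)
    if (nOut == 0L) return(numeric(0))
    x[seq.int(1L, by = m, length.out = nOut)]
}
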