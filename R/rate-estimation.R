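## Step 2: cycle detectors (breaths-per-minute and pulses-per-minute blocks),
## piecewise-constant interpolation to the intermediate rate, and assembly of
## the eight IF signals.

#' Breaths-per-minute block: cycle detection on a sine-shaped signal
#'
#' Detects alternating local maxima and minima with a hysteresis threshold
#' (a fraction of a running peak-to-peak estimate), emitting one event per
#' completed cycle: the rate is `60 / (interval between successive maxima)`
#' in cycles/min and the amplitude is the max minus min within the cycle.
#' The hysteresis adapts as an exponential moving average of recent cycle
#' amplitudes, which makes detection invariant to overall signal scale. A
#' refractory interval suppresses maxima that follow the previous one too
#' closely (noise-driven double counts).
#'
#' @param x numeric; band-limited oscillatory signal.
#' @param fs sampling rate of `x`, Hz.
#' @param hysteresis fraction of the running peak-to-peak estimate (default
#'   0.2; 0.3 suits the blunter TEB pulse wave).
#' @param refractory minimum spacing between maxima, seconds (default 1 s for
#'   respiration; 0.3 s for the TEB pulse band).
#' @return A `data.frame` (cycle events) with columns `time` (s, position of
#'   the cycle-closing maximum), `rate` (cycles/min) and `amplitude`.
#'   Zero rows if no full cycle was found (e.g. a constant input).
#' @examples
#' t <- seq(0, 120, by = 1 / 50)
#' ev <- bpmBlock(sin(2 * pi * 0.25 * t), fs = 50)
#' mean(ev$rate)        # ~15 breaths/min
#' mean(ev$amplitude)   # ~2 (peak-to-peak)
#' @export
bpmBlock <- function(x, fs, hysteresis = 0.2, refractory = 1.0) {
    empty <- data.frame(time = numeric(0), rate = numeric(0),
                        amplitude = numeric(0))
    n <- length(x)
    if (n < 3L) return(empty)
    init <- x[seq_len(min(n, as.integer(round(10 * fs))))]
    A <- diff(range(init))
    if (!is.finite(A) || A <= 0) return(empty)
    h <- hysteresis * A
    phase <- 0L           # 0 unknown, 1 rising (seek max), -1 falling
    cmV <- x[1L]; cmI <- 1L   # running max since last confirmed minimum
    cnV <- x[1L]              # running min since last confirmed maximum
    lastMaxT <- -Inf
    times <- numeric(0); rates <- numeric(0); amps <- numeric(0)
    for (i in seq_len(n)) {
        xi <- x[i]
        if (xi > cmV) { cmV <- xi; cmI <- i }
        if (xi < cnV) { cnV <- xi }
        if (phase >= 0L && cmV - xi > h) {
            tMax <- (cmI - 1L) / fs
            if (tMax - lastMaxT >= refractory) {
                if (is.finite(lastMaxT)) {
                    amp <- cmV - cnV
                    times <- c(times, tMax)
                    rates <- c(rates, 60 / (tMax - lastMaxT))
                    amps <- c(amps, amp)
                    A <- 0.7 * A + 0.3 * amp
                    h <- hysteresis * A
                }
                lastMaxT <- tMax
            }
            phase <- -1L
            cnV <- xi
        } else if (phase <= 0L && xi - cnV > h) {
            phase <- 1L
            cmV <- xi; cmI <- i
        }
    }
    data.frame(time = times, rate = rates, amplitude = amps)
}

#' Pulses-per-minute block: beat detection by thresholded differentiation
#'
#' Computes the five-sample differentiation `d[n] = x[n] - x[n-5]` and marks a
#' beat wherever `d` crosses an adaptive threshold upward, subject to a
#' refractory period. The threshold is `thresholdFactor` times a running 95th
#' percentile of the positive values of `d` over the trailing `window`
#' seconds (updated every `hop` seconds and held in between), so detection is
#' invariant to signal amplitude.
#'
#' @param x numeric; pulse-bearing signal (the 30 Hz low-pass ECG branch).
#' @param fs sampling rate, Hz.
#' @param diffLag differentiation lag in samples (default 5).
#' @param thresholdFactor threshold as a fraction of the running percentile.
#' @param refractory minimum inter-beat interval, seconds (default 0.25, i.e.
#'   up to 240 beats/min).
#' @param probs percentile of positive `d` used by the threshold.
#' @param window trailing window for the percentile, seconds.
#' @param hop threshold update interval, seconds.
#' @return A cycle-event `data.frame` with columns `time`, `rate`
#'   (beats/min) and `amplitude` (`NA`; the PPM block does not measure
#'   depth). Zero rows if no beats were found.
#' @export
ppmBlock <- function(x, fs, diffLag = 5L, thresholdFactor = 0.5,
                     refractory = 0.25, probs = 0.95, window = 5, hop = 1) {
    empty <- data.frame(time = numeric(0), rate = numeric(0),
                        amplitude = numeric(0))
    n <- length(x)
    if (n <= diffLag + 1L) return(empty)
    d <- c(numeric(diffLag), x[(diffLag + 1L):n] - x[seq_len(n - diffLag)])
    hopN <- max(1L, as.integer(round(hop * fs)))
    winN <- max(hopN, as.integer(round(window * fs)))
    anchors <- seq.int(1L, n, by = hopN)
    thrAt <- vapply(anchors, function(i) {
        seg <- d[max(1L, i - winN + 1L):i]
        pos <- seg[seg > 0]
        if (length(pos) < 3L) return(Inf)
        thresholdFactor * as.numeric(quantile(pos, probs, names = FALSE))
    }, numeric(1))
    thr <- thrAt[findInterval(seq_len(n), anchors)]
    above <- d >= thr
    cross <- which(above & !c(FALSE, above[-n]))
    if (length(cross) == 0L) return(empty)
    beatT <- numeric(0)
    last <- -Inf
    for (i in cross) {
        t <- (i - 1L) / fs
        if (t - last >= refractory) {
            beatT <- c(beatT, t)
            last <- t
        }
    }
    if (length(beatT) < 2L) return(empty)
    data.frame(time = beatT[-1L],
               rate = 60 / diff(beatT),
               amplitude = NA_real_)
}

## ZOH of an event series onto a uniform grid starting at t0.
zohSeries <- function(times, values, tout) {
    if (length(times) == 0L) {
        stop("no cycle events: window unusable", call. = FALSE)
    }
    if (all(is.na(values))) return(rep(NA_real_, length(tout)))
    if (length(times) == 1L) return(rep(values, length(tout)))
    approx(times, values, xout = tout, method = "constant",
           f = 0, rule = 2, ties = "ordered")$y
}

#' Piecewise-constant interpolation of cycle events to the intermediate rate
#'
#' Each output sample takes the most recent event's value (last-value hold,
#' left-closed: an event falling exactly on a sample instant updates that
#' sample). Samples before the first event take the first event's value.
#'
#' @param events cycle events from [bpmBlock()] or [ppmBlock()].
#' @param duration trace duration, seconds.
#' @param ifRate output rate, Hz (default 50).
#' @param t0 time of the first output sample, seconds.
#' @return A list with numeric vectors `rate` and `amplitude`, each of length
#'   `floor(duration * ifRate)`.
#' @export
zohInterpolate <- function(events, duration, ifRate = 50, t0 = 0) {
    stopifnot2(duration >= 0, "'duration' must be non-negative")
    if (nrow(events) == 0L) {
        stop("no cycle events: window unusable", call. = FALSE)
    }
    tout <- t0 + (seq_len(floor(duration * ifRate)) - 1L) / ifRate
    list(rate = zohSeries(events$time, events$rate, tout),
         amplitude = zohSeries(events$time, events$amplitude, tout))
}

#' Assemble the eight intermediate-frequency signals of a recording
#'
#' Runs both filter chains, the cycle detectors and the zero-order-hold
#' interpolation, producing the `ECF`, `ERT`, `ERD`, `EPPM`, `ZCF`, `ZRT`,
#' `ZRD`, `ZPPM` traces on a common 50 Hz grid. Detectors operate on the
#' warm-up-free span of each chain; a detector that finds no cycles leaves
#' its column(s) `NA` with a warning.
#'
#' @param rec a [RawRecording-class].
#' @param ifRate common intermediate rate, Hz.
#' @param bpmHysteresis,bpmRefractory respiration-cycle detector settings.
#' @param zppmHysteresis,zppmRefractory TEB pulse-cycle detector settings
#'   (blunter wave, faster cycles).
#' @param ppmThresholdFactor,ppmRefractory ECG beat detector settings.
#' @return An [IFSignalSet-class].
#' @export
assembleIFSignals <- function(rec, ifRate = 50,
                              bpmHysteresis = 0.2, bpmRefractory = 1.0,
                              zppmHysteresis = 0.3, zppmRefractory = 0.3,
                              ppmThresholdFactor = 0.5, ppmRefractory = 0.25) {
    stopifnot(is(rec, "RawRecording"))
    ecgF <- ecgFilterChain(rec@ecg, rec@fsEcg)
    tebF <- tebFilterChain(rec@teb, rec@fsTeb)
    duration <- recordingDuration(rec)
    nIf <- min(floor(length(rec@ecg) * ifRate / rec@fsEcg),
               floor(length(rec@teb) * ifRate / rec@fsTeb))
    validStart <- max(ecgF@warmup / rec@fsEcg, tebF@warmup / rec@fsTeb)
    validEnd <- duration - validStart
    if (validEnd <= validStart) {
        stop("recording shorter than twice the filter warm-up span")
    }

    seg <- function(x, fs) {
        i0 <- as.integer(floor(validStart * fs)) + 1L
        i1 <- length(x) - i0 + 1L
        x[i0:i1]
    }
    naCol <- rep(NA_real_, nIf)
    hold <- function(events) {
        if (nrow(events) == 0L) {
            return(list(rate = naCol, amplitude = naCol))
        }
        tout <- (seq_len(nIf) - 1L) / ifRate
        list(rate = zohSeries(events$time + validStart, events$rate, tout),
             amplitude = zohSeries(events$time + validStart, events$amplitude,
                                   tout))
    }

    ecf <- decimateToIF(ecgF@fe1, rec@fsEcg, ifRate)[seq_len(nIf)]
    zcf <- decimateToIF(tebF@fe1, rec@fsTeb, ifRate)[seq_len(nIf)]

    evResp <- bpmBlock(decimateToIF(seg(ecgF@fe2, rec@fsEcg), rec@fsEcg, ifRate),
                       ifRate, bpmHysteresis, bpmRefractory)
    evZResp <- bpmBlock(decimateToIF(seg(tebF@fe2, rec@fsTeb), rec@fsTeb, ifRate),
                        ifRate, bpmHysteresis, bpmRefractory)
    evBeat <- ppmBlock(seg(ecgF@fe3, rec@fsEcg), rec@fsEcg,
                       thresholdFactor = ppmThresholdFactor,
                       refractory = ppmRefractory)
    evZBeat <- bpmBlock(decimateToIF(seg(tebF@fe3, rec@fsTeb), rec@fsTeb, ifRate),
                        ifRate, zppmHysteresis, zppmRefractory)

    streams <- list(ERT = evResp, ZRT = evZResp, EPPM = evBeat, ZPPM = evZBeat)
    emptyOnes <- names(streams)[vapply(streams, nrow, integer(1)) == 0L]
    if (length(emptyOnes)) {
        warning("no cycles detected for: ", paste(emptyOnes, collapse = ", "),
                "; signal(s) set to NA")
    }
    hResp <- hold(evResp); hZResp <- hold(evZResp)
    hBeat <- hold(evBeat); hZBeat <- hold(evZBeat)

    signals <- cbind(ECF = ecf, ERT = hResp$rate, ERD = hResp$amplitude,
                     EPPM = hBeat$rate, ZCF = zcf, ZRT = hZResp$rate,
                     ZRD = hZResp$amplitude, ZPPM = hZBeat$rate)
    new("IFSignalSet", signals = signals, ifRate = ifRate,
        validStart = validStart, validEnd = validEnd,
        subjectId = rec@subjectId, labels = rec@labels)
}

#' Export the eight IF signals as delimited text
#'
#' Writes a tab-separated table with a `time_s` column followed by the eight
#' signal columns, for external inspection.
#'
#' @param x an [IFSignalSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeIFSignals <- function(x, path) {
    stopifnot(is(x, "IFSignalSet"))
    df <- data.frame(time_s = (seq_len(nrow(x@signals)) - 1L) / x@ifRate,
                     x@signals, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(path)
}
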