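## Synthetic multi-subject ECG + TEB generator with known ground truth.
##
## The generator emulates the statistical structure of the study conditions:
## class-conditional mean heart rate, respiration rate and respiration depth,
## plus per-channel slow levels. The ECG channel is a quasi-periodic train of
## narrow raised-cosine pulses riding on a respiration-coupled baseline
## wander and slow drift; the TEB channel is dominated by the respiration
## oscillation with a smaller cardiac-frequency component and drift. Gaussian
## noise is added to both. Every random draw is controlled by a seed.

CLASS_TABLE <- data.frame(
    label = c("neutral", "emotional", "mental", "physical",
              "neutral_emotion", "sad", "disgust", "low_mental", "high_mental"),
    hr  = c(72.07, 70.99, 74.62, 130.43, 72.10, 70.21, 71.12, 74.37, 74.77),
    rr  = c(28.17, 29.62, 27.69, 24.75, 27.95, 29.53, 28.46, 28.76, 27.59),
    erd = c(0.32, 0.40, 0.45, 1.20, 0.32, 0.43, 0.43, 0.44, 0.45),
    zrd = c(0.09, 0.16, 0.27, 0.67, 0.09, 0.09, 0.23, 0.19, 0.25),
    ecf = c(4.92, 4.93, 4.92, 5.36, 4.92, 4.93, 4.92, 4.92, 4.92),
    zcf = c(5.61, 6.33, 5.74, 7.89, 5.60, 5.74, 6.89, 5.75, 5.72),
    stringsAsFactors = FALSE
)

#' Class-conditional generator conditions
#'
#' Returns the default class conditions for one of the three classification
#' tasks: mean heart rate (`hr`, beats/min), respiration rate (`rr`,
#' breaths/min), ECG and TEB respiration depths (`erd`, `zrd`, amplitude
#' units) and the slow channel levels (`ecf`, `zcf`). For the emotion task
#' the neutral row is the emotion-specific one (labelled `neutral`).
#'
#' @param analysis `"activity"` (4 classes), `"emotion"` (3) or
#'   `"mental"` (2).
#' @return A `data.frame`, one row per class.
#' @examples
#' classConditions("activity")
#' @export
classConditions <- function(analysis = c("activity", "emotion", "mental")) {
    analysis <- match.arg(analysis)
    rows <- switch(analysis,
        activity = c("neutral", "emotional", "mental", "physical"),
        emotion = c("neutral_emotion", "sad", "disgust"),
        mental = c("low_mental", "high_mental"))
    out <- CLASS_TABLE[match(rows, CLASS_TABLE$label), , drop = FALSE]
    out$label[out$label == "neutral_emotion"] <- "neutral"
    rownames(out) <- NULL
    out
}

#' Construct a custom class condition
#'
#' @param label class label.
#' @param hr mean heart rate, beats/min (in (30, 220)).
#' @param rr mean respiration rate, breaths/min (in (4, 60)).
#' @param erd,zrd respiration depth of the ECG baseline wander and of the TEB
#'   oscillation (amplitude units; the generated sinusoid has amplitude
#'   depth/2, i.e. peak-to-peak = depth).
#' @param ecf,zcf slow (below 0.1 Hz) channel levels.
#' @return A one-row `data.frame` compatible with [classConditions()].
#' @export
classCondition <- function(label, hr, rr, erd = 0.4, zrd = 0.2,
                           ecf = 4.9, zcf = 5.7) {
    stopifnot2(hr > 30 && hr < 220, "'hr' must lie in (30, 220) beats/min")
    stopifnot2(rr > 4 && rr < 60, "'rr' must lie in (4, 60) breaths/min")
    data.frame(label = as.character(label), hr = hr, rr = rr,
               erd = erd, zrd = zrd, ecf = ecf, zcf = zcf,
               stringsAsFactors = FALSE)
}

#' Per-subject profile with multiplicative physiological offsets
#'
#' Subject identity acts as a confounder: one multiplicative factor per
#' physiological quantity is drawn once per subject (log-normal with
#' standard deviation `jitter` on the log scale) and applied to every class
#' condition of that subject's recording. This creates the subject-level
#' grouping that leave-one-subject-out evaluation must respect.
#'
#' @param subjectId subject label.
#' @param jitter fractional inter-subject standard deviation (0 disables).
#' @param seed integer; fully determines the subject's draws.
#' @return A list with the subject id, the three factors and the seed.
#' @export
subjectProfile <- function(subjectId, jitter = 0.05, seed = NULL) {
    f <- withSeed(seed, exp(rnorm(3L, 0, jitter)))
    list(subjectId = as.character(subjectId),
         hrFactor = f[1L], rrFactor = f[2L], depthFactor = f[3L],
         jitter = jitter, seed = seed)
}

## piecewise-constant lookup of a schedule column on a time grid
schedAt <- function(t, bounds, values) {
    idx <- pmin(findInterval(t, bounds, rightmost.closed = FALSE) , length(values))
    idx[idx < 1L] <- 1L
    values[idx]
}

#' Generate one labelled two-channel recording
#'
#' @param schedule `data.frame` with a `duration` column (seconds) plus the
#'   condition columns of [classConditions()]; one row per contiguous
#'   labelled segment. Total duration must be at least 60 s.
#' @param profile a [subjectProfile()]; its factors scale `hr`, `rr` and the
#'   depths.
#' @param seed integer seed for phases, beat jitter and noise (`NULL` uses
#'   the current RNG stream).
#' @param fsEcg,fsTeb channel sampling rates, Hz.
#' @param ecgNoiseSd,tebNoiseSd additive white-noise standard deviations
#'   (the ECG beat template has unit amplitude).
#' @param hrvSd beat-to-beat fractional jitter of the inter-beat interval.
#' @param driftAmplitude,driftFrequency slow sinusoidal drift added to both
#'   channels (amplitude units, Hz).
#' @param cardiacAmplitude amplitude of the TEB cardiac-frequency component.
#' @param beatWidth ECG raised-cosine beat template width, seconds.
#' @return A [RawRecording-class]; `groundTruth()` holds the realized
#'   piecewise-constant targets.
#' @examples
#' sch <- cbind(duration = 300, classConditions("activity")[1, ])
#' rec <- generateRecording(sch, subjectProfile("S1", seed = 1), seed = 7)
#' rec
#' @export
generateRecording <- function(schedule,
                              profile = subjectProfile("S1", jitter = 0),
                              seed = NULL,
                              fsEcg = 250, fsTeb = 100,
                              ecgNoiseSd = 0.02, tebNoiseSd = 0.005,
                              hrvSd = 0.02,
                              driftAmplitude = 0.05, driftFrequency = 0.02,
                              cardiacAmplitude = 0.05, beatWidth = 0.08) {
    need <- c("duration", "hr", "rr", "erd", "zrd", "ecf", "zcf", "label")
    stopifnot2(all(need %in% names(schedule)),
               paste("schedule must have columns:", paste(need, collapse = ", ")))
    stopifnot2(all(schedule$duration > 0), "segment durations must be positive")
    total <- sum(schedule$duration)
    stopifnot2(total >= 60, "total duration must be at least 60 s (one window)")
    stopifnot2(all(is.finite(schedule$hr)) && all(schedule$hr > 0) &&
               all(is.finite(schedule$rr)) && all(schedule$rr > 0),
               "unknown or invalid class condition (hr/rr must be positive)")

    sch <- schedule
    sch$hr <- sch$hr * profile$hrFactor
    sch$rr <- sch$rr * profile$rrFactor
    sch$erd <- sch$erd * profile$depthFactor
    sch$zrd <- sch$zrd * profile$depthFactor
    ends <- cumsum(sch$duration)
    bounds <- c(0, ends[-length(ends)])

    withSeed(seed, {
        phases <- runif(4L, 0, 2 * pi)
        nE <- as.integer(round(total * fsEcg))
        nT <- as.integer(round(total * fsTeb))
        tE <- (seq_len(nE) - 1L) / fsEcg
        tT <- (seq_len(nT) - 1L) / fsTeb

        ## respiration phase: integral of the piecewise-constant rate
        respPhase <- function(t, fs) {
            2 * pi * cumsum(schedAt(t, bounds, sch$rr) / 60) / fs + phases[1L]
        }
        cardPhase <- function(t, fs) {
            2 * pi * cumsum(schedAt(t, bounds, sch$hr) / 60) / fs + phases[2L]
        }

        ## ECG beat train: intervals follow the local heart rate with
        ## log-normal beat-to-beat jitter (mean-one)
        beats <- numeric(0)
        tb <- 0
        while (tb < total) {
            hrNow <- schedAt(tb, bounds, sch$hr)
            jit <- if (hrvSd > 0) exp(rnorm(1L, -hrvSd^2 / 2, hrvSd)) else 1
            tb <- tb + 60 / hrNow * jit
            if (tb < total) beats <- c(beats, tb)
        }
        pulses <- numeric(nE)
        half <- beatWidth / 2
        for (tb in beats) {
            i0 <- max(1L, as.integer(ceiling((tb - half) * fsEcg)) + 1L)
            i1 <- min(nE, as.integer(floor((tb + half) * fsEcg)) + 1L)
            if (i1 >= i0) {
                tt <- tE[i0:i1] - tb
                pulses[i0:i1] <- pulses[i0:i1] +
                    0.5 * (1 + cos(2 * pi * tt / beatWidth))
            }
        }

        ecg <- schedAt(tE, bounds, sch$ecf) +
            driftAmplitude * sin(2 * pi * driftFrequency * tE + phases[3L]) +
            (schedAt(tE, bounds, sch$erd) / 2) * sin(respPhase(tE, fsEcg)) +
            pulses +
            rnorm(nE, 0, ecgNoiseSd)
        teb <- schedAt(tT, bounds, sch$zcf) +
            driftAmplitude * sin(2 * pi * driftFrequency * tT + phases[4L]) +
            (schedAt(tT, bounds, sch$zrd) / 2) * sin(respPhase(tT, fsTeb)) +
            cardiacAmplitude * sin(cardPhase(tT, fsTeb)) +
            rnorm(nT, 0, tebNoiseSd)

        labels <- data.frame(start = bounds, end = ends,
                             label = sch$label, stringsAsFactors = FALSE)
        truth <- list(schedule = cbind(start = bounds, end = ends,
                                       sch[setdiff(names(sch), "duration")]),
                      profile = profile, beatTimes = beats)
        new("RawRecording", ecg = ecg, teb = teb,
            fsEcg = fsEcg, fsTeb = fsTeb,
            subjectId = profile$subjectId, labels = labels, truth = truth)
    })
}

#' Generate a balanced multi-subject cohort
#'
#' One recording per subject, containing every class for `classDuration`
#' seconds (segment order randomly permuted per subject). Subject-level
#' multiplicative offsets are drawn once per subject so that subject identity
#' confounds the class signal, as assumed by leave-one-subject-out
#' evaluation.
#'
#' @param nSubjects number of subjects (at least 2).
#' @param conditions class-condition `data.frame` (see [classConditions()]).
#' @param classDuration seconds of each class per subject.
#' @param jitter inter-subject fractional standard deviation of the
#'   physiological factors (0 makes all subjects identical in expectation).
#' @param seed master seed; determines all subject draws.
#' @param shuffleClasses permute segment order per subject.
#' @param ... passed to [generateRecording()] (noise levels etc.).
#' @return A list of [RawRecording-class], one per subject.
#' @examples
#' coh <- generateCohort(2, classConditions("mental"), classDuration = 100,
#'                       seed = 1)
#' length(coh)
#' @export
generateCohort <- function(nSubjects, conditions, classDuration = 150,
                           jitter = 0.05, seed = NULL, shuffleClasses = TRUE,
                           ...) {
    stopifnot2(nSubjects >= 2, "'nSubjects' must be at least 2")
    stopifnot2(is.data.frame(conditions) && nrow(conditions) > 0,
               "'conditions' must be a non-empty class-condition data.frame")
    withSeed(seed, {
        recs <- vector("list", nSubjects)
        for (i in seq_len(nSubjects)) {
            prof <- subjectProfile(sprintf("S%02d", i), jitter = jitter)
            ord <- if (shuffleClasses) sample.int(nrow(conditions)) else
                seq_len(nrow(conditions))
            sch <- cbind(duration = classDuration,
                         conditions[ord, , drop = FALSE])
            recSeed <- sample.int(.Machine$integer.max - 1L, 1L)
            recs[[i]] <- generateRecording(sch, prof, seed = recSeed, ...)
        }
        names(recs) <- vapply(recs, subjectId, character(1))
        recs
    })
}

#' Write / read a recording as delimited text plus a JSON label sidecar
#'
#' `writeRecording()` stores each channel as a two-column (`time_s`,
#' `value`) tab-separated file (`ecg.tsv`, `teb.tsv`) and the subject id and
#' label intervals as `labels.json`. `readRecording()` restores the
#' recording (without generator ground truth).
#'
#' @param rec a [RawRecording-class].
#' @param dir directory to write to / read from (created if needed).
#' @return `writeRecording()` returns `dir` invisibly; `readRecording()`
#'   returns a [RawRecording-class].
#' @export
writeRecording <- function(rec, dir) {
    stopifnot(is(rec, "RawRecording"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    chan <- function(x, fs, f) {
        utils::write.table(
            data.frame(time_s = (seq_along(x) - 1L) / fs, value = x),
            file.path(dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
    }
    chan(rec@ecg, rec@fsEcg, "ecg.tsv")
    chan(rec@teb, rec@fsTeb, "teb.tsv")
    meta <- list(subject_id = rec@subjectId,
                 fs_ecg = rec@fsEcg, fs_teb = rec@fsTeb,
                 labels = rec@labels)
    jsonlite::write_json(meta, file.path(dir, "labels.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}

#' @rdname writeRecording
#' @export
readRecording <- function(dir) {
    meta <- jsonlite::read_json(file.path(dir, "labels.json"),
                                simplifyVector = TRUE)
    rd <- function(f) utils::read.table(file.path(dir, f), header = TRUE,
                                        sep = "\t")$value
    labels <- as.data.frame(meta$labels)
    new("RawRecording", ecg = rd("ecg.tsv"), teb = rd("teb.tsv"),
        fsEcg = meta$fs_ecg, fsTeb = meta$fs_teb,
        subjectId = meta$subject_id, labels = labels, truth = list())
}
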