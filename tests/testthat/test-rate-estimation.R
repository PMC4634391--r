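test_that("the cycle detector reads rate and depth off pure sinusoids", {
    t <- seq(0, 120, by = 1 / 50)
    ev <- bpmBlock(sin(2 * pi * 0.25 * t), fs = 50)
    expect_gt(nrow(ev), 25)
    expect_equal(mean(ev$rate), 15, tolerance = 0.02)
    expect_equal(mean(ev$amplitude), 2, tolerance = 0.02)
    ev2 <- bpmBlock(sin(2 * pi * 0.5 * t), fs = 50, refractory = 0.5)
    expect_equal(mean(ev2$rate), 30, tolerance = 0.02)
    expect_true(all(diff(ev$time) > 0))
    expect_true(all(ev$rate > 0))
})

test_that("constant input yields no cycle events", {
    expect_identical(nrow(bpmBlock(rep(2.5, 500), fs = 50)), 0L)
    expect_identical(nrow(ppmBlock(rep(1, 5000), fs = 250)), 0L)
})

test_that("rate estimates are invariant to signal amplitude scaling", {
    t <- seq(0, 120, by = 1 / 50)
    x <- sin(2 * pi * 0.3 * t) + 0.05 * sin(2 * pi * 1.1 * t)
    base <- mean(bpmBlock(x, fs = 50)$rate)
    for (g in c(0.1, 10)) {
        expect_equal(mean(bpmBlock(g * x, fs = 50)$rate), base,
                     tolerance = 1e-9)
    }
    tp <- (0:(250 * 120 - 1)) / 250
    pulse <- (sin(2 * pi * 1.2 * tp))^20
    basep <- mean(ppmBlock(pulse, fs = 250)$rate)
    for (g in c(0.1, 10)) {
        expect_equal(mean(ppmBlock(g * pulse, fs = 250)$rate), basep,
                     tolerance = 1e-9)
    }
})

test_that("for periodic inputs the estimated rate error is within one part per cycle count", {
    t <- seq(0, 240, by = 1 / 50)
    ev <- bpmBlock(sin(2 * pi * 0.2 * t), fs = 50)
    expect_lt(abs(mean(ev$rate) - 12) / 12, 1 / nrow(ev))
})

test_that("beat thresholding recovers pulse-train rates", {
    tp <- (0:(250 * 150 - 1)) / 250
    p12 <- pmax(0, sin(2 * pi * 1.2 * tp))^10
    expect_equal(mean(ppmBlock(p12, fs = 250)$rate), 72, tolerance = 0.01)
    p20 <- pmax(0, sin(2 * pi * 2 * tp))^10
    ev <- ppmBlock(p20, fs = 250)
    expect_equal(mean(ev$rate), 120, tolerance = 0.01)
    ## no misses, no doubles in the interior
    expect_lte(abs(nrow(ev) - (floor(150 * 2) - 1)), 2)
})

test_that("zero-order hold matches a loop-based oracle on random event sets", {
    set.seed(42)
    for (rep in 1:20) {
        nEv <- sample(2:15, 1)
        times <- sort(runif(nEv, 0, 18))
        ev <- data.frame(time = times, rate = runif(nEv, 5, 40),
                         amplitude = runif(nEv))
        out <- zohInterpolate(ev, duration = 20, ifRate = 50)
        tout <- (seq_len(1000) - 1) / 50
        oracle <- vapply(tout, function(tt) {
            k <- which(ev$time <= tt)
            if (length(k) == 0) ev$rate[1] else ev$rate[max(k)]
        }, numeric(1))
        expect_identical(out$rate, oracle)
    }
})

test_that("hold conventions: single event, exact-sample event, empty error", {
    one <- data.frame(time = 5, rate = 15, amplitude = 1)
    out <- zohInterpolate(one, duration = 20, ifRate = 50)
    expect_equal(out$rate, rep(15, 1000))
    ## event exactly on a sample instant: that sample takes the new value
    ev <- data.frame(time = c(0.02, 10), rate = c(15, 30), amplitude = c(1, 2))
    out2 <- zohInterpolate(ev, duration = 20, ifRate = 50)
    expect_equal(out2$rate[10 * 50 + 1], 30)
    expect_equal(out2$rate[10 * 50], 15)
    empty <- data.frame(time = numeric(0), rate = numeric(0),
                        amplitude = numeric(0))
    expect_error(zohInterpolate(empty, 20, 50), "unusable")
})

test_that("the assembled IF signals share one grid and track the programmed state", {
    rec <- generateRecording(singleClassSchedule(240), seed = 31,
                             ecgNoiseSd = 0, tebNoiseSd = 0)
    ifs <- assembleIFSignals(rec)
    sig <- ifSignals(ifs)
    expect_identical(dim(sig), c(12000L, 8L))
    expect_false(anyNA(sig))
    vr <- validRange(ifs)
    i <- seq(floor(vr[1] * 50) + 1, floor(vr[2] * 50))
    truthHr <- groundTruth(rec)$schedule$hr[1]
    truthRr <- groundTruth(rec)$schedule$rr[1]
    expect_equal(mean(sig[i, "EPPM"]), truthHr, tolerance = 0.02)
    expect_equal(mean(sig[i, "ZPPM"]), truthHr, tolerance = 0.02)
    expect_equal(mean(sig[i, "ERT"]), truthRr, tolerance = 0.04)
    expect_equal(mean(sig[i, "ZRT"]), truthRr, tolerance = 0.04)
    ## noise-free respiration trace is piecewise constant near ground truth
    expect_lt(max(abs(sig[i, "ZRT"] - truthRr)), 1.5)
})
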