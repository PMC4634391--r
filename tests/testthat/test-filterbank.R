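tone <- function(f, fs, duration) sin(2 * pi * f * (0:(duration * fs - 1)) / fs)

## steady-state RMS over the warm-up-free middle of a filtered signal
midRms <- function(x, warmup) {
    m <- x[(warmup + 1):(length(x) - warmup)]
    sqrt(mean(m^2))
}

test_that("filter specs validate their band edges", {
    expect_error(filterSpec("fir_lowpass", 100, 200, fs = 250), "inside")
    expect_error(filterSpec("fir_lowpass", -1, 0.5, fs = 250), "positive")
    expect_error(filterSpec("ifir_lowpass", 1150, 6, 250, stretch = 25),
                 "stretch")
    expect_error(filterSpec("ifir_bandpass", 400, c(0.5, 0.1), 100,
                            stretch = 10), "increasing")
})

test_that("low-pass designs have unit DC gain and linear-phase symmetry", {
    for (spec in list(filterSpec("fir_lowpass", 100, 30, 250),
                      filterSpec("ifir_lowpass", 1150, 0.1, 250, stretch = 25),
                      filterSpec("ifir_lowpass", 400, 0.1, 100, stretch = 10))) {
        filt <- designFilter(spec)
        if (spec@kind == "ifir_lowpass") {
            expect_equal(filterResponse(filt, 0), 1, tolerance = 0.01)
        } else {
            expect_equal(sum(filt$coef), 1, tolerance = 0.01)
        }
        ## symmetric coefficients <=> linear phase, group delay order*SF/2
        expect_equal(filt$coef, rev(filt$coef), tolerance = 1e-12)
        expect_identical(filt$delay,
                         as.integer(spec@order * spec@stretch / 2))
    }
})

test_that("the narrow-band ECG stages separate the slow and respiration bands", {
    cf <- designFilter(filterSpec("ifir_lowpass", 1150, 0.1, 250, stretch = 25))
    rf <- designFilter(filterSpec("ifir_bandpass", 1150, c(0.1, 0.5), 250,
                                  stretch = 25))
    expect_equal(filterResponse(cf, 0.05), 1, tolerance = 0.02)
    expect_lt(filterResponse(cf, 0.5), 0.05)
    expect_lt(filterResponse(cf, 0.25), 0.05)
    expect_equal(filterResponse(rf, 0.25), 1, tolerance = 0.02)
    expect_lt(filterResponse(rf, 0.05), 1 / 20)
    ## images of the stretched prototype sit at multiples of fs/SF = 10 Hz;
    ## the 0.5 Hz anti-aliasing low-pass must suppress them
    lf <- designFilter(filterSpec("fir_lowpass", 100, 0.5, 250))
    expect_lt(filterResponse(lf, 10) * filterResponse(cf, 10), 0.01)
})

test_that("filters are linear and time-invariant", {
    filt <- designFilter(filterSpec("fir_lowpass", 100, 30, 250))
    set.seed(8)
    x1 <- rnorm(2000); x2 <- rnorm(2000)
    a <- 0.7; b <- -1.3
    expect_equal(physiostress:::applyFilter(filt, a * x1 + b * x2),
                 a * physiostress:::applyFilter(filt, x1) +
                     b * physiostress:::applyFilter(filt, x2),
                 tolerance = 1e-9)
    ## time invariance: shifting the input shifts the output
    sh <- 37L
    y <- physiostress:::applyFilter(filt, x1)
    ysh <- physiostress:::applyFilter(filt, c(numeric(sh), x1))
    expect_equal(ysh[(sh + 200):(sh + 1800)], y[200:1800], tolerance = 1e-9)
})

test_that("a tone sweep lands in exactly one of FE1/FE2 outside the 0.1 Hz transition band", {
    ## stated transition band around the 0.1 Hz split: (0.07, 0.13) Hz
    dur <- 400
    for (f in c(0.02, 0.05, 0.2, 0.3, 0.45)) {
        ch <- ecgFilterChain(tone(f, 250, dur))
        r1 <- midRms(ch@fe1, ch@warmup)
        r2 <- midRms(ch@fe2, ch@warmup)
        if (f < 0.07) expect_gt(r1 / r2, 10) else expect_gt(r2 / r1, 10)
    }
})

test_that("ECG chain routes tones to the expected branches", {
    dur <- 400
    slow <- ecgFilterChain(tone(0.05, 250, dur))
    expect_equal(midRms(slow@fe1, slow@warmup), sqrt(0.5), tolerance = 0.05)
    expect_gt(midRms(slow@fe1, slow@warmup) / midRms(slow@fe2, slow@warmup), 20)
    resp <- ecgFilterChain(tone(0.25, 250, dur))
    expect_equal(midRms(resp@fe2, resp@warmup), sqrt(0.5), tolerance = 0.05)
    expect_gt(midRms(resp@fe2, resp@warmup) / midRms(resp@fe1, resp@warmup), 20)
    zero <- ecgFilterChain(numeric(250 * 120))
    expect_equal(max(abs(zero@fe1), abs(zero@fe2), abs(zero@fe3)), 0)
})

test_that("TEB chain routes respiration and pulse tones to their branches", {
    dur <- 300
    resp <- tebFilterChain(tone(0.25, 100, dur))
    expect_gt(midRms(resp@fe2, resp@warmup) / midRms(resp@fe3, resp@warmup), 10)
    pulse <- tebFilterChain(tone(1.2, 100, dur))
    expect_gt(midRms(pulse@fe3, pulse@warmup) / midRms(pulse@fe2, pulse@warmup), 10)
    zero <- tebFilterChain(numeric(100 * 120))
    expect_equal(max(abs(zero@fe1), abs(zero@fe2), abs(zero@fe3)), 0)
})

test_that("too-short inputs are refused with a warm-up message", {
    expect_error(ecgFilterChain(numeric(1000)), "warm-up")
})

test_that("decimation keeps every m-th sample with exact arithmetic", {
    expect_equal(decimateToIF(rep(3.2, 250), fs = 250), rep(3.2, 50))
    expect_length(decimateToIF(rnorm(3000), fs = 250), 600)
    expect_length(decimateToIF(rnorm(3001), fs = 250), 600)
    expect_error(decimateToIF(rnorm(100), fs = 130), "integer multiple")
    ## a slow sinusoid decimates onto the analytic resampling exactly
    t250 <- (0:(250 * 60 - 1)) / 250
    x <- sin(2 * pi * 0.05 * t250)
    y <- decimateToIF(x, 250)
    t50 <- (0:(length(y) - 1)) / 50
    expect_lt(max(abs(y - sin(2 * pi * 0.05 * t50))), 1e-6)
})
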