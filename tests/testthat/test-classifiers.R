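test_that("well-separated clouds are classified without training error", {
    set.seed(1)
    n <- 150
    X <- rbind(matrix(rnorm(n * 2, 0, 0.3), n, 2),
               matrix(rnorm(n * 2, 4, 0.3), n, 2))
    y <- rep(c("low", "high"), each = n)
    fit <- linearFit(X, y)
    expect_equal(mean(linearPredict(fit, X)$decision != y), 0)
})

test_that("least-squares weights match the pseudoinverse closed form", {
    set.seed(2)
    X <- matrix(rnorm(80 * 3), 80, 3)
    y <- factor(rep_len(c("u", "v", "w"), 80))
    fit <- linearFit(X, y, ridge = 0, standardize = FALSE)
    Y <- sapply(levels(y), function(k) as.numeric(y == k))
    expect_equal(fit$weights, qr.solve(cbind(1, X), Y), tolerance = 1e-8,
                 ignore_attr = TRUE)
})

test_that("duplicating every sample leaves the weights unchanged", {
    set.seed(3)
    X <- matrix(rnorm(60 * 4), 60, 4)
    y <- rep_len(c("a", "b"), 60)
    f1 <- linearFit(X, y, standardize = FALSE)
    f2 <- linearFit(rbind(X, X), c(y, y), standardize = FALSE)
    expect_equal(f1$weights, f2$weights, tolerance = 1e-9)
})

test_that("degenerate single-class training is refused", {
    expect_error(linearFit(matrix(rnorm(20), 10, 2), rep("a", 10)),
                 "single class")
})

test_that("the MLP solves the XOR pattern the linear classifier cannot", {
    set.seed(4)
    n <- 400
    X <- matrix(runif(2 * n), n, 2)
    y <- ifelse(xor(X[, 1] > 0.5, X[, 2] > 0.5), "a", "b")
    subj <- rep(sprintf("S%d", 1:8), each = n / 8)
    tr <- subj %in% sprintf("S%d", 1:6)
    linErr <- mean(linearPredict(linearFit(X[tr, ], y[tr]),
                                 X[!tr, ])$decision != y[!tr])
    m <- mlpTrain(X[tr, ], y[tr], subj[tr], mlpConfig(seed = 2))
    mlpErr <- mean(mlpPredict(m, X[!tr, ])$decision != y[!tr])
    expect_gt(linErr, 0.3)
    expect_lt(mlpErr, 0.05)
})

test_that("MLP training is deterministic given the seed", {
    set.seed(5)
    X <- matrix(rnorm(200 * 3), 200, 3)
    y <- rep_len(c("a", "b", "c"), 200)
    subj <- rep(sprintf("S%d", 1:5), each = 40)
    m1 <- mlpTrain(X, y, subj, mlpConfig(seed = 11, restarts = 2))
    m2 <- mlpTrain(X, y, subj, mlpConfig(seed = 11, restarts = 2))
    expect_identical(m1$net$wts, m2$net$wts)
    expect_identical(mlpPredict(m1, X)$scores, mlpPredict(m2, X)$scores)
})

test_that("argmax decisions break ties toward the lowest class index", {
    scores <- matrix(c(0.5, 0.5), 1, 2)
    dec <- physiostress:::argmaxDecision(scores, c("one", "two"))
    expect_identical(as.character(dec), "one")
})

test_that("prediction refuses mismatched feature dimensions", {
    set.seed(6)
    X <- matrix(rnorm(100 * 3), 100, 3)
    y <- rep_len(c("a", "b"), 100)
    fit <- linearFit(X, y)
    expect_error(linearPredict(fit, X[, 1:2]), "dimension mismatch")
    m <- mlpTrain(X, y, rep(sprintf("S%d", 1:4), each = 25),
                  mlpConfig(seed = 1, restarts = 1))
    expect_error(mlpPredict(m, X[, 1:2]), "dimension mismatch")
})

test_that("early stopping keeps the best validation error seen", {
    set.seed(7)
    n <- 300
    X <- matrix(rnorm(n * 4), n, 4)
    y <- ifelse(X[, 1] + 0.5 * rnorm(n) > 0, "a", "b")
    subj <- rep(sprintf("S%d", 1:6), each = 50)
    m <- mlpTrain(X, y, subj, mlpConfig(seed = 3, restarts = 2))
    for (trace in m$valTraces) {
        expect_lte(min(trace), trace[length(trace)])
    }
    expect_lte(m$valMse, min(vapply(m$valTraces, min, numeric(1))) + 1e-12)
})

test_that("shuffled labels leave held-out accuracy at chance", {
    set.seed(8)
    n <- 480
    X <- matrix(rnorm(n * 5), n, 5)
    y <- sample(rep_len(c("a", "b"), n))
    subj <- rep(sprintf("S%d", 1:8), each = 60)
    tr <- subj %in% sprintf("S%d", 1:6)
    m <- mlpTrain(X[tr, ], y[tr], subj[tr], mlpConfig(seed = 4, restarts = 2))
    err <- mean(mlpPredict(m, X[!tr, ])$decision != y[!tr])
    ## binomial 3-sigma band around 0.5 with 120 test samples
    expect_lt(abs(err - 0.5), 3 * sqrt(0.25 / sum(!tr)) + 0.05)
})
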