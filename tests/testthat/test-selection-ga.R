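test_that("repair leaves under-budget sets untouched and always lands under budget", {
    sel <- c("ECG.ECF.mean", "ECG.EPPM.std")
    expect_identical(sort(gaRepair(sel, nmax = 1e6, seed = 1)), sort(sel))
    cat <- featureCatalog()
    for (s in 1:50) {
        out <- gaRepair(cat$name, nmax = 80000, seed = s)
        expect_gt(length(out), 0)
        expect_lt(totalNop(out), 80000)
    }
})

test_that("an unsatisfiable budget errors naming the cheapest single-feature cost", {
    ## cheapest single feature is a non-sort statistic of the slow TEB
    ## component: 10000 + 4000 + 900 + 300 = 15200 ops/s
    expect_error(gaRepair("ECG.ECF.mean", nmax = 100),
                 "cheapest single feature costs 15200")
})

test_that("duplicate individuals are perturbed into distinct sets", {
    pop <- list(c("ECG.ECF.mean", "ECG.ECF.std"),
                c("ECG.ECF.mean", "ECG.ECF.std"),
                "TEB.ZRT.max")
    out <- dedupePopulation(pop, seed = 3)
    keys <- vapply(out, function(f) paste(sort(f), collapse = ","), "")
    expect_identical(anyDuplicated(keys), 0L)
    ## first occurrence and already-distinct members unchanged
    expect_setequal(out[[1]], pop[[1]])
    expect_setequal(out[[3]], pop[[3]])
    ## the altered copy differs by exactly one feature
    expect_identical(length(setdiff(out[[2]], pop[[2]])), 1L)
})

test_that("fitness is near zero for linearly predictable labels and at the no-information level for noise", {
    set.seed(5)
    n <- 400; M <- 4
    subj <- rep(sprintf("S%d", 1:8), each = n / 8)
    y <- rep_len(LETTERS[1:M], n)
    Xgood <- cbind(sapply(LETTERS[1:M], function(k) as.numeric(y == k)),
                   matrix(rnorm(n * 4, 0, 0.01), n, 4))
    seGood <- featureSE(Xgood, y, subj)
    expect_lt(gaFitness(seGood, rownames(seGood)[1:4]), 0.01)
    Xnoise <- matrix(rnorm(n * 6), n, 6)
    seNoise <- featureSE(Xnoise, y, subj)
    ## one-hot target variance summed over outputs: (M-1)/M
    expect_equal(gaFitness(seNoise, c("f1", "f2")), (M - 1) / M,
                 tolerance = 0.05)
})

test_that("the GA recovers planted informative features under a generous budget", {
    hits <- 0L
    for (s in 1:5) {
        p <- plantedFeatureSE(500 + s)
        cfg <- gaConfig(nmax = 6e5, populationSize = 60, survivors = 10,
                        generations = 25, restarts = 1, seed = s)
        res <- selectFeaturesGA(p$se, cfg)
        hits <- hits + all(p$informative %in% selectedFeatures(res))
        expect_lt(res@nop, 6e5)
        expect_true(all(diff(res@trajectories[, 1]) <= 1e-12))
    }
    expect_gte(hits, 4L)
})

test_that("the returned individual respects the budget at realistic settings", {
    p <- plantedFeatureSE(77)
    cfg <- gaConfig(nmax = 60000, populationSize = 30, survivors = 6,
                    generations = 8, restarts = 2, seed = 2)
    res <- selectFeaturesGA(p$se, cfg)
    expect_lt(res@nop, 60000)
    expect_equal(res@nop, totalNop(selectedFeatures(res)))
    expect_true(all(is.finite(res@trajectories)))
})

test_that("feature selection is deterministic given the seed", {
    p <- plantedFeatureSE(12)
    cfg <- gaConfig(nmax = 2e5, populationSize = 20, survivors = 5,
                    generations = 5, restarts = 2, seed = 9)
    a <- selectFeaturesGA(p$se, cfg)
    b <- selectFeaturesGA(p$se, cfg)
    expect_identical(selectedFeatures(a), selectedFeatures(b))
    expect_identical(a@trajectories, b@trajectories)
})

test_that("unsatisfiable GA budgets error out before evolving", {
    p <- plantedFeatureSE(1)
    expect_error(selectFeaturesGA(p$se, gaConfig(nmax = 10, populationSize = 10,
                                                 survivors = 2, generations = 1,
                                                 restarts = 1, seed = 1)),
                 "unsatisfiable")
})
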