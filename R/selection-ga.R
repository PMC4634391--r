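## Budget-constrained genetic algorithm for feature selection: minimize the
## cross-validated mean squared error of a least-squares linear classifier
## subject to the strict operations-per-second constraint Nop < Nmax.

#' Genetic-algorithm configuration
#'
#' Defaults follow the selection procedure: a population of 200 feature
#' combinations, the best 20 surviving each generation, per-individual
#' mutation probability 10\%, 100 generations, and 5 independent restarts
#' from random initial populations (the best final individual across
#' restarts wins). The best individual of each generation is carried over
#' unaltered (elitism).
#'
#' @param nmax budget in operations per second (strict: `Nop < nmax`).
#' @param populationSize,survivors,mutationProb,generations,restarts the
#'   evolutionary parameters.
#' @param initMaxFeatures initial individuals draw a uniform 1..this many
#'   features before repair.
#' @param ridge relative ridge coefficient of the fitness classifier.
#' @param seed RNG seed controlling the whole run.
#' @return A list of settings (class `gaConfig`).
#' @export
gaConfig <- function(nmax, populationSize = 200, survivors = 20,
                     mutationProb = 0.10, generations = 100, restarts = 5,
                     initMaxFeatures = 20, ridge = 1e-8, seed = NULL) {
    stopifnot2(survivors < populationSize,
               "'survivors' must be smaller than 'populationSize'")
    stopifnot2(mutationProb >= 0 && mutationProb <= 1,
               "'mutationProb' must lie in [0, 1]")
    stopifnot2(nmax > 0, "'nmax' must be positive")
    structure(list(nmax = nmax, populationSize = populationSize,
                   survivors = survivors, mutationProb = mutationProb,
                   generations = generations, restarts = restarts,
                   initMaxFeatures = initMaxFeatures, ridge = ridge,
                   seed = seed),
              class = "gaConfig")
}

#' Result of a genetic-algorithm feature selection
#'
#' @slot features character; the selected feature names.
#' @slot fitness numeric; cross-validated linear-classifier MSE.
#' @slot nop numeric; operations-per-second cost of the selection.
#' @slot trajectories matrix; best fitness per generation (rows) and restart
#'   (columns) -- non-increasing down each column by elitism.
#' @slot nmax numeric; the budget the selection satisfies strictly.
#' @export
setClass("GAResult",
    representation(features = "character", fitness = "numeric",
                   nop = "numeric", trajectories = "matrix",
                   nmax = "numeric"))

setMethod("show", "GAResult", function(object) {
    cat(sprintf("GAResult: %d feature(s), fitness %.4f, Nop %g < Nmax %g\n",
                length(object@features), object@fitness, object@nop,
                object@nmax))
    cat(" ", paste(object@features, collapse = ", "), "\n")
})

#' @describeIn GAResult-class selected feature names.
#' @param x a `GAResult`.
#' @export
selectedFeatures <- function(x) x@features

## fast Nop evaluator over positions of `features` in the catalog
nopEvaluator <- function(features) {
    cat <- featureCatalog()
    idxCat <- match(features, cat$name)
    stopifnot2(!anyNA(idxCat),
               paste("feature names must come from the catalog; unknown:",
                     paste(features[is.na(idxCat)], collapse = ", ")))
    sg <- signalStages()
    stageNames <- names(sg$costs)
    depIdx <- lapply(sg$deps, match, stageNames)
    stageCostVec <- unname(sg$costs)
    sigLevels <- names(sg$deps)
    sigId <- match(cat$signal[idxCat], sigLevels)
    paramCostV <- cat$paramCost[idxCat]
    sortV <- cat$sortBased[idxCat]
    sortIncV <- ifelse(sortV, SORT_INCREMENT[cat$parameter[idxCat]], 0)
    function(idx) {
        if (length(idx) == 0L) return(0)
        stages <- unique(unlist(depIdx[unique(sigId[idx])], use.names = FALSE))
        s <- sum(stageCostVec[stages]) + sum(paramCostV[idx[!sortV[idx]]])
        sb <- idx[sortV[idx]]
        if (length(sb)) {
            for (g in unique(sigId[sb])) {
                s <- s + SORT_COST + sum(sortIncV[sb[sigId[sb] == g]])
            }
        }
        s
    }
}

## precomputed-Gram fitness evaluator: by-subject (k-1)-fold CV of the
## ridge-stabilized least-squares linear classifier, MSE summed over outputs
fitnessEvaluator <- function(X, y, subjects, ridge = 1e-8) {
    stopifnot2(!anyNA(X), "feature matrix must be complete (no NA)")
    std <- standardizer(X)
    Xa <- cbind(1, applyStd(X, std))
    y <- factor(y)
    Y <- oneHot(y, levels(y))
    us <- unique(subjects)
    stopifnot2(length(us) >= 2L, "design set must hold at least 2 subjects")
    folds <- lapply(us, function(s) subjects == s)
    pre <- lapply(folds, function(te) {
        tr <- !te
        list(A = crossprod(Xa[tr, , drop = FALSE]),
             B = crossprod(Xa[tr, , drop = FALSE], Y[tr, , drop = FALSE]),
             TT = crossprod(Xa[te, , drop = FALSE]),
             U = crossprod(Xa[te, , drop = FALSE], Y[te, , drop = FALSE]),
             const = sum(Y[te, ]^2),
             n = sum(te))
    })
    function(idx) {
        cols <- c(1L, idx + 1L)
        mse <- vapply(pre, function(p) {
            A <- p$A[cols, cols, drop = FALSE]
            lam <- ridge * mean(diag(A))
            W <- tryCatch(
                solve(A + diag(lam, length(cols)),
                      p$B[cols, , drop = FALSE]),
                error = function(e) NULL)
            if (is.null(W)) return(Inf)
            sse <- sum(W * (p$TT[cols, cols, drop = FALSE] %*% W)) -
                2 * sum(W * p$U[cols, , drop = FALSE]) + p$const
            max(sse, 0) / p$n
        }, numeric(1))
        mean(mse)
    }
}

repairIdx <- function(idx, nmax, nopFun, nFeat) {
    while (length(idx) && nopFun(idx) >= nmax) {
        idx <- idx[-sample.int(length(idx), 1L)]
    }
    tries <- 0L
    while (length(idx) == 0L) {
        cand <- sample.int(nFeat, 1L)
        if (nopFun(cand) < nmax) {
            idx <- cand
        } else if ((tries <- tries + 1L) > 10L * nFeat) {
            stop("budget unsatisfiable during repair", call. = FALSE)
        }
    }
    sort(idx)
}

dedupeIdx <- function(pop, nFeat, maxTries = 20L) {
    keys <- vapply(pop, paste, character(1), collapse = ",")
    for (i in seq_along(pop)) {
        tries <- 0L
        while (i > 1L && keys[i] %in% keys[seq_len(i - 1L)] &&
               tries < maxTries) {
            idx <- pop[[i]]
            out <- setdiff(seq_len(nFeat), idx)
            if (length(out) == 0L) break
            pos <- sample.int(length(idx), 1L)
            idx[pos] <- out[sample.int(length(out), 1L)]
            pop[[i]] <- sort(idx)
            keys[i] <- paste(pop[[i]], collapse = ",")
            tries <- tries + 1L
        }
    }
    pop
}

crossoverIdx <- function(p1, p2) {
    u <- union(p1, p2)
    child <- u[runif(length(u)) < 0.5]
    if (length(child) == 0L) child <- u[sample.int(length(u), 1L)]
    sort(child)
}

mutateIdx <- function(idx, nFeat) {
    out <- setdiff(seq_len(nFeat), idx)
    if (length(out) == 0L || length(idx) == 0L) return(idx)
    idx[sample.int(length(idx), 1L)] <- out[sample.int(length(out), 1L)]
    sort(idx)
}

#' Repair a feature set to satisfy the budget
#'
#' Randomly removes features while `Nop >= nmax`; if everything is removed,
#' random single features are drawn until one fits. Errors (naming the
#' cheapest single-feature cost) when no single feature fits the budget.
#'
#' @param features character vector of catalog feature names.
#' @param nmax budget, operations per second.
#' @param seed optional RNG seed.
#' @return A character vector of features with `Nop < nmax`.
#' @export
gaRepair <- function(features, nmax, seed = NULL) {
    cat <- featureCatalog()
    nopFun <- nopEvaluator(cat$name)
    cheapest <- min(vapply(seq_len(nrow(cat)), nopFun, numeric(1)))
    if (cheapest >= nmax) {
        stop(sprintf(
            "budget unsatisfiable: cheapest single feature costs %g ops/s (Nmax = %g)",
            cheapest, nmax), call. = FALSE)
    }
    idx <- match(features, cat$name)
    stopifnot2(!anyNA(idx), "unknown feature name(s)")
    withSeed(seed, cat$name[repairIdx(idx, nmax, nopFun, nrow(cat))])
}

#' Enforce pairwise-distinct individuals in a population
#'
#' Any individual identical (as a set) to an earlier one has one randomly
#' chosen feature replaced by a random non-member, with a bounded number of
#' retries.
#'
#' @param population list of character vectors of catalog feature names.
#' @param seed optional RNG seed.
#' @return The population with duplicates perturbed.
#' @export
dedupePopulation <- function(population, seed = NULL) {
    cat <- featureCatalog()
    pop <- lapply(population, function(f) {
        idx <- match(f, cat$name)
        stopifnot2(!anyNA(idx), "unknown feature name(s)")
        sort(idx)
    })
    withSeed(seed, {
        pop <- dedupeIdx(pop, nrow(cat))
        lapply(pop, function(idx) cat$name[idx])
    })
}

#' Cross-validated fitness of a feature subset
#'
#' The GA's ranking criterion: mean over by-subject folds of the per-window
#' squared error (summed over the one-hot outputs) of the ridge-stabilized
#' least-squares linear classifier, trained on the remaining subjects.
#'
#' @param se feature SummarizedExperiment (windows of the design set) with
#'   `colData` columns `subject` and `label`.
#' @param features character vector of row names of `se` to evaluate.
#' @param ridge relative ridge coefficient.
#' @return The mean squared error (lower is better).
#' @export
gaFitness <- function(se, features, ridge = 1e-8) {
    X <- t(SummarizedExperiment::assay(se, "features"))
    cd <- SummarizedExperiment::colData(se)
    fit <- fitnessEvaluator(X, cd$label, as.character(cd$subject), ridge)
    idx <- match(features, colnames(X))
    stopifnot2(!anyNA(idx), "unknown feature name(s)")
    fit(idx)
}

#' Budget-constrained feature selection by genetic algorithm
#'
#' Runs `restarts` independent populations; within each generation:
#' duplicate individuals are perturbed, over-budget individuals repaired,
#' all are ranked by [gaFitness()], the best `survivors` breed the next
#' population by uniform set-crossover of two random parents, and mutation
#' replaces one member feature per individual with probability
#' `mutationProb` -- the generation's best individual is carried over
#' untouched. The best final individual across restarts is returned.
#'
#' @param se design-set feature SummarizedExperiment; row names must be
#'   catalog feature names, `colData` must hold `subject` and `label`.
#' @param config a [gaConfig()].
#' @return A [GAResult-class].
#' @export
selectFeaturesGA <- function(se, config) {
    stopifnot(inherits(config, "gaConfig"))
    X <- t(SummarizedExperiment::assay(se, "features"))
    cd <- SummarizedExperiment::colData(se)
    featNames <- colnames(X)
    nFeat <- length(featNames)
    nopFun <- nopEvaluator(featNames)
    cheapest <- min(vapply(seq_len(nFeat), nopFun, numeric(1)))
    if (cheapest >= config$nmax) {
        stop(sprintf(
            "budget unsatisfiable: cheapest single feature costs %g ops/s (Nmax = %g)",
            cheapest, config$nmax), call. = FALSE)
    }
    fitFun <- fitnessEvaluator(X, cd$label, as.character(cd$subject),
                               config$ridge)
    cache <- new.env(parent = emptyenv())
    evalFit <- function(idx) {
        key <- paste(idx, collapse = ",")
        v <- cache[[key]]
        if (is.null(v)) {
            v <- fitFun(idx)
            cache[[key]] <- v
        }
        v
    }

    P <- config$populationSize; S <- config$survivors
    G <- config$generations
    traj <- matrix(NA_real_, G, config$restarts)
    best <- NULL
    restartSeeds <- childSeeds(config$seed, config$restarts)
    for (r in seq_len(config$restarts)) {
        res <- withSeed(restartSeeds[r], {
            pop <- lapply(seq_len(P), function(i) {
                sort(sample.int(nFeat, sample.int(config$initMaxFeatures, 1L)))
            })
            bestTraj <- numeric(G)
            for (g in seq_len(G)) {
                pop <- dedupeIdx(pop, nFeat)
                pop <- lapply(pop, repairIdx, nmax = config$nmax,
                              nopFun = nopFun, nFeat = nFeat)
                fit <- vapply(pop, evalFit, numeric(1))
                ord <- order(fit)
                bestTraj[g] <- fit[ord[1L]]
                surv <- pop[ord[seq_len(S)]]
                if (g < G) {
                    newPop <- vector("list", P)
                    newPop[[1L]] <- surv[[1L]]  # elite, unaltered
                    for (i in 2:P) {
                        par <- sample.int(S, 2L, replace = TRUE)
                        child <- crossoverIdx(surv[[par[1L]]], surv[[par[2L]]])
                        if (runif(1L) < config$mutationProb) {
                            child <- mutateIdx(child, nFeat)
                        }
                        newPop[[i]] <- child
                    }
                    pop <- newPop
                }
            }
            list(idx = pop[[which.min(vapply(pop, evalFit, numeric(1)))]],
                 traj = bestTraj)
        })
        ## final ranking uses the evaluated population of the last generation
        traj[, r] <- res$traj
        fitR <- evalFit(res$idx)
        if (is.null(best) || fitR < best$fitness) {
            best <- list(idx = res$idx, fitness = fitR)
        }
    }
    new("GAResult",
        features = featNames[best$idx],
        fitness = best$fitness,
        nop = nopFun(best$idx),
        trajectories = traj,
        nmax = as.numeric(config$nmax))
}
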