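## Classifiers: the least-squares linear classifier (also the GA's fitness
## engine) and the 10-unit tan-sigmoid multilayer perceptron with
## early-stopped training.

standardizer <- function(X) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    list(center = ctr, scale = scl)
}
applyStd <- function(X, std) {
    sweep(sweep(X, 2L, std$center, "-"), 2L, std$scale, "/")
}
oneHot <- function(y, levels) {
    Y <- matrix(0, length(y), length(levels),
                dimnames = list(NULL, levels))
    Y[cbind(seq_along(y), match(as.character(y), levels))] <- 1
    Y
}
argmaxDecision <- function(scores, levels) {
    ## ties broken by lowest class index
    factor(levels[apply(scores, 1L, which.max)], levels = levels)
}

#' Least-squares linear classifier
#'
#' Fits weights (with bias) minimizing the squared error between linear
#' outputs and one-hot class targets; a tiny ridge term (`ridge` times the
#' mean diagonal of the normal matrix) stabilizes rank-deficient designs.
#' Features are standardized with training-set mean and variance by default.
#' Prediction decides by the maximal output, ties to the lowest class index.
#'
#' @param X numeric matrix, windows x features.
#' @param y class labels (factor or character).
#' @param ridge relative ridge coefficient.
#' @param standardize standardize columns before fitting.
#' @return An object of class `linearClassifier`.
#' @export
linearFit <- function(X, y, ridge = 1e-8, standardize = TRUE) {
    X <- as.matrix(X)
    y <- factor(y)
    stopifnot2(nlevels(y) >= 2L, "training set holds a single class")
    stopifnot2(nrow(X) >= nlevels(y), "need at least one sample per class")
    std <- if (standardize) standardizer(X) else
        list(center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
    Xs <- cbind(1, applyStd(X, std))
    Y <- oneHot(y, levels(y))
    A <- crossprod(Xs)
    lam <- ridge * mean(diag(A))
    W <- solve(A + diag(lam, ncol(Xs)), crossprod(Xs, Y))
    structure(list(weights = W, levels = levels(y), std = std,
                   features = colnames(X)),
              class = "linearClassifier")
}

#' @rdname linearFit
#' @param fit a `linearClassifier`.
#' @param newX matrix of samples to score.
#' @return `linearPredict()`: a list with `scores` (samples x classes) and
#'   `decision` (factor).
#' @export
linearPredict <- function(fit, newX) {
    newX <- as.matrix(newX)
    stopifnot2(ncol(newX) == length(fit$std$center),
               "feature dimension mismatch")
    scores <- cbind(1, applyStd(newX, fit$std)) %*% fit$weights
    list(scores = scores, decision = argmaxDecision(scores, fit$levels))
}

#' Multilayer-perceptron configuration
#'
#' One hidden layer of `hiddenUnits` tan-sigmoid neurons, linear outputs
#' trained on one-hot targets by quasi-Newton squared-error minimization
#' ([nnet::nnet]). Training is chunked: every `chunkEpochs` optimizer
#' iterations the validation error (on a held-out fraction of *subjects*) is
#' measured; training stops once it has failed to improve for `patience`
#' consecutive checks, and the best-validation weights are kept. The whole
#' process restarts `restarts` times from random weights; the network with
#' the lowest decision error over the full design set wins.
#'
#' @param hiddenUnits hidden-layer size.
#' @param restarts independent trainings from random initial weights.
#' @param validationFraction fraction of subjects held out for early
#'   stopping.
#' @param maxEpochs optimizer iteration budget per restart.
#' @param patience consecutive non-improving validation checks tolerated.
#' @param chunkEpochs iterations between validation checks.
#' @param seed RNG seed for splits and initial weights.
#' @return A list of settings (class `mlpConfig`).
#' @export
mlpConfig <- function(hiddenUnits = 10, restarts = 5,
                      validationFraction = 0.1, maxEpochs = 200,
                      patience = 6, chunkEpochs = 10, seed = NULL) {
    stopifnot2(hiddenUnits >= 1, "'hiddenUnits' must be >= 1")
    stopifnot2(validationFraction > 0 && validationFraction < 1,
               "'validationFraction' must lie in (0, 1)")
    structure(list(hiddenUnits = hiddenUnits, restarts = restarts,
                   validationFraction = validationFraction,
                   maxEpochs = maxEpochs, patience = patience,
                   chunkEpochs = chunkEpochs, seed = seed),
              class = "mlpConfig")
}

mseOf <- function(net, X, Y) {
    P <- predict(net, X)
    mean(rowSums((Y - P)^2))
}

#' Train the MLP classifier
#'
#' @param X numeric matrix, windows x features.
#' @param y class labels.
#' @param subjects subject id per window; the validation split groups by
#'   subject so early stopping measures generalization to unseen people.
#' @param config an [mlpConfig()].
#' @return An object of class `mlpClassifier` holding the winning network,
#'   the standardizer and per-restart validation traces.
#' @export
mlpTrain <- function(X, y, subjects, config = mlpConfig()) {
    X <- as.matrix(X)
    y <- factor(y)
    subjects <- as.character(subjects)
    us <- unique(subjects)
    stopifnot2(length(us) >= 2L,
               "need at least 2 subjects for a by-subject validation split")
    std <- standardizer(X)
    Xs <- applyStd(X, std)
    Y <- oneHot(y, levels(y))
    withSeed(config$seed, {
        nVal <- max(1L, round(config$validationFraction * length(us)))
        nVal <- min(nVal, length(us) - 1L)
        valSubj <- sample(us, nVal)
        isVal <- subjects %in% valSubj
        Xtr <- Xs[!isVal, , drop = FALSE]; Ytr <- Y[!isVal, , drop = FALSE]
        Xva <- Xs[isVal, , drop = FALSE]; Yva <- Y[isVal, , drop = FALSE]

        best <- NULL
        traces <- vector("list", config$restarts)
        for (r in seq_len(config$restarts)) {
            net <- NULL
            bestVal <- Inf; bestNet <- NULL; bad <- 0L
            epochs <- 0L; trace <- numeric(0)
            while (epochs < config$maxEpochs) {
                args <- list(x = Xtr, y = Ytr, size = config$hiddenUnits,
                             linout = TRUE, trace = FALSE,
                             maxit = config$chunkEpochs, MaxNWts = 100000L)
                if (!is.null(net)) args$Wts <- net$wts
                net <- do.call(nnet::nnet, args)
                epochs <- epochs + config$chunkEpochs
                v <- mseOf(net, Xva, Yva)
                trace <- c(trace, v)
                if (v < bestVal - 1e-12) {
                    bestVal <- v; bestNet <- net; bad <- 0L
                } else {
                    bad <- bad + 1L
                    if (bad >= config$patience) break
                }
            }
            traces[[r]] <- trace
            designErr <- mean(argmaxDecision(predict(bestNet, Xs),
                                             levels(y)) != y)
            if (is.null(best) || designErr < best$designErr) {
                best <- list(net = bestNet, designErr = designErr,
                             valMse = bestVal)
            }
        }
        structure(list(net = best$net, levels = levels(y), std = std,
                       designErr = best$designErr, valMse = best$valMse,
                       valTraces = traces, config = config,
                       valSubjects = valSubj),
                  class = "mlpClassifier")
    })
}

#' Score new windows with a trained MLP
#'
#' @param model an `mlpClassifier` from [mlpTrain()].
#' @param newX matrix of samples (same feature dimension as training).
#' @return A list with `scores` and the argmax `decision` (ties to the
#'   lowest class index).
#' @export
mlpPredict <- function(model, newX) {
    newX <- as.matrix(newX)
    stopifnot2(ncol(newX) == length(model$std$center),
               "feature dimension mismatch")
    scores <- predict(model$net, applyStd(newX, model$std))
    list(scores = scores, decision = argmaxDecision(scores, model$levels))
}
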