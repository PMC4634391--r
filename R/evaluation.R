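## Leave-one-subject-out harness, confusion-matrix error metrics and the
## budget sweep.

#' Leave-one-subject-out folds
#'
#' One fold per subject: the fold's test set is exactly that subject's
#' windows, the design set everything else. Subjects with zero windows
#' cannot occur in a feature SummarizedExperiment; a factor level without
#' windows is simply absent.
#'
#' @param se feature SummarizedExperiment with `colData$subject`.
#' @return A list of folds, each a list with `subject`, `design` and `test`
#'   (column indices).
#' @export
losoSplit <- function(se) {
    subj <- as.character(SummarizedExperiment::colData(se)$subject)
    us <- unique(subj)
    stopifnot2(length(us) >= 2L, "need at least 2 subjects")
    lapply(us, function(s) {
        list(subject = s,
             design = which(subj != s),
             test = which(subj == s))
    })
}

#' Per-class and average error probabilities of a confusion matrix
#'
#' Rows are true classes. The per-class error is the off-diagonal row sum
#' divided by the row sum, in percent; the average is the *unweighted* mean
#' over classes. A class with no samples (zero row) is excluded with a
#' warning.
#'
#' @param confusion square numeric matrix of counts.
#' @return A list with `perClass` (named percents) and `average`.
#' @examples
#' errorMetrics(diag(5, 3))$average  # 0
#' @export
errorMetrics <- function(confusion) {
    confusion <- as.matrix(confusion)
    stopifnot2(nrow(confusion) == ncol(confusion),
               "confusion matrix must be square")
    stopifnot2(all(confusion >= 0), "counts must be non-negative")
    rs <- rowSums(confusion)
    if (any(rs == 0)) {
        warning("class(es) without samples excluded from the average: ",
                paste(rownames(confusion)[rs == 0], collapse = ", "))
    }
    ok <- rs > 0
    perClass <- rep(NA_real_, nrow(confusion))
    perClass[ok] <- 100 * (rs[ok] - diag(confusion)[ok]) / rs[ok]
    names(perClass) <- rownames(confusion)
    list(perClass = perClass, average = mean(perClass[ok]))
}

#' Full leave-one-subject-out analysis
#'
#' For every fold: the genetic algorithm selects a feature subset on the
#' design set under the budget, the classifier is trained on the design set
#' (the MLP with its by-subject validation split and restarts) and evaluated
#' on the held-out subject. Confusion counts are pooled over folds. Windows
#' with a missing value in any catalog feature are dropped up front.
#'
#' @param se pooled feature SummarizedExperiment (see [cohortFeatures()]).
#' @param gaCfg a [gaConfig()] carrying the budget `nmax`.
#' @param mlpCfg an [mlpConfig()]; ignored for the linear classifier.
#' @param classifier `"mlp"` or `"linear"`.
#' @param seed RNG seed for the whole analysis.
#' @param analysis free-form description stored in the result.
#' @return A [CVResult-class].
#' @export
runAnalysis <- function(se, gaCfg, mlpCfg = mlpConfig(),
                        classifier = c("mlp", "linear"), seed = NULL,
                        analysis = "LOSO") {
    classifier <- match.arg(classifier)
    A <- SummarizedExperiment::assay(se, "features")
    complete <- colSums(is.na(A)) == 0L
    if (!all(complete)) {
        message(sum(!complete), " window(s) with missing features dropped")
        se <- se[, complete]
        A <- A[, complete, drop = FALSE]
    }
    cd <- SummarizedExperiment::colData(se)
    y <- factor(as.character(cd$label))
    subj <- as.character(cd$subject)
    classes <- levels(y)
    M <- length(classes)
    conf <- matrix(0L, M, M, dimnames = list(true = classes, pred = classes))
    folds <- losoSplit(se)
    foldSeeds <- childSeeds(seed, 2L * length(folds))
    foldInfo <- vector("list", length(folds))
    X <- t(A)
    for (i in seq_along(folds)) {
        f <- folds[[i]]
        gaCfgF <- gaCfg; gaCfgF$seed <- foldSeeds[2L * i - 1L]
        sel <- selectFeaturesGA(se[, f$design], gaCfgF)
        feats <- selectedFeatures(sel)
        Xd <- X[f$design, feats, drop = FALSE]
        Xt <- X[f$test, feats, drop = FALSE]
        yd <- y[f$design]
        pred <- if (classifier == "mlp") {
            cfg <- mlpCfg; cfg$seed <- foldSeeds[2L * i]
            m <- mlpTrain(Xd, yd, subj[f$design], cfg)
            mlpPredict(m, Xt)$decision
        } else {
            m <- linearFit(Xd, yd)
            linearPredict(m, Xt)$decision
        }
        truth <- factor(as.character(y[f$test]), levels = classes)
        conf <- conf + unclass(table(truth, factor(pred, levels = classes)))
        foldInfo[[i]] <- list(subject = f$subject, features = feats,
                              nop = sel@nop,
                              testError = mean(pred != truth))
    }
    em <- errorMetrics(conf)
    new("CVResult", confusion = conf, perClassError = em$perClass,
        averageError = em$average, folds = foldInfo, analysis = analysis)
}

#' Error versus computational budget
#'
#' Repeats [runAnalysis()] over a grid of budgets, reporting the
#' distribution of average error per budget (quartiles for box-plot-style
#' summaries). The study-scale grid is 20,000 to 200,000 ops/s in steps of
#' 20,000 with 100 repetitions; the defaults here are meant to be scaled to
#' the problem at hand via `repetitions` and the GA settings in `gaCfg`.
#'
#' @param se pooled feature SummarizedExperiment.
#' @param nmaxValues numeric vector of budgets.
#' @param repetitions analyses per budget (different seeds).
#' @param gaCfg,mlpCfg,classifier passed to [runAnalysis()] (the `nmax` in
#'   `gaCfg` is overridden by each grid value).
#' @param seed master seed.
#' @return A list with `runs` (data.frame of nmax, rep, averageError) and
#'   `summary` (per-budget quartiles).
#' @export
nmaxSweep <- function(se, nmaxValues = seq(20000, 200000, by = 20000),
                      repetitions = 1, gaCfg, mlpCfg = mlpConfig(),
                      classifier = "linear", seed = NULL) {
    stopifnot2(repetitions >= 1, "'repetitions' must be at least 1")
    seeds <- childSeeds(seed, length(nmaxValues) * repetitions)
    runs <- expand.grid(rep = seq_len(repetitions), nmax = nmaxValues)
    runs$averageError <- NA_real_
    for (i in seq_len(nrow(runs))) {
        cfg <- gaCfg
        cfg$nmax <- runs$nmax[i]
        res <- runAnalysis(se, cfg, mlpCfg, classifier = classifier,
                           seed = seeds[i])
        runs$averageError[i] <- averageError(res)
    }
    qs <- do.call(rbind, lapply(split(runs$averageError, runs$nmax), quantile,
                                probs = c(0.25, 0.5, 0.75), names = FALSE))
    summary <- data.frame(nmax = as.numeric(rownames(qs)),
                          q25 = qs[, 1L], median = qs[, 2L], q75 = qs[, 3L],
                          row.names = NULL)
    list(runs = runs[, c("nmax", "rep", "averageError")], summary = summary)
}
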