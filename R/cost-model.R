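## Operations-per-second cost model: per-stage filter costs computed from the
## stated rules, fixed block constants, and shared-stage / shared-sort
## accounting over the dependency closure of a feature subset.

## processing-block constants (operations per second)
BLOCK_COSTS <- c(
    ECG.DEC = 3750,   # FE1 decimation to the intermediate rate
    ECG.BPM = 9050,   # respiration cycle detection + interpolation
    ECG.PPM = 8800,   # beat detection on the wideband branch
    TEB.DEC = 900,
    TEB.BPM = 2116,
    TEB.PPM = 2116    # TEB pulse rate reuses the cycle detector
)
SORT_COST <- 27580
SORT_INCREMENT <- c(trimmed_mean_25 = 225, median = 0, p25 = 0, p75 = 0)

#' Operations-per-second cost of a filter stage
#'
#' Plain FIR stages cost `order * fs` multiply-accumulates per second; an
#' IFIR stage runs its `order`-tap prototype on the stretch-decimated grid
#' and therefore costs `order * fs / stretch`.
#'
#' @param spec a [FilterSpec-class].
#' @return Operations per second (numeric scalar).
#' @examples
#' stageCost(filterSpec("fir_lowpass", 100, 0.5, fs = 250))            # 25000
#' stageCost(filterSpec("ifir_lowpass", 1150, 0.1, 250, stretch = 25)) # 11500
#' @export
stageCost <- function(spec) {
    stopifnot(is(spec, "FilterSpec"))
    if (spec@kind == "fir_lowpass") {
        spec@order * spec@fs
    } else {
        spec@order * spec@fs / spec@stretch
    }
}

## per-signal processing stages with their costs; filter stages are computed
## from the rules, never stored as literals
signalStages <- function() {
    e <- ecgFilterSpecs()
    z <- tebFilterSpecs()
    st <- c(
        ECG.LF = stageCost(e$lf), ECG.MF = stageCost(e$mf),
        ECG.CF = stageCost(e$cf), ECG.RF = stageCost(e$rf),
        TEB.LF = stageCost(z$lf), TEB.CF = stageCost(z$cf),
        TEB.RF = stageCost(z$rf), TEB.PULSE = stageCost(z$pulse),
        BLOCK_COSTS
    )
    deps <- list(
        ECF  = c("ECG.LF", "ECG.CF", "ECG.DEC"),
        ERT  = c("ECG.LF", "ECG.RF", "ECG.BPM"),
        ERD  = c("ECG.LF", "ECG.RF", "ECG.BPM"),
        EPPM = c("ECG.MF", "ECG.PPM"),
        ZCF  = c("TEB.LF", "TEB.CF", "TEB.DEC"),
        ZRT  = c("TEB.LF", "TEB.RF", "TEB.BPM"),
        ZRD  = c("TEB.LF", "TEB.RF", "TEB.BPM"),
        ZPPM = c("TEB.LF", "TEB.PULSE", "TEB.PPM")
    )
    list(costs = st, deps = deps)
}

#' Total operations per second of a feature subset
#'
#' Sums (i) the cost of every processing stage in the dependency closure of
#' the selected features, each counted once however many features share it;
#' (ii) the per-parameter costs, where rank-based statistics of the same
#' signal share a single sort (counted once, plus the per-parameter
#' increment over the shared sort: 225 for the trimmed mean, 0 for median
#' and percentiles).
#'
#' @param selection character vector of feature names from
#'   [featureCatalog()].
#' @param itemize return a per-item breakdown instead of the total.
#' @return Total operations per second, or (with `itemize = TRUE`) a list
#'   with `stages`, `parameters`, `sorts` and `total`.
#' @examples
#' totalNop(character(0))        # 0
#' totalNop("ECG.ECF.mean")      # 25000 + 11500 + 3750 + 300
#' @export
totalNop <- function(selection, itemize = FALSE) {
    if (length(selection) == 0L) {
        return(if (itemize) list(stages = numeric(0), parameters = numeric(0),
                                 sorts = numeric(0), total = 0) else 0)
    }
    cat <- featureCatalog()
    idx <- match(selection, cat$name)
    stopifnot2(!anyNA(idx),
               paste("unknown feature(s):",
                     paste(selection[is.na(idx)], collapse = ", ")))
    sel <- cat[idx, , drop = FALSE]
    sg <- signalStages()
    stageNames <- unique(unlist(sg$deps[unique(sel$signal)], use.names = FALSE))
    stages <- sg$costs[stageNames]
    nonSort <- !sel$sortBased
    params <- setNames(sel$paramCost[nonSort], sel$name[nonSort])
    sorts <- numeric(0)
    for (s in unique(sel$signal[sel$sortBased])) {
        inc <- sum(SORT_INCREMENT[sel$parameter[sel$sortBased & sel$signal == s]])
        sorts[paste0("sort.", s)] <- SORT_COST + inc
    }
    total <- sum(stages) + sum(params) + sum(sorts)
    if (itemize) list(stages = stages, parameters = params, sorts = sorts,
                      total = total)
    else total
}

#' Does a feature subset fit the computational budget?
#'
#' The constraint is the strict inequality `Nop < Nmax`.
#'
#' @param selection feature names.
#' @param nmax budget, operations per second.
#' @return `TRUE` if `totalNop(selection) < nmax`.
#' @examples
#' checkBudget("ECG.ECF.mean", nmax = 40551)  # TRUE
#' checkBudget("ECG.ECF.mean", nmax = 40550)  # FALSE
#' @export
checkBudget <- function(selection, nmax) {
    totalNop(selection) < nmax
}
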