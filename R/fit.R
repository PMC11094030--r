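#' Chi-square distance between model and data curves
#'
#' chi^2 = sum_i (model_i - data_i)^2 / sem_i^2, the objective minimized
#' during parameter fitting: squared residuals weighted by the measured
#' per-timepoint experimental errors.
#'
#' @param modelCurve,dataCurve numeric vectors on a common time grid.
#' @param sem per-timepoint standard errors (no zeros; floor small values
#'   before calling).
#' @return chi-square scalar.
#' @export
chi2Objective <- function(modelCurve, dataCurve, sem) {
  if (length(modelCurve) != length(dataCurve) ||
      length(dataCurve) != length(sem))
    stop("curves and sem must share one time grid")
  if (any(sem == 0))
    stop("sem contains zeros; apply a floor (e.g. pmax(sem, eps)) first")
  sum((modelCurve - dataCurve)^2 / sem^2)
}

#' Genetic-algorithm minimization over box-constrained parameters
#'
#' Real-coded GA with tournament selection, two-point crossover,
#' Gaussian mutation and elitism. Parameters spanning decades (rate
#' constants) are searched on a log10 scale when \code{logScale} is TRUE
#' for that parameter. Fully reproducible given \code{seed}.
#'
#' @param objective function taking a named numeric vector and returning
#'   the scalar to minimize.
#' @param ranges named list of numeric(2) lower/upper bounds (all
#'   non-degenerate).
#' @param popSize population size.
#' @param generations number of generations.
#' @param pCrossover two-point crossover probability.
#' @param pMutation per-gene mutation probability.
#' @param mutSd initial mutation sd as a fraction of each (transformed)
#'   range; annealed tenfold over the run so late generations refine
#'   rather than explore.
#' @param elite number of elites copied unchanged each generation.
#' @param tournament tournament size.
#' @param logScale logical, recycled over parameters: search that
#'   dimension in log10 space.
#' @param seed integer seed (required).
#' @return list: \code{par} (named best parameters), \code{value} (best
#'   objective), \code{trace} (best value per generation),
#'   \code{evaluations}.
#' @export
fitGA <- function(objective, ranges, popSize = 50, generations = 100,
                  pCrossover = 0.6, pMutation = 0.2, mutSd = 0.1,
                  elite = 2, tournament = 3, logScale = FALSE,
                  seed = NULL) {
  if (is.null(seed)) stop("seed is required")
  np <- length(ranges)
  lo <- vapply(ranges, `[`, numeric(1), 1)
  hi <- vapply(ranges, `[`, numeric(1), 2)
  if (any(hi <= lo)) stop("ranges must be non-degenerate (lo < hi)")
  logScale <- rep_len(logScale, np)
  if (any(logScale & lo <= 0))
    stop("log-scale search requires positive lower bounds")
  tlo <- ifelse(logScale, log10(lo), lo)
  thi <- ifelse(logScale, log10(hi), hi)
  back <- function(x) {
    v <- ifelse(logScale, 10^x, x)
    names(v) <- names(ranges)
    v
  }
  set.seed(seed)
  pop <- matrix(stats::runif(popSize * np, tlo, thi), popSize, np,
                byrow = TRUE)
  evalPop <- function(p) apply(p, 1, function(row) objective(back(row)))
  fit <- evalPop(pop)
  evals <- popSize
  trace <- numeric(generations)
  for (gen in seq_len(generations)) {
    ord <- order(fit)
    newPop <- pop[ord[seq_len(elite)], , drop = FALSE]
    while (nrow(newPop) < popSize) {
      pick <- function() {
        cand <- sample.int(popSize, tournament)
        cand[which.min(fit[cand])]
      }
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      if (stats::runif(1) < pCrossover && np >= 2) {
        cut <- sort(sample.int(np + 1, 2) - 1L)
        if (cut[1] < cut[2]) {
          seg <- (cut[1] + 1):cut[2]
          tmp <- p1[seg]; p1[seg] <- p2[seg]; p2[seg] <- tmp
        }
      }
      sdNow <- mutSd * 10^(-(gen - 1) / max(generations - 1, 1))
      mutate <- function(p) {
        hitGenes <- stats::runif(np) < pMutation
        if (any(hitGenes)) {
          k <- which(hitGenes)
          p[k] <- p[k] + stats::rnorm(length(k), 0, sdNow * (thi[k] - tlo[k]))
          p[k] <- pmin(pmax(p[k], tlo[k]), thi[k])
        }
        p
      }
      newPop <- rbind(newPop, mutate(p1))
      if (nrow(newPop) < popSize) newPop <- rbind(newPop, mutate(p2))
    }
    pop <- newPop
    fit <- evalPop(pop)
    evals <- evals + popSize
    trace[gen] <- min(fit)
  }
  best <- which.min(fit)
  list(par = back(pop[best, ]), value = fit[best], trace = trace,
       evaluations = evals)
}

#' Build a chi-square objective over model rate parameters
#'
#' Returns a closure mapping a named parameter vector (any of
#' \code{kMem}, \code{kDyn}, \code{kFrev}, \code{kB}, \code{dSol},
#' \code{dMem}) onto the chi-square distance between the simulated
#' observable and a target curve. Used together with \code{\link{fitGA}}
#' to recover rate constants from cluster-growth data.
#'
#' @param model a \code{dynaminModel} providing the fixed components.
#' @param data list with \code{times}, \code{values} and \code{sem}
#'   (target curve on its own grid).
#' @param observable \code{"dynCopies"}, \code{"relDensity"} or a
#'   function(series) returning a numeric vector on \code{data$times}.
#' @return function(par) -> chi-square.
#' @export
makeModelObjective <- function(model, data,
                               observable = c("dynCopies", "relDensity")) {
  obsFun <- if (is.function(observable)) observable else {
    observable <- match.arg(observable)
    function(series) observables(series)[[observable]]
  }
  function(par) {
    init <- model$init
    rates <- model$rates
    for (nm in names(par)) {
      if (nm %in% c("dSol", "dMem")) init[[nm]] <- par[[nm]]
      else rates[[nm]] <- par[[nm]]
    }
    series <- try(simulateODE(init = init, rates = rates,
                              geometry = model$geometry,
                              times = data$times,
                              tEnd = max(data$times)), silent = TRUE)
    if (inherits(series, "try-error")) return(1e12)
    chi2Objective(obsFun(series), data$values, data$sem)
  }
}
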