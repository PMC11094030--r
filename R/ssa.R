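#' Stochastic (Gillespie) simulation of the recruitment network
#'
#' Exact stochastic simulation of the seven reactions in copy numbers.
#' Initial copies are obtained from the densities via the geometry
#' (membrane species over the patch area, cluster species over the
#' cluster disk, solution over the volume) and rounded to integers.
#' Bimolecular 3D propensity constants are k/(602.214 V) per pair per
#' second; purely-2D reactions carry the additional DF factor,
#' i.e. k/(602.214 A h). Dynamin-dynamin binding is booked per site:
#' each activated dynamin exposes \code{valence} independent sites
#' reacting at kDyn/valence, so the total propensity equals the
#' mass-action one while permitting the oligomer interpretation. An
#' optional titration/degradation pair (0th-order supply, 1st-order
#' decay) holds the solution pool near its initial concentration so that
#' a truncated solution volume does not deplete; without it the total
#' dynamin copy number is conserved exactly.
#'
#' @param model a \code{dynaminModel}; or supply \code{init},
#'   \code{rates}, \code{geometry}.
#' @param tEnd end time, seconds.
#' @param seed integer seed (required).
#' @param recordTimes times at which the state is recorded (default 81
#'   points over [0, tEnd]).
#' @param valence dynamin-dynamin binding sites per molecule.
#' @param titration \code{NULL} (off) or numeric(2): 0th-order supply
#'   rate (uM/s) and 1st-order degradation rate (1/s) for the solution
#'   pool, e.g. \code{c(100, 10)}.
#' @param maxEvents hard cap on simulated events.
#' @param init,rates,geometry optional overrides.
#' @return list: \code{times}, \code{copies} (matrix time x species,
#'   absolute copy numbers), \code{events} (number of reactions fired),
#'   \code{geometry}.
#' @export
simulateSSA <- function(model = NULL, tEnd = 4, seed = NULL,
                        recordTimes = NULL, valence = 4, titration = NULL,
                        maxEvents = 1e7,
                        init = NULL, rates = NULL, geometry = NULL) {
  if (is.null(seed)) stop("seed is required")
  if (!is.null(model)) {
    if (is.null(init)) init <- model$init
    if (is.null(rates)) rates <- model$rates
    if (is.null(geometry)) geometry <- model$geometry
  }
  set.seed(seed)
  rates <- .normRates(rates)
  g <- geometry
  if (is.null(recordTimes)) recordTimes <- seq(0, tEnd, length.out = 81)
  nV <- .AVOGADRO_UM * g@volume       # copies per uM
  n <- c(Dsol = round(init$dSol * nV),
         Rmem = round(init$rMem * g@area),
         Aclus = round(init$aClus * g@clusterArea),
         Dmem = round(init$dMem * g@area),
         Dclus = round(init$dClus * g@clusterArea),
         D2dclus = round(init$d2dclus * g@clusterArea))
  c3 <- function(k) k / nV            # 3D bimolecular, per pair per s
  c2 <- function(k) k * g@df / nV     # purely-2D bimolecular
  kDynSite <- rates$kDyn / valence
  useTitration <- !is.null(titration)
  if (useTitration) {
    aSupply <- titration[1] * nV      # copies/s
    kDeg <- titration[2]
  }
  nRec <- length(recordTimes)
  copies <- matrix(NA_real_, nRec, 6, dimnames = list(NULL, .SPECIES))
  # per-site bookkeeping: valence sites at kDyn/valence == mass action
  cKin <- c(c3(rates$kFrev), rates$kB, c2(rates$kMem2D), c3(rates$kMem),
            c2(rates$kDyn2D / valence) * valence, c3(kDynSite) * valence,
            c2(rates$kDyn2D / valence) * valence, c3(kDynSite) * valence)
  # stoichiometry: reactions x species (Dsol Rmem Aclus Dmem Dclus D2dclus)
  stoich <- rbind(
    c(-1, -1, 0, +1, 0, 0),   # 1f: Dsol + Rmem -> Dmem
    c(+1, +1, 0, -1, 0, 0),   # 1b
    c(0, 0, -1, -1, 0, +1),   # 2: Dmem + Aclus -> D2dclus
    c(-1, 0, -1, 0, +1, 0),   # 3: Dsol + Aclus -> Dclus
    c(0, 0, 0, -1, 0, +1),    # 4: Dmem + D2dclus -> 2 D2dclus
    c(-1, 0, 0, 0, +1, 0),    # 5: Dsol + Dclus -> 2 Dclus
    c(0, 0, 0, -1, 0, +1),    # 6: Dmem + Dclus -> D2dclus + Dclus
    c(-1, 0, 0, 0, +1, 0),    # 7: Dsol + D2dclus -> Dclus + D2dclus
    c(+1, 0, 0, 0, 0, 0),     # titration supply
    c(-1, 0, 0, 0, 0, 0))     # titration degradation
  nReact <- if (useTitration) 10L else 8L
  n <- unname(n)
  a <- numeric(nReact)
  iRec <- 1L
  t <- 0
  events <- 0L
  repeat {
    a[1] <- cKin[1] * n[1] * n[2]
    a[2] <- cKin[2] * n[4]
    a[3] <- cKin[3] * n[4] * n[3]
    a[4] <- cKin[4] * n[1] * n[3]
    a[5] <- cKin[5] * n[4] * n[6]
    a[6] <- cKin[6] * n[1] * n[5]
    a[7] <- cKin[7] * n[4] * n[5]
    a[8] <- cKin[8] * n[1] * n[6]
    if (useTitration) { a[9] <- aSupply; a[10] <- kDeg * n[1] }
    a0 <- sum(a)
    if (!is.finite(a0)) stop("propensity overflow")
    tNext <- if (a0 > 0) t + stats::rexp(1, a0) else Inf
    while (iRec <= nRec && recordTimes[iRec] <= min(tNext, tEnd)) {
      copies[iRec, ] <- n
      iRec <- iRec + 1L
    }
    if (tNext > tEnd || a0 == 0) break
    t <- tNext
    u <- stats::runif(1) * a0
    j <- 1L; s <- a[1]
    while (s < u && j < nReact) { j <- j + 1L; s <- s + a[j] }
    n <- n + stoich[j, ]
    events <- events + 1L
    if (events >= maxEvents) stop("maxEvents reached at t = ", format(t))
  }
  while (iRec <= nRec) { copies[iRec, ] <- n; iRec <- iRec + 1L }
  list(times = recordTimes, copies = copies, events = events, geometry = g)
}

#' Cluster-localized dynamin copies from an SSA run
#'
#' Same bookkeeping as \code{\link{observables}}: all cluster-species
#' copies plus the fraction of membrane-species copies expected within
#' the cluster disk (area ratio).
#'
#' @param ssa result of \code{\link{simulateSSA}}.
#' @return numeric vector of copies per recorded time.
#' @export
ssaDynCopies <- function(ssa) {
  g <- ssa$geometry
  ssa$copies[, "Dclus"] + ssa$copies[, "D2dclus"] +
    ssa$copies[, "Dmem"] * g@clusterArea / g@area
}
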