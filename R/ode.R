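# fill in the optional purely-2D rate constants (reactions 2, 4, 6);
# they default to their 3D counterparts, i.e. k^2D = k/h realized through
# the DF scaling, but can be set independently (e.g. to 0 to switch the
# lateral recruitment channels off)
.normRates <- function(rates) {
  if (is.null(rates$kMem2D)) rates$kMem2D <- rates$kMem
  if (is.null(rates$kDyn2D)) rates$kDyn2D <- rates$kDyn
  rates
}

# reaction rates (uM/s) for the 7-reaction network in the uM
# representation; purely-2D reactions (2, 4, 6) carry the dimensionality
# factor DF = V/(A h)
.reactionRatesUM <- function(y, rates, df) {
  with(as.list(c(y, rates)), {
    c(r1f = kFrev * Dsol * Rmem,
      r1b = kB * Dmem,
      r2 = df * kMem2D * Dmem * Aclus,
      r3 = kMem * Dsol * Aclus,
      r4 = df * kDyn2D * Dmem * D2dclus,
      r5 = kDyn * Dsol * Dclus,
      r6 = df * kDyn2D * Dmem * Dclus,
      r7 = kDyn * Dsol * D2dclus)
  })
}

# stoichiometry: species x reactions
.STOICH <- local({
  s <- matrix(0, 6, 8, dimnames = list(
    c("Dsol", "Rmem", "Aclus", "Dmem", "Dclus", "D2dclus"),
    c("r1f", "r1b", "r2", "r3", "r4", "r5", "r7", "r6")))
  s[, "r1f"] <- c(-1, -1, 0, +1, 0, 0)   # Dsol + Rmem -> Dmem
  s[, "r1b"] <- c(+1, +1, 0, -1, 0, 0)   # Dmem -> Dsol + Rmem
  s[, "r2"]  <- c(0, 0, -1, -1, 0, +1)   # Dmem + Aclus -> D2dclus
  s[, "r3"]  <- c(-1, 0, -1, 0, +1, 0)   # Dsol + Aclus -> Dclus
  s[, "r4"]  <- c(0, 0, 0, -1, 0, +1)    # Dmem + D2dclus -> 2 D2dclus
  s[, "r5"]  <- c(-1, 0, 0, 0, +1, 0)    # Dsol + Dclus -> 2 Dclus
  s[, "r6"]  <- c(0, 0, 0, -1, 0, +1)    # Dmem + Dclus -> D2dclus + Dclus
  s[, "r7"]  <- c(-1, 0, 0, 0, +1, 0)    # Dsol + D2dclus -> Dclus + D2dclus
  s[, c("r1f", "r1b", "r2", "r3", "r4", "r5", "r6", "r7")]
})

.odeRhs <- function(t, y, parms) {
  r <- .reactionRatesUM(y, parms$rates, parms$df)
  list(as.numeric(.STOICH[, names(r)] %*% r))
}

#' Deterministic (ODE) simulation of the recruitment network
#'
#' Integrates the seven-reaction network with all six species expressed
#' as volume concentrations (uM): surface densities are converted to
#' copies over their own area (membrane patch for Rmem/Dmem, cluster disk
#' for Aclus/Dclus/D2dclus) and then to concentrations via the system
#' volume; the three purely-2D reactions are multiplied by
#' DF = V/(A h). A stiff-capable integrator (lsoda) is used with tight
#' default tolerances.
#'
#' @param model a \code{dynaminModel} (see \code{\link{dynaminModel}});
#'   alternatively supply \code{init}, \code{rates}, \code{geometry}.
#' @param tEnd end time, seconds.
#' @param times output times (default 401 points over [0, tEnd]).
#' @param atol,rtol absolute/relative solver tolerances.
#' @param init,rates,geometry optional overrides of the model components.
#' @return a \code{\link{StateTimeSeries}} (concentrations in uM).
#' @export
simulateODE <- function(model = NULL, tEnd = 4, times = NULL,
                        atol = 1e-9, rtol = 1e-7,
                        init = NULL, rates = NULL, geometry = NULL) {
  if (!is.null(model)) {
    if (is.null(init)) init <- model$init
    if (is.null(rates)) rates <- model$rates
    if (is.null(geometry)) geometry <- model$geometry
  }
  if (is.null(times)) times <- seq(0, tEnd, length.out = 401)
  rates <- .normRates(rates)
  y0 <- .initialStateUM(init, geometry)
  sol <- deSolve::lsoda(y0, times, .odeRhs,
                        parms = list(rates = rates, df = geometry@df),
                        atol = atol, rtol = rtol)
  states <- as.matrix(sol[, .SPECIES, drop = FALSE])
  if (min(states) < -atol * 1e3)
    stop("negative state beyond tolerance; integration failed (min = ",
         format(min(states)), ")")
  states[states < 0] <- 0
  methods::new("StateTimeSeries", times = as.numeric(sol[, "time"]),
               states = states, geometry = geometry, rates = rates,
               solver = list(method = "lsoda", atol = atol, rtol = rtol))
}

#' Cluster-growth observables of a simulated time series
#'
#' RelDensity(t) = ([D]mem + [D]clus + [D]2dclus)(t) / [D]mem(0) -- the
#' relative increase in dynamin density within the cluster footprint
#' (equal-density initialization makes the per-area and per-volume forms
#' agree). DynCopies(t) is the absolute dynamin copy number localized to
#' the cluster disk: cluster-species copies plus the membrane-species
#' copies lying within the disk (density over the patch times the disk
#' area). fraction2D(t) = [D]2dclus / ([D]clus + [D]2dclus) is the share
#' of cluster dynamin that arrived laterally from the membrane (defined
#' as 0 while the cluster is empty).
#'
#' @param series a \code{\link{StateTimeSeries}}.
#' @return data.frame: \code{time}, \code{relDensity}, \code{dynCopies},
#'   \code{fraction2D}.
#' @export
observables <- function(series) {
  st <- series@states
  g <- series@geometry
  if (st[1, "Dmem"] <= 0) stop("[D]mem(0) must be positive")
  relDensity <- (st[, "Dmem"] + st[, "Dclus"] + st[, "D2dclus"]) / st[1, "Dmem"]
  dens <- .statesToDensities(st, g)
  dynCopies <- (dens[, "Dmem"] + dens[, "Dclus"] + dens[, "D2dclus"]) *
    g@clusterArea
  tot2d <- st[, "Dclus"] + st[, "D2dclus"]
  fraction2D <- ifelse(tot2d > 0, st[, "D2dclus"] / tot2d, 0)
  data.frame(time = series@times, relDensity = unname(relDensity),
             dynCopies = unname(dynCopies), fraction2D = unname(fraction2D))
}

#' Relative intensity of an experimental trace with background offset
#'
#' RelIntensity(t) = (I(t) - delta) / (I(0) - delta), the normalization
#' the model is fitted against; delta is a background offset.
#'
#' @param trace data.frame with columns \code{time}, \code{fi}.
#' @param delta background offset (must be < I(0)).
#' @return data.frame: \code{time}, \code{relIntensity}.
#' @export
relIntensity <- function(trace, delta = 0) {
  i0 <- trace$fi[1]
  if (i0 <= delta) stop("offset delta must be smaller than I(0)")
  data.frame(time = trace$time,
             relIntensity = (trace$fi - delta) / (i0 - delta))
}

#' Choose the background offset matching a target fold increase
#'
#' Solves for delta such that the peak relative intensity equals
#' \code{foldTarget} (the fold increase measured independently from
#' single-particle track counts). The peak relative intensity
#' (P - delta)/(I0 - delta) is monotone increasing in delta for
#' delta < I0, giving the closed form
#' delta = (foldTarget * I0 - P) / (foldTarget - 1).
#'
#' @param trace data.frame with columns \code{time}, \code{fi}.
#' @param foldTarget desired peak relative intensity (> raw fold
#'   max(fi)/fi(1), else the target is unreachable and an error is
#'   raised).
#' @return delta.
#' @export
chooseOffset <- function(trace, foldTarget) {
  i0 <- trace$fi[1]
  p <- max(trace$fi)
  if (foldTarget <= p / i0)
    stop("foldTarget must exceed the raw fold ", format(p / i0))
  (foldTarget * i0 - p) / (foldTarget - 1)
}
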