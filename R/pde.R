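#' Reduced spatial (membrane PDE + well-mixed bath) simulation
#'
#' Simulates the recruitment network on an L x L periodic membrane grid.
#' Membrane species (Rmem, Dmem) diffuse at \code{dMem}; cluster species
#' (Aclus, Dclus, D2dclus) are confined to the central disk of radius
#' \code{geometry@clusterRadius} and do not diffuse; the solution pool is
#' a single well-mixed bath of volume V coupled to every surface cell
#' (solution diffusion, ~7 um^2/s, equilibrates the ~1.9 um column two
#' orders of magnitude faster than membrane transport, so the full 3D
#' solution profile is reduced to its mean). Reactions are integrated
#' cellwise with a midpoint (RK2) step; diffusion with unconditionally
#' stable implicit Euler via a pre-factorized sparse periodic Laplacian.
#' The activator is normalized so its total copy number matches the
#' requested density times the exact disk area despite the discrete mask.
#'
#' @param model a \code{dynaminModel}; or supply \code{init},
#'   \code{rates}, \code{geometry}.
#' @param tEnd end time, seconds.
#' @param dMem membrane diffusion coefficient, um^2/s (measured values
#'   0.045 or 0.02).
#' @param grid target cell side, um (default 0.015; adjusted so an
#'   integer number of cells tiles the domain). Must resolve the cluster
#'   disk with at least 5 cells across.
#' @param dt time step, seconds (capped at \code{maxDt}).
#' @param maxDt maximum admissible time step, seconds.
#' @param recordTimes times at which domain totals are recorded.
#' @param recruiterInCluster initialize the free recruiter inside the
#'   cluster disk as well (keeps the initial condition identical to the
#'   well-mixed ODE); \code{FALSE} restricts it to outside the disk.
#' @param initFields optional named list of nx-by-nx density matrices
#'   (any of Rmem, Dmem, Aclus, Dclus, D2dclus) overriding the uniform
#'   initial fields, e.g. to study pure diffusion of a localized bump.
#' @param init,rates,geometry optional overrides.
#' @return list: \code{times}, \code{copies} (matrix time x species,
#'   domain-total copies), \code{fields} (list of final-state density
#'   matrices, copies/um^2), \code{grid} (cell side), \code{mask}
#'   (logical matrix of the cluster disk), \code{radialProfile}
#'   (data.frame r, dMem density at tEnd), \code{geometry}.
#' @export
simulateMembranePDE <- function(model = NULL, tEnd = 4, dMem = 0.045,
                                grid = 0.015, dt = 0.01, maxDt = 0.1,
                                recordTimes = NULL,
                                recruiterInCluster = TRUE, initFields = NULL,
                                init = NULL, rates = NULL, geometry = NULL) {
  if (!is.null(model)) {
    if (is.null(init)) init <- model$init
    if (is.null(rates)) rates <- model$rates
    if (is.null(geometry)) geometry <- model$geometry
  }
  g <- geometry
  dt <- min(dt, maxDt)
  L <- g@side
  nx <- max(4L, round(L / grid))
  hcell <- L / nx
  if (2 * g@clusterRadius / hcell < 5)
    stop("grid too coarse: need >= 5 cells across the cluster disk")
  cellArea <- hcell^2
  xc <- (seq_len(nx) - 0.5) * hcell - L / 2
  gx <- matrix(xc, nx, nx); gy <- t(gx)
  mask <- gx^2 + gy^2 <= g@clusterRadius^2
  nCells <- nx * nx
  maskV <- as.vector(mask)
  nMask <- sum(maskV)

  # fields as vectors of copies/um^2
  rmem <- rep(init$rMem, nCells)
  if (!recruiterInCluster) rmem[maskV] <- 0
  dmem <- rep(init$dMem, nCells)
  aclusTotal <- init$aClus * g@clusterArea
  aclus <- numeric(nCells); aclus[maskV] <- aclusTotal / (nMask * cellArea)
  dclus <- numeric(nCells); dclus[maskV] <- init$dClus * g@clusterArea /
    (nMask * cellArea)
  d2d <- numeric(nCells); d2d[maskV] <- init$d2dclus * g@clusterArea /
    (nMask * cellArea)
  dsol <- init$dSol                       # uM, well-mixed bath
  if (!is.null(initFields)) {
    grab <- function(name, cur) {
      if (is.null(initFields[[name]])) cur else as.vector(initFields[[name]])
    }
    rmem <- grab("Rmem", rmem); dmem <- grab("Dmem", dmem)
    aclus <- grab("Aclus", aclus); dclus <- grab("Dclus", dclus)
    d2d <- grab("D2dclus", d2d)
  }

  # periodic 5-point Laplacian (per um^2), implicit Euler factorization
  idx <- matrix(seq_len(nCells), nx, nx)
  shift <- function(m, di, dj) {
    i <- ((seq_len(nx) - 1 + di) %% nx) + 1
    j <- ((seq_len(nx) - 1 + dj) %% nx) + 1
    m[i, j]
  }
  ii <- rep(seq_len(nCells), 5)
  jj <- c(seq_len(nCells), as.vector(shift(idx, 1, 0)),
          as.vector(shift(idx, -1, 0)), as.vector(shift(idx, 0, 1)),
          as.vector(shift(idx, 0, -1)))
  vv <- c(rep(-4, nCells), rep(1, 4 * nCells)) / hcell^2
  lap <- Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                              dims = c(nCells, nCells))
  sysM <- Matrix::Diagonal(nCells) - dt * dMem * lap
  fac <- Matrix::lu(sysM)

  rates <- .normRates(rates)
  k2mem <- rates$kMem2D / (.AVOGADRO_UM * g@h)   # um^2/s per copy
  k2dyn <- rates$kDyn2D / (.AVOGADRO_UM * g@h)
  bathFactor <- cellArea / (g@volume * .AVOGADRO_UM)  # copies -> uM in bath

  # cellwise reaction derivatives; returns list of field derivatives and
  # the bath derivative (uM/s)
  deriv <- function(rmem, dmem, aclus, dclus, d2d, dsol) {
    r1f <- rates$kFrev * dsol * rmem
    r1b <- rates$kB * dmem
    r2 <- k2mem * dmem * aclus
    r3 <- rates$kMem * dsol * aclus
    r4 <- k2dyn * dmem * d2d
    r5 <- rates$kDyn * dsol * dclus
    r6 <- k2dyn * dmem * dclus
    r7 <- rates$kDyn * dsol * d2d
    list(rmem = -r1f + r1b,
         dmem = r1f - r1b - r2 - r4 - r6,
         aclus = -r2 - r3,
         dclus = r3 + r5 + r7,
         d2d = r2 + r4 + r6,
         dsol = sum(r1b - r1f - r3 - r5 - r7) * bathFactor)
  }

  if (is.null(recordTimes))
    recordTimes <- seq(0, tEnd, length.out = min(81, ceiling(tEnd / dt) + 1))
  nRec <- length(recordTimes)
  copies <- matrix(NA_real_, nRec, 6, dimnames = list(NULL, .SPECIES))
  totals <- function() c(
    Dsol = dsol * g@volume * .AVOGADRO_UM,
    Rmem = sum(rmem) * cellArea, Aclus = sum(aclus) * cellArea,
    Dmem = sum(dmem) * cellArea, Dclus = sum(dclus) * cellArea,
    D2dclus = sum(d2d) * cellArea)
  iRec <- 1L
  recordUpTo <- function(tNow) {
    while (iRec <= nRec && recordTimes[iRec] <= tNow + 1e-12) {
      copies[iRec, ] <<- totals()
      iRec <<- iRec + 1L
    }
  }
  recordUpTo(0)
  nSteps <- ceiling(tEnd / dt)
  for (s in seq_len(nSteps)) {
    # RK2 midpoint for reactions
    d1 <- deriv(rmem, dmem, aclus, dclus, d2d, dsol)
    d2 <- deriv(rmem + dt / 2 * d1$rmem, dmem + dt / 2 * d1$dmem,
                aclus + dt / 2 * d1$aclus, dclus + dt / 2 * d1$dclus,
                d2d + dt / 2 * d1$d2d, dsol + dt / 2 * d1$dsol)
    rmem <- pmax(rmem + dt * d2$rmem, 0)
    dmem <- pmax(dmem + dt * d2$dmem, 0)
    aclus <- pmax(aclus + dt * d2$aclus, 0)
    dclus <- pmax(dclus + dt * d2$dclus, 0)
    d2d <- pmax(d2d + dt * d2$d2d, 0)
    dsol <- max(dsol + dt * d2$dsol, 0)
    # implicit diffusion of the mobile membrane species
    rmem <- as.numeric(Matrix::solve(fac, rmem))
    dmem <- as.numeric(Matrix::solve(fac, dmem))
    if (!all(is.finite(dmem)))
      stop("PDE step diverged; reduce dt (currently ", dt, " s)")
    recordUpTo(s * dt)
  }
  recordUpTo(tEnd + 1)
  r <- sqrt(gx^2 + gy^2)
  ord <- order(as.vector(r))
  radial <- data.frame(r = as.vector(r)[ord],
                       dMemDensity = matrix(dmem, nx, nx)[ord])
  list(times = recordTimes, copies = copies,
       fields = list(Rmem = matrix(rmem, nx, nx),
                     Dmem = matrix(dmem, nx, nx),
                     Aclus = matrix(aclus, nx, nx),
                     Dclus = matrix(dclus, nx, nx),
                     D2dclus = matrix(d2d, nx, nx)),
       grid = hcell, mask = mask, radialProfile = radial, geometry = g)
}

#' Domain-total copies of an ODE run (for comparison with SSA/PDE)
#'
#' @param series a \code{\link{StateTimeSeries}}.
#' @return matrix time x species of absolute copy numbers.
#' @export
stateCopies <- function(series) {
  g <- series@geometry
  nV <- .AVOGADRO_UM * g@volume
  series@states * nV
}
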