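# copies per um^3 corresponding to 1 uM
.AVOGADRO_UM <- 602.214

#' Build the single-cluster membrane geometry
#'
#' Clusters are assumed evenly distributed, so each cluster owns a square
#' membrane patch of side L = 1/sqrt(density) and area A = L^2; the
#' solution compartment above it has volume V = A * vOverA; the cluster
#' is a disk of area pi * clusterRadius^2; purely-2D reactions in the
#' volume-concentration representation are scaled by the dimensionality
#' factor DF = V/(A h) = vOverA/h.
#'
#' @param density cluster density, clusters/um^2 (> 0).
#' @param clusterRadius nanocluster radius, um.
#' @param vOverA volume-to-area ratio of the cell, um (default 1.9, a
#'   representative mammalian-cell value).
#' @param h nanoscopic 3D-to-2D conversion length, um (default 0.01,
#'   about the size of the molecule).
#' @return a \code{\link{ModelGeometry}}.
#' @export
buildGeometry <- function(density, clusterRadius, vOverA = 1.9, h = 0.01) {
  if (density <= 0) stop("density must be > 0")
  side <- 1 / sqrt(density)
  area <- side^2
  clusterArea <- pi * clusterRadius^2
  if (clusterArea >= area)
    stop("cluster area exceeds the membrane patch; reduce clusterRadius or density")
  volume <- area * vOverA
  methods::new("ModelGeometry", density = density, side = side, area = area,
               clusterRadius = clusterRadius, clusterArea = clusterArea,
               vOverA = vOverA, volume = volume, h = h, df = vOverA / h)
}

#' Off-rate enforcing the pre-cluster binding equilibrium
#'
#' The solution/membrane pools are initialized at steady state of the
#' reversible recruiter binding by choosing the off-rate so that
#' \code{dSol * rMem / dMem = kB / kFrev}; hence
#' \code{kB = kFrev * dSol * rMem / dMem}. \code{rMem/dMem} is a
#' dimensionless surface-density ratio, so \code{kB} has units 1/s when
#' \code{kFrev} is in 1/(uM s) and \code{dSol} in uM.
#'
#' @param dSol solution dynamin concentration, uM.
#' @param rMem free membrane-recruiter density, copies/um^2.
#' @param dMem membrane dynamin density, copies/um^2 (> 0).
#' @param kFrev recruiter on-rate, 1/(uM s).
#' @return kB in 1/s.
#' @export
equilibriumKb <- function(dSol, rMem, dMem, kFrev) {
  if (dMem <= 0) stop("dMem must be > 0")
  kFrev * dSol * rMem / dMem
}

#' Convert between the model's concentration units
#'
#' Exact linear conversions among micromolar, copies per cubic
#' micrometre, copies per square micrometre and absolute copies, using
#' 602.214 copies/um^3 per uM and, where needed, an explicit area or the
#' geometry's volume.
#'
#' @param value numeric value(s) to convert.
#' @param from,to one of \code{"uM"}, \code{"copies_per_um3"},
#'   \code{"copies_per_um2"}, \code{"copies"}.
#' @param geometry a \code{\link{ModelGeometry}} (required whenever
#'   \code{copies} or surface densities are involved).
#' @param area area used for surface-density conversions, um^2
#'   (default: the geometry's membrane area; pass
#'   \code{geometry@clusterArea} for cluster species).
#' @return converted value(s).
#' @export
convertUnits <- function(value, from, to, geometry = NULL, area = NULL) {
  units <- c("uM", "copies_per_um3", "copies_per_um2", "copies")
  if (!(from %in% units) || !(to %in% units))
    stop("unknown units: ", from, " -> ", to)
  if (from == to) return(value)
  needGeom <- c("copies_per_um2", "copies")
  if ((from %in% needGeom || to %in% needGeom) && is.null(geometry))
    stop("geometry is required for conversions involving copies")
  if (!is.null(geometry) && is.null(area)) area <- geometry@area
  toCopies <- switch(from,
    uM = value * .AVOGADRO_UM * geometry@volume,
    copies_per_um3 = value * geometry@volume,
    copies_per_um2 = value * area,
    copies = value)
  switch(to,
    uM = toCopies / (.AVOGADRO_UM * geometry@volume),
    copies_per_um3 = toCopies / geometry@volume,
    copies_per_um2 = toCopies / area,
    copies = toCopies)
}

# species order used by every simulator
.SPECIES <- c("Dsol", "Rmem", "Aclus", "Dmem", "Dclus", "D2dclus")

#' Assemble a dynamin recruitment model
#'
#' Bundles geometry, initial surface/solution densities and rate
#' constants. Presets reproduce the optimized Dyn1bb model:
#' pre-stimulation geometry 0.54 clusters/um^2 with cluster radius
#' 0.083 um; [D]mem = 30 copies/um^2, [D]sol = 10 uM, [R]mem = 4.85
#' copies/um^2, [A]clus = 207 copies/um^2; kMem = 0.017, kFrev = 0.09,
#' kDyn = 0.035 (all 1/(uM s)); kB from the equilibrium condition
#' (0.1455 1/s, printed rounded as 0.15); h = 10 nm. The post preset
#' applies the stimulation transform (\code{\link{applyStimulation}}):
#' geometry from 3.1 clusters/um^2 with radius 0.096 um, membrane
#' density scaled by \code{densityScale} with solution dynamin reduced
#' to conserve total copies, and kMem replaced by kMemPost = 0.0024
#' 1/(uM s) (0.006 for the stochastic variant, which compensates for the
#' discrete seeding of activated dynamin).
#'
#' @param preset \code{"dyn1bb-pre"}, \code{"dyn1bb-post"} or
#'   \code{"dyn1bb-post-ssa"}.
#' @param densityScale post-stimulation membrane dynamin scale factor
#'   (>= 1).
#' @return list of class \code{dynaminModel}: \code{geometry},
#'   \code{rates} (kFrev, kB, kMem, kDyn, 1/(uM s) except kB in 1/s),
#'   \code{init} (densities: dSol uM; rMem, dMem copies/um^2 over the
#'   patch; aClus copies/um^2 over the cluster disk; dClus, d2dclus 0).
#' @export
dynaminModel <- function(preset = c("dyn1bb-pre", "dyn1bb-post",
                                    "dyn1bb-post-ssa"),
                         densityScale = 2) {
  preset <- match.arg(preset)
  geom <- buildGeometry(0.54, clusterRadius = 0.083)
  init <- list(dSol = 10, rMem = 4.85, dMem = 30, aClus = 207,
               dClus = 0, d2dclus = 0)
  rates <- list(kFrev = 0.09,
                kB = equilibriumKb(10, 4.85, 30, 0.09),
                kMem = 0.017, kDyn = 0.035)
  model <- structure(list(geometry = geom, rates = rates, init = init,
                          preset = preset),
                     class = "dynaminModel")
  if (preset == "dyn1bb-pre") return(model)
  kMemPost <- if (preset == "dyn1bb-post-ssa") 0.006 else 0.0024
  applyStimulation(model, postDensity = 3.1, clusterRadius = 0.096,
                   densityScale = densityScale, kMemPost = kMemPost)
}

#' Apply the post-stimulation transform to a model
#'
#' Three changes mimic stimulation: (1) a new geometry from the increased
#' cluster density (smaller patch per cluster), (2) the initial membrane
#' dynamin density is scaled up by \code{densityScale} and the solution
#' pool is reduced so that total dynamin copies per unit membrane are
#' conserved (delta dSol = delta dMem / (vOverA * 602.214)), and (3) the
#' activator binding rate kMem is replaced by its post-stimulation value.
#' kDyn, kFrev, the free recruiter density and the activator density are
#' unchanged; kB keeps its pre-stimulation value so that the pre-stim
#' state remains the reference equilibrium.
#'
#' @param model a \code{dynaminModel}.
#' @param postDensity post-stimulation cluster density, clusters/um^2.
#' @param clusterRadius post-stimulation cluster radius, um.
#' @param densityScale membrane-density scale factor (>= 1).
#' @param kMemPost post-stimulation activator binding rate, 1/(uM s).
#' @return the transformed \code{dynaminModel}.
#' @export
applyStimulation <- function(model, postDensity = 3.1,
                             clusterRadius = 0.096, densityScale = 2,
                             kMemPost = 0.0024) {
  if (densityScale < 1) stop("densityScale must be >= 1")
  geomOld <- model$geometry
  geom <- buildGeometry(postDensity, clusterRadius = clusterRadius,
                        vOverA = geomOld@vOverA, h = geomOld@h)
  init <- model$init
  dMemNew <- init$dMem * densityScale
  dSolNew <- init$dSol - (dMemNew - init$dMem) / (geom@vOverA * .AVOGADRO_UM)
  if (dSolNew < 0)
    stop("copy conservation would drive the solution concentration negative")
  init$dMem <- dMemNew
  init$dSol <- dSolNew
  rates <- model$rates
  rates$kMem <- kMemPost
  structure(list(geometry = geom, rates = rates, init = init,
                 preset = model$preset),
            class = "dynaminModel")
}

# initial densities -> state vector in uM (the solver's representation)
.initialStateUM <- function(init, geometry) {
  g <- geometry
  c(Dsol = init$dSol,
    Rmem = convertUnits(init$rMem, "copies_per_um2", "uM", g),
    Aclus = convertUnits(init$aClus, "copies_per_um2", "uM", g,
                         area = g@clusterArea),
    Dmem = convertUnits(init$dMem, "copies_per_um2", "uM", g),
    Dclus = convertUnits(init$dClus, "copies_per_um2", "uM", g,
                         area = g@clusterArea),
    D2dclus = convertUnits(init$d2dclus, "copies_per_um2", "uM", g,
                           area = g@clusterArea))
}

# state in uM -> densities (copies/um^2; membrane species over the patch
# area, cluster species over the cluster disk area) and copies
.statesToDensities <- function(states, geometry) {
  g <- geometry
  out <- states
  out[, "Rmem"] <- convertUnits(states[, "Rmem"], "uM", "copies_per_um2", g)
  out[, "Dmem"] <- convertUnits(states[, "Dmem"], "uM", "copies_per_um2", g)
  out[, "Aclus"] <- convertUnits(states[, "Aclus"], "uM", "copies_per_um2", g,
                                 area = g@clusterArea)
  out[, "Dclus"] <- convertUnits(states[, "Dclus"], "uM", "copies_per_um2", g,
                                 area = g@clusterArea)
  out[, "D2dclus"] <- convertUnits(states[, "D2dclus"], "uM",
                                   "copies_per_um2", g, area = g@clusterArea)
  out
}
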