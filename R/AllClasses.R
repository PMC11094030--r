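#' @import methods
NULL

#' TrackSet: a set of single-particle trajectories
#'
#' Container for sptPALM-style trajectory data: a table of localizations
#' (one row per detection) grouped by trajectory id, together with the
#' acquisition frame time, total duration and the area of the imaged
#' region of interest.
#'
#' @slot detections data.frame with columns \code{id}, \code{x}, \code{y}
#'   (micrometres), \code{frame} (0-based integer) and \code{t} (seconds),
#'   sorted by id then time.
#' @slot frameTime numeric(1), frame interval in seconds (0.02 for 50 Hz).
#' @slot duration numeric(1), acquisition duration in seconds.
#' @slot roiArea numeric(1), region-of-interest area in square micrometres.
#' @slot metadata list of free-form annotations (e.g. density flags set by
#'   \code{\link{filterTracks}}).
#'
#' @aliases TrackSet-class
#' @exportClass TrackSet
setClass("TrackSet",
  representation(
    detections = "data.frame",
    frameTime = "numeric",
    duration = "numeric",
    roiArea = "numeric",
    metadata = "list"
  ),
  prototype(
    detections = data.frame(id = integer(), x = numeric(), y = numeric(),
                            frame = integer(), t = numeric()),
    frameTime = 0.02, duration = 0, roiArea = 1, metadata = list()
  )
)

setValidity("TrackSet", function(object) {
  msg <- character()
  d <- object@detections
  need <- c("id", "x", "y", "frame", "t")
  if (!all(need %in% names(d)))
    msg <- c(msg, paste("detections must have columns", paste(need, collapse = ", ")))
  if (length(object@roiArea) != 1 || !is.finite(object@roiArea) || object@roiArea <= 0)
    msg <- c(msg, "roiArea must be a single positive number")
  if (length(object@frameTime) != 1 || object@frameTime <= 0)
    msg <- c(msg, "frameTime must be a single positive number")
  if (nrow(d) > 0 && all(need %in% names(d))) {
    if (any(!is.finite(d$x)) || any(!is.finite(d$y)))
      msg <- c(msg, "coordinates must be finite")
    bad <- vapply(split(d$frame, d$id), function(f) any(diff(f) <= 0), logical(1))
    if (any(bad))
      msg <- c(msg, paste("frames not strictly increasing for id(s):",
                          paste(utils::head(names(bad)[bad], 5), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' StClusterSet: spatiotemporal nanoclusters detected in a TrackSet
#'
#' Result of 3D (x, y, pseudo-spatial time) DBSCAN clustering. Holds one
#' row per surviving cluster plus the detection-level cluster labels, and
#' the clustering parameters used (so footprint radii can be reconstructed
#' downstream).
#'
#' @slot clusters data.frame with columns \code{cluster}, \code{x},
#'   \code{y} (centroid, micrometres), \code{radius} (RMS member distance
#'   from the centroid, micrometres), \code{tStart}, \code{tEnd},
#'   \code{lifetime} (seconds), \code{nDetections}, \code{nTrajectories}.
#' @slot assignments data.frame of the clustered detections (columns
#'   \code{id}, \code{x}, \code{y}, \code{t}, \code{cluster}; noise points
#'   carry cluster \code{-1}).
#' @slot params list of clustering parameters (see
#'   \code{\link{clusteringParams}}).
#' @slot roiArea numeric(1), square micrometres.
#'
#' @aliases StClusterSet-class
#' @exportClass StClusterSet
setClass("StClusterSet",
  representation(
    clusters = "data.frame",
    assignments = "data.frame",
    params = "list",
    roiArea = "numeric"
  ),
  prototype(
    clusters = data.frame(), assignments = data.frame(),
    params = list(), roiArea = 1
  )
)

setValidity("StClusterSet", function(object) {
  msg <- character()
  cl <- object@clusters
  if (nrow(cl) > 0) {
    if (any(cl$lifetime < 0)) msg <- c(msg, "cluster lifetimes must be >= 0")
    if (any(cl$radius < 0)) msg <- c(msg, "cluster radii must be >= 0")
  }
  if (object@roiArea <= 0) msg <- c(msg, "roiArea must be positive")
  if (length(msg)) msg else TRUE
})

#' ModelGeometry: single-cluster membrane domain geometry
#'
#' The reaction-diffusion model follows recruitment to one nanocluster in
#' a square patch of membrane whose side is set by the measured cluster
#' density (clusters are assumed evenly spaced, so each cluster owns
#' 1/density of membrane). The solution compartment above the patch has
#' volume \code{V = A * vOverA}.
#'
#' @slot density clusters per square micrometre.
#' @slot side patch side L = 1/sqrt(density), micrometres.
#' @slot area patch area A = L^2, square micrometres.
#' @slot clusterRadius nanocluster disk radius, micrometres.
#' @slot clusterArea pi * clusterRadius^2, square micrometres.
#' @slot vOverA cell volume-to-membrane-area ratio, micrometres.
#' @slot volume solution volume above the patch, cubic micrometres.
#' @slot h nanoscopic length converting 3D to 2D rate constants, micrometres.
#' @slot df dimensionality factor DF = V/(A*h) = vOverA/h, dimensionless.
#'
#' @aliases ModelGeometry-class
#' @exportClass ModelGeometry
setClass("ModelGeometry",
  representation(
    density = "numeric", side = "numeric", area = "numeric",
    clusterRadius = "numeric", clusterArea = "numeric",
    vOverA = "numeric", volume = "numeric", h = "numeric", df = "numeric"
  )
)

setValidity("ModelGeometry", function(object) {
  msg <- character()
  vals <- c(object@density, object@side, object@area, object@clusterRadius,
            object@clusterArea, object@vOverA, object@volume, object@h, object@df)
  if (any(!is.finite(vals)) || any(vals <= 0))
    msg <- c(msg, "all geometry quantities must be positive and finite")
  else {
    if (object@clusterArea >= object@area)
      msg <- c(msg, "cluster area must be smaller than the membrane patch area")
    if (abs(object@df - object@vOverA / object@h) > 1e-9 * object@df)
      msg <- c(msg, "df must equal vOverA/h")
  }
  if (length(msg)) msg else TRUE
})

#' StateTimeSeries: time course of the six model species
#'
#' @slot times numeric vector of output times, seconds.
#' @slot states matrix (time x species) of concentrations in micromolar;
#'   columns \code{Dsol}, \code{Rmem}, \code{Aclus}, \code{Dmem},
#'   \code{Dclus}, \code{D2dclus}.
#' @slot geometry the \code{\link{ModelGeometry}} used.
#' @slot rates list of rate constants used.
#' @slot solver list of solver metadata (tolerances, diagnostics).
#'
#' @aliases StateTimeSeries-class
#' @exportClass StateTimeSeries
setClass("StateTimeSeries",
  representation(
    times = "numeric", states = "matrix", geometry = "ModelGeometry",
    rates = "list", solver = "list"
  )
)

setValidity("StateTimeSeries", function(object) {
  msg <- character()
  if (nrow(object@states) != length(object@times))
    msg <- c(msg, "states must have one row per time point")
  if (is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "times must be strictly increasing")
  if (length(msg)) msg else TRUE
})
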