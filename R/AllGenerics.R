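#' Accessors for TrackSet and StClusterSet objects
#'
#' \code{detections} returns the localization table; \code{frameTime},
#' \code{roiArea} and \code{acquisitionDuration} return acquisition
#' constants; \code{nTracks} and \code{trackLengths} summarize trajectory
#' membership; \code{clusters} returns the per-cluster table of an
#' \code{StClusterSet}.
#'
#' @param object a \code{\link{TrackSet}} or \code{\link{StClusterSet}}.
#' @return \code{detections}/\code{clusters}: a data.frame;
#'   \code{frameTime}, \code{roiArea}, \code{acquisitionDuration}:
#'   numeric(1); \code{nTracks}: integer(1); \code{trackLengths}: named
#'   integer vector of detections per trajectory.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("detections", function(object) standardGeneric("detections"))

#' @rdname accessors
#' @export
setGeneric("frameTime", function(object) standardGeneric("frameTime"))

#' @rdname accessors
#' @export
setGeneric("roiArea", function(object) standardGeneric("roiArea"))

#' @rdname accessors
#' @export
setGeneric("acquisitionDuration",
           function(object) standardGeneric("acquisitionDuration"))

#' @rdname accessors
#' @export
setGeneric("nTracks", function(object) standardGeneric("nTracks"))

#' @rdname accessors
#' @export
setGeneric("trackLengths", function(object) standardGeneric("trackLengths"))

#' @rdname accessors
#' @export
setGeneric("clusters", function(object) standardGeneric("clusters"))

#' @rdname accessors
#' @export
setMethod("detections", "TrackSet", function(object) object@detections)

#' @rdname accessors
#' @export
setMethod("frameTime", "TrackSet", function(object) object@frameTime)

#' @rdname accessors
#' @export
setMethod("roiArea", "TrackSet", function(object) object@roiArea)

#' @rdname accessors
#' @export
setMethod("acquisitionDuration", "TrackSet", function(object) object@duration)

#' @rdname accessors
#' @export
setMethod("nTracks", "TrackSet",
          function(object) length(unique(object@detections$id)))

#' @rdname accessors
#' @export
setMethod("trackLengths", "TrackSet", function(object) {
  d <- object@detections
  if (nrow(d) == 0) return(integer(0))
  tab <- table(d$id)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
})

#' @rdname accessors
#' @export
setMethod("clusters", "StClusterSet", function(object) object@clusters)

#' @rdname accessors
#' @export
setMethod("roiArea", "StClusterSet", function(object) object@roiArea)

setMethod("show", "TrackSet", function(object) {
  cat("TrackSet with", nTracks(object), "trajectories,",
      nrow(object@detections), "detections\n")
  cat("  frameTime:", object@frameTime, "s; duration:", object@duration,
      "s; ROI area:", object@roiArea, "um^2\n")
  if (isTRUE(object@metadata$densityFlag))
    cat("  [flagged: trajectory density exceeds limit]\n")
})

setMethod("show", "StClusterSet", function(object) {
  cat("StClusterSet with", nrow(object@clusters), "clusters in",
      object@roiArea, "um^2\n")
  if (nrow(object@clusters) > 0)
    cat("  mean radius:", signif(mean(object@clusters$radius), 3),
        "um; mean lifetime:", signif(mean(object@clusters$lifetime), 3), "s\n")
})

setMethod("show", "ModelGeometry", function(object) {
  cat("ModelGeometry:", object@density, "clusters/um^2\n")
  cat(sprintf("  side L = %.4g um, area A = %.4g um^2, V = %.4g um^3\n",
              object@side, object@area, object@volume))
  cat(sprintf("  cluster radius %.3g um (area %.4g um^2), h = %.3g um, DF = %.4g\n",
              object@clusterRadius, object@clusterArea, object@h, object@df))
})

setMethod("show", "StateTimeSeries", function(object) {
  cat("StateTimeSeries:", length(object@times), "time points over",
      max(object@times), "s;", ncol(object@states), "species (uM)\n")
})
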