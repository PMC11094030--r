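#' Spatiotemporal clustering parameters
#'
#' Parameter bundle for 3D DBSCAN nanocluster detection, with presets
#' matching the two published tool configurations: \code{"boosh"}
#' (epsilon 0.05 um, minimum points 3, time window 10 s, cluster size
#' screen 0.15 um -- the neurosecretory-cell settings; neurons use
#' minPoints 8 and a 0.3 um screen) and \code{"nastic"} (time threshold
#' 20 s, radius factor 1.2, cluster threshold 3).
#'
#' @param preset \code{"boosh"} or \code{"nastic"}; sets defaults below.
#' @param epsilon DBSCAN neighborhood radius, micrometres.
#' @param minPoints DBSCAN core-point threshold (neighborhood includes the
#'   point itself).
#' @param timeWindow spatiotemporal scalar: two co-located detections
#'   separated by \code{timeWindow} seconds map exactly \code{epsilon}
#'   apart in the transformed third coordinate.
#' @param clusterSizeScreen clusters with radius above this are discarded,
#'   micrometres.
#' @param clusterThreshold minimum member trajectories per cluster.
#' @param radiusFactor compatibility multiplier applied to the cluster
#'   radius when constructing the xy footprint used for trajectory-rate
#'   and trapping membership (1 = footprint equals the RMS radius).
#' @param minTrajLength,maxTrajLength trajectory length screen applied
#'   before clustering.
#' @return a list of class \code{clusteringParams}.
#' @export
clusteringParams <- function(preset = c("boosh", "nastic"),
                             epsilon = 0.05, minPoints = NULL,
                             timeWindow = NULL, clusterSizeScreen = 0.15,
                             clusterThreshold = 3, radiusFactor = NULL,
                             minTrajLength = 8, maxTrajLength = 100) {
  preset <- match.arg(preset)
  if (is.null(minPoints)) minPoints <- 3
  if (is.null(timeWindow)) timeWindow <- if (preset == "nastic") 20 else 10
  if (is.null(radiusFactor)) radiusFactor <- if (preset == "nastic") 1.2 else 1
  stopifnot(epsilon > 0, minPoints >= 1, timeWindow > 0, radiusFactor > 0)
  structure(list(preset = preset, epsilon = epsilon, minPoints = minPoints,
                 timeWindow = timeWindow,
                 clusterSizeScreen = clusterSizeScreen,
                 clusterThreshold = clusterThreshold,
                 radiusFactor = radiusFactor,
                 minTrajLength = minTrajLength,
                 maxTrajLength = maxTrajLength),
            class = "clusteringParams")
}

#' Pseudo-spatial transform of detection times
#'
#' Maps each detection (x, y, t) to (x, y, t * epsilon / timeWindow) so
#' that a single DBSCAN radius epsilon applies in both space and
#' (transformed) time: two co-located detections separated by exactly
#' \code{timeWindow} seconds end up exactly \code{epsilon} apart.
#'
#' @param det data.frame with columns \code{x}, \code{y}, \code{t}, or a
#'   \code{\link{TrackSet}}.
#' @param epsilon DBSCAN radius, micrometres.
#' @param timeWindow temporal window mapped to epsilon, seconds (> 0).
#' @return numeric matrix with columns x, y, z.
#' @export
pseudoSpatialTransform <- function(det, epsilon, timeWindow) {
  stopifnot(timeWindow > 0, epsilon > 0)
  if (methods::is(det, "TrackSet")) det <- detections(det)
  cbind(x = det$x, y = det$y, z = det$t * epsilon / timeWindow)
}

# precompute the closed eps-neighborhood of every point with a uniform
# grid of cell side eps: candidates for all points of a cell are the
# points of its 27-cell block, found via integer-coded cell lookups
.neighborLists <- function(pts, eps) {
  n <- nrow(pts)
  cells <- floor(sweep(pts, 2, apply(pts, 2, min)) / eps)
  nx <- max(cells[, 1]) + 3; ny <- max(cells[, 2]) + 3
  code <- (cells[, 1] + 1) + (cells[, 2] + 1) * nx +
          (cells[, 3] + 1) * nx * ny
  byCell <- split(seq_len(n), code)
  cellCodes <- as.numeric(names(byCell))
  lookup <- new.env(hash = TRUE, size = length(byCell))
  for (k in seq_along(byCell))
    assign(as.character(cellCodes[k]), byCell[[k]], envir = lookup)
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1)) %*%
    c(1, nx, nx * ny)
  nb <- vector("list", n)
  eps2 <- eps^2
  for (k in seq_along(byCell)) {
    members <- byCell[[k]]
    cand <- unlist(lapply(cellCodes[k] + offsets, function(cc) {
      lookup[[as.character(cc)]]
    }), use.names = FALSE)
    cx <- pts[cand, 1]; cy <- pts[cand, 2]; cz <- pts[cand, 3]
    for (i in members) {
      d2 <- (cx - pts[i, 1])^2 + (cy - pts[i, 2])^2 + (cz - pts[i, 3])^2
      nb[[i]] <- cand[d2 <= eps2]
    }
  }
  nb
}

#' 3D DBSCAN on a point cloud
#'
#' Standard DBSCAN in the (x, y, pseudo-spatial time) metric: a point is a
#' core point if its closed epsilon-neighborhood (including itself) holds
#' at least \code{minPoints} points; clusters are grown from core points;
#' border points are assigned to the first-discovered cluster (points are
#' seeded in input order, so the labeling is deterministic for a fixed
#' input order); noise is labeled \code{-1}. Neighbor queries use a
#' uniform grid of cell side epsilon.
#'
#' @param points numeric matrix with 3 columns (e.g. from
#'   \code{\link{pseudoSpatialTransform}}).
#' @param epsilon neighborhood radius.
#' @param minPoints core-point threshold.
#' @return integer vector of cluster labels (1, 2, ...; noise = -1).
#' @export
dbscan3d <- function(points, epsilon, minPoints) {
  n <- nrow(points)
  if (n == 0) return(integer(0))
  stopifnot(ncol(points) == 3, epsilon > 0, minPoints >= 1)
  nb <- .neighborLists(points, epsilon)
  core <- lengths(nb) >= minPoints
  labels <- rep(0L, n)   # 0 = unvisited
  nextCluster <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L) next
    if (!core[i]) { labels[i] <- -1L; next }
    nextCluster <- nextCluster + 1L
    labels[i] <- nextCluster
    queue <- nb[[i]]
    head <- 1L
    while (head <= length(queue)) {
      j <- queue[head]; head <- head + 1L
      if (labels[j] == -1L) labels[j] <- nextCluster  # noise -> border
      if (labels[j] != 0L) next
      labels[j] <- nextCluster
      if (core[j]) {
        nbj <- nb[[j]]
        queue <- c(queue, nbj[labels[nbj] <= 0L])
      }
    }
  }
  labels
}

#' Detect spatiotemporal nanoclusters in a TrackSet
#'
#' Full detection pipeline: trajectory length screening, canonical
#' sorting by (t, id) for deterministic border-point assignment,
#' pseudo-spatial transform, 3D DBSCAN, per-cluster summarization
#' (centroid, RMS radius, temporal extent) and screening by radius
#' (\code{clusterSizeScreen}) and member-trajectory count
#' (\code{clusterThreshold}).
#'
#' @param ts a \code{\link{TrackSet}}.
#' @param params a \code{\link{clusteringParams}}.
#' @return an \code{\link{StClusterSet}}.
#' @export
clusterTracks <- function(ts, params = clusteringParams()) {
  tsF <- filterTracks(ts, minLen = params$minTrajLength,
                      maxLen = params$maxTrajLength, densityLimit = Inf)
  d <- detections(tsF)
  d <- d[order(d$t, d$id), , drop = FALSE]
  if (nrow(d) == 0) {
    return(methods::new("StClusterSet",
      clusters = .emptyClusterTable(), assignments = d,
      params = unclass(params), roiArea = ts@roiArea))
  }
  pts <- pseudoSpatialTransform(d, params$epsilon, params$timeWindow)
  labels <- dbscan3d(pts, params$epsilon, params$minPoints)
  d$cluster <- labels
  keepLab <- sort(unique(labels[labels > 0]))
  rows <- lapply(keepLab, function(lab) {
    m <- d[d$cluster == lab, , drop = FALSE]
    cx <- mean(m$x); cy <- mean(m$y)
    data.frame(cluster = lab, x = cx, y = cy,
               radius = sqrt(mean((m$x - cx)^2 + (m$y - cy)^2)),
               tStart = min(m$t), tEnd = max(m$t),
               lifetime = max(m$t) - min(m$t),
               nDetections = nrow(m),
               nTrajectories = length(unique(m$id)))
  })
  cl <- if (length(rows)) do.call(rbind, rows) else .emptyClusterTable()
  keep <- cl$radius <= params$clusterSizeScreen &
          cl$nTrajectories >= params$clusterThreshold
  cl <- cl[keep, , drop = FALSE]
  d$cluster[!(d$cluster %in% cl$cluster)] <- -1L
  # relabel surviving clusters 1..k
  if (nrow(cl) > 0) {
    remap <- stats::setNames(seq_len(nrow(cl)), cl$cluster)
    d$cluster[d$cluster > 0] <- unname(remap[as.character(d$cluster[d$cluster > 0])])
    cl$cluster <- seq_len(nrow(cl))
  }
  rownames(cl) <- NULL
  methods::new("StClusterSet", clusters = cl, assignments = d,
               params = unclass(params), roiArea = ts@roiArea)
}

.emptyClusterTable <- function() {
  data.frame(cluster = integer(), x = numeric(), y = numeric(),
             radius = numeric(), tStart = numeric(), tEnd = numeric(),
             lifetime = numeric(), nDetections = integer(),
             nTrajectories = integer())
}

# footprint radius used for membership tests (RMS radius x compatibility factor)
.footprintRadius <- function(scs) {
  f <- scs@params$radiusFactor
  if (is.null(f)) f <- 1
  scs@clusters$radius * f
}

#' Summary metrics over a cluster set
#'
#' Cluster density over the ROI, mean radius, mean lifetime, hotspot
#' fraction, and (when a \code{\link{TrackSet}} is supplied) the mean
#' trajectory detection rates during and immediately before each
#' cluster's lifetime.
#'
#' @param scs an \code{\link{StClusterSet}}.
#' @param ts optional \code{\link{TrackSet}} for the trajectory rates.
#' @return list: \code{density} (clusters/um^2), \code{meanRadius} (um),
#'   \code{meanLifetime} (s), \code{hotspotFraction} (%),
#'   \code{meanRateDuring}, \code{meanRateBefore} (trajectories/s, NA
#'   without \code{ts}), \code{nClusters}.
#' @export
clusterMetrics <- function(scs, ts = NULL) {
  cl <- clusters(scs)
  rates <- if (!is.null(ts) && nrow(cl) > 0) trajectoryRates(scs, ts) else NULL
  list(
    density = nrow(cl) / scs@roiArea,
    meanRadius = if (nrow(cl)) mean(cl$radius) else NA_real_,
    meanLifetime = if (nrow(cl)) mean(cl$lifetime) else NA_real_,
    hotspotFraction = detectHotspots(scs),
    meanRateDuring = if (!is.null(rates)) mean(rates$rateDuring, na.rm = TRUE)
                     else NA_real_,
    meanRateBefore = if (!is.null(rates)) mean(rates$rateBefore, na.rm = TRUE)
                     else NA_real_,
    nClusters = nrow(cl)
  )
}

#' Hotspot fraction of a cluster set
#'
#' A cluster belongs to a hotspot when another cluster with a strictly
#' non-overlapping lifetime interval has its centroid within the sum of
#' the two radii -- repeated clustering at the same membrane location at
#' different times.
#'
#' @param scs an \code{\link{StClusterSet}}.
#' @return hotspot fraction in percent.
#' @export
detectHotspots <- function(scs) {
  cl <- clusters(scs)
  n <- nrow(cl)
  if (n < 2) return(0)
  hot <- logical(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    disjoint <- cl$tEnd[i] < cl$tStart[j] || cl$tEnd[j] < cl$tStart[i]
    if (!disjoint) next
    dc <- sqrt((cl$x[i] - cl$x[j])^2 + (cl$y[i] - cl$y[j])^2)
    if (dc < cl$radius[i] + cl$radius[j]) hot[i] <- hot[j] <- TRUE
  }
  100 * mean(hot)
}

#' Trajectory detection rates before and during each cluster's lifetime
#'
#' For each cluster, counts the trajectories with at least one detection
#' inside the cluster's xy footprint (a time-extruded cylinder of radius
#' RMS-radius x radiusFactor) during its lifetime [tStart, tEnd], divided
#' by the lifetime; and the same count over the window of equal length
#' immediately before, [tStart - lifetime, tStart). A before-window that
#' would start before time 0 is clipped and its rate normalized by the
#' actual window length. Zero-lifetime clusters are skipped with a
#' warning (rates NA).
#'
#' @param scs an \code{\link{StClusterSet}}.
#' @param ts the \code{\link{TrackSet}} the clusters were detected in.
#' @return data.frame: \code{cluster}, \code{rateBefore},
#'   \code{rateDuring} (trajectories per second).
#' @export
trajectoryRates <- function(scs, ts) {
  cl <- clusters(scs)
  d <- detections(ts)
  fr <- .footprintRadius(scs)
  out <- data.frame(cluster = cl$cluster,
                    rateBefore = NA_real_, rateDuring = NA_real_)
  if (nrow(cl) == 0) return(out)
  zero <- cl$lifetime <= 0
  if (any(zero))
    warning(sum(zero), " zero-lifetime cluster(s) skipped in trajectoryRates")
  for (i in seq_len(nrow(cl))) {
    if (zero[i]) next
    inFoot <- (d$x - cl$x[i])^2 + (d$y - cl$y[i])^2 <= fr[i]^2
    during <- inFoot & d$t >= cl$tStart[i] & d$t <= cl$tEnd[i]
    t0 <- max(cl$tStart[i] - cl$lifetime[i], 0)
    beforeWin <- cl$tStart[i] - t0
    before <- inFoot & d$t >= t0 & d$t < cl$tStart[i]
    out$rateDuring[i] <- length(unique(d$id[during])) / cl$lifetime[i]
    out$rateBefore[i] <- if (beforeWin > 0)
      length(unique(d$id[before])) / beforeWin else NA_real_
  }
  out
}
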