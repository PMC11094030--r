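# Independent reference implementations and fixture builders shared by
# the test files. The oracles deliberately avoid the package's internal
# helpers: the DBSCAN oracle works from a full distance matrix with the
# textbook seed-set expansion, and the trapping oracle re-derives the
# three entry rules directly from the definitions.

# textbook DBSCAN over a precomputed distance matrix; border points go to
# the first-discovered cluster (points visited in input order), noise -1
oracleDbscan <- function(pts, eps, minPts) {
  n <- nrow(pts)
  dmat <- as.matrix(stats::dist(pts))
  regionQuery <- function(i) which(dmat[i, ] <= eps)
  labels <- rep(NA_integer_, n)
  clusterId <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i])) next
    seeds <- regionQuery(i)
    if (length(seeds) < minPts) { labels[i] <- -1L; next }
    clusterId <- clusterId + 1L
    labels[i] <- clusterId
    k <- 1L
    while (k <= length(seeds)) {
      q <- seeds[k]; k <- k + 1L
      if (!is.na(labels[q]) && labels[q] == -1L) labels[q] <- clusterId
      if (!is.na(labels[q])) next
      labels[q] <- clusterId
      qSeeds <- regionQuery(q)
      if (length(qSeeds) >= minPts)
        seeds <- c(seeds, qSeeds[is.na(labels[qSeeds]) |
                                 labels[qSeeds] == -1L])
    }
  }
  labels
}

# direct evaluation of the trapping rules for every (trajectory, cluster)
# pair; `footprint` must already include any radius factor
oracleTrapping <- function(clusterTab, footprint, det, requireConfined = TRUE) {
  out <- list()
  for (ci in seq_len(nrow(clusterTab))) {
    cc <- clusterTab[ci, ]
    for (id in unique(det$id)) {
      tr <- det[det$id == id, , drop = FALSE]
      tr <- tr[order(tr$t), , drop = FALSE]
      within <- (tr$x - cc$x)^2 + (tr$y - cc$y)^2 <= footprint[ci]^2 &
        tr$t >= cc$tStart & tr$t <= cc$tEnd
      if (!any(within)) next
      if (within[1]) next                       # rule 1
      if (!within[nrow(tr)]) next               # rule 2
      entry <- which(within)[1]
      if (entry > 1 && any(within[seq_len(entry - 1)])) next  # rule 3
      if (requireConfined) {
        post <- seq(entry, nrow(tr))
        post <- post[tr$t[post] <= cc$tEnd]
        inFoot <- (tr$x[post] - cc$x)^2 + (tr$y[post] - cc$y)^2 <=
          footprint[ci]^2
        if (!all(inFoot)) next
      }
      out[[length(out) + 1]] <- data.frame(id = id, cluster = cc$cluster,
                                           entryStep = entry - 1L)
    }
  }
  if (length(out) == 0)
    return(data.frame(id = integer(), cluster = integer(),
                      entryStep = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# plain 2D Brownian trajectory without boundaries (for estimator tests)
brownianTrack <- function(id, nSteps, d, dt = 0.02, x0 = 0, y0 = 0,
                          t0 = 0, sigma = 0) {
  s <- sqrt(2 * d * dt)
  x <- cumsum(c(x0, stats::rnorm(nSteps, 0, s)))
  y <- cumsum(c(y0, stats::rnorm(nSteps, 0, s)))
  if (sigma > 0) {
    x <- x + stats::rnorm(nSteps + 1, 0, sigma)
    y <- y + stats::rnorm(nSteps + 1, 0, sigma)
  }
  frames <- as.integer(round(t0 / dt)) + 0:nSteps
  data.frame(id = id, x = x, y = y, frame = frames, t = frames * dt)
}

# assemble a TrackSet from a list of detection data.frames
makeTrackSet <- function(detList, frameTime = 0.02, roiArea = 100,
                         duration = NULL) {
  det <- do.call(rbind, detList)
  rownames(det) <- NULL
  if (is.null(duration)) duration <- if (nrow(det)) max(det$t) else 0
  methods::new("TrackSet", detections = det, frameTime = frameTime,
               duration = duration, roiArea = roiArea, metadata = list())
}

# StClusterSet built directly from a cluster table (bypassing detection),
# e.g. from a simulation's ground-truth layout
makeClusterSet <- function(clusterTab, roiArea, radiusFactor = 1) {
  tab <- data.frame(cluster = clusterTab$cluster, x = clusterTab$x,
                    y = clusterTab$y, radius = clusterTab$radius,
                    tStart = clusterTab$tStart, tEnd = clusterTab$tEnd,
                    lifetime = clusterTab$tEnd - clusterTab$tStart,
                    nDetections = NA_integer_, nTrajectories = NA_integer_)
  methods::new("StClusterSet", clusters = tab,
               assignments = data.frame(), roiArea = roiArea,
               params = list(radiusFactor = radiusFactor))
}
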