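#' Find trajectories that laterally diffuse into a nanocluster and stay
#'
#' Certifies, for each cluster, the trajectories that sample the membrane
#' in 2D and then become confined in the cluster. A detection is "within"
#' a cluster when it lies inside the xy footprint (RMS radius x
#' radiusFactor) during the cluster's temporal window. The three rules
#' are: (1) the first detection of the trajectory is not within the
#' cluster, (2) the last detection is within the cluster, (3) the
#' trajectory does not intercept the cluster boundary before its step of
#' entry (at detection resolution: no pre-entry detection within; with
#' \code{strictBoundary = TRUE} additionally no segment between
#' consecutive pre-entry detections inside the temporal window crosses
#' the footprint circle). With \code{requireConfined = TRUE} (default)
#' every detection after entry and before the cluster's end must also lie
#' within the footprint, i.e. the molecule stays confined for the
#' remainder of the cluster lifetime.
#'
#' @param scs an \code{\link{StClusterSet}}.
#' @param ts the matching \code{\link{TrackSet}} (same coordinate frame
#'   and time base).
#' @param requireConfined require post-entry confinement (see above).
#' @param strictBoundary also test segment-circle crossings before entry.
#' @return data.frame of trapping records: \code{id}, \code{cluster},
#'   \code{entryStep} (0-based index of the entry detection within the
#'   trajectory; >= 1 by rule 1).
#' @export
findTrappedTrajectories <- function(scs, ts, requireConfined = TRUE,
                                    strictBoundary = FALSE) {
  cl <- clusters(scs)
  d <- detections(ts)
  fr <- .footprintRadius(scs)
  recs <- list()
  if (nrow(cl) == 0 || nrow(d) == 0)
    return(data.frame(id = d$id[0], cluster = integer(), entryStep = integer()))
  trajs <- split(d, d$id)
  for (ci in seq_len(nrow(cl))) {
    for (tr in trajs) {
      es <- .entryStep(tr, cl$x[ci], cl$y[ci], fr[ci],
                       cl$tStart[ci], cl$tEnd[ci],
                       requireConfined, strictBoundary)
      if (!is.na(es))
        recs[[length(recs) + 1]] <- data.frame(id = tr$id[1],
                                               cluster = cl$cluster[ci],
                                               entryStep = es)
    }
  }
  if (length(recs) == 0)
    return(data.frame(id = d$id[0], cluster = integer(), entryStep = integer()))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

# entry step (0-based) if the trajectory satisfies the trapping rules for
# one cluster footprint, else NA. Shared by the fast path and the tests'
# brute-force comparisons (the oracle in the test suite re-derives the
# rules independently).
.entryStep <- function(tr, cx, cy, fr, t0, t1, requireConfined,
                       strictBoundary) {
  n <- nrow(tr)
  inWin <- tr$t >= t0 & tr$t <= t1
  inFoot <- (tr$x - cx)^2 + (tr$y - cy)^2 <= fr^2
  within <- inWin & inFoot
  if (!any(within)) return(NA_integer_)
  if (within[1]) return(NA_integer_)            # rule 1
  if (!within[n]) return(NA_integer_)           # rule 2
  entry <- which(within)[1]
  # rule 3 at detection resolution is implied by 'entry' being the first
  # within-detection; the strict mode also rejects pass-throughs between
  # consecutive pre-entry detections while the cluster is alive
  if (strictBoundary && entry > 2) {
    for (k in seq_len(entry - 2)) {
      if (tr$t[k] > t1 || tr$t[k + 1] < t0) next
      if (.segmentCrossesCircle(tr$x[k], tr$y[k], tr$x[k + 1], tr$y[k + 1],
                                cx, cy, fr))
        return(NA_integer_)
    }
  }
  if (requireConfined) {
    post <- seq(entry, n)
    post <- post[tr$t[post] <= t1]
    if (!all(inFoot[post])) return(NA_integer_)
  }
  entry - 1L   # 0-based
}

.segmentCrossesCircle <- function(x1, y1, x2, y2, cx, cy, r) {
  dx <- x2 - x1; dy <- y2 - y1
  fx <- x1 - cx; fy <- y1 - cy
  a <- dx^2 + dy^2
  if (a == 0) return(fx^2 + fy^2 <= r^2)
  tt <- pmin(pmax(-(fx * dx + fy * dy) / a, 0), 1)
  (fx + tt * dx)^2 + (fy + tt * dy)^2 <= r^2
}

#' Entry-aligned frame-to-frame displacements
#'
#' Pools the frame-to-frame displacements of all trapped trajectories by
#' step number relative to the step of entry: the displacement leaving
#' the detection at absolute index entryStep + s is assigned relative
#' step s, so step 0 is the first displacement made after entering the
#' cluster and negative steps are the pre-entry (2D sampling) phase.
#'
#' @param records trapping records from
#'   \code{\link{findTrappedTrajectories}}.
#' @param ts the matching \code{\link{TrackSet}}.
#' @return data.frame: \code{step}, \code{mean} (um), \code{sem},
#'   \code{n}; steps observed fewer than twice carry \code{sparse = TRUE}.
#'   Empty records give an empty data.frame (no error).
#' @export
entryAlignedDisplacements <- function(records, ts) {
  empty <- data.frame(step = integer(), mean = numeric(), sem = numeric(),
                      n = integer(), sparse = logical())
  if (nrow(records) == 0) return(empty)
  d <- detections(ts)
  trajs <- split(d, d$id)
  steps <- integer(0); disps <- numeric(0)
  for (r in seq_len(nrow(records))) {
    tr <- trajs[[as.character(records$id[r])]]
    n <- nrow(tr)
    if (n < 2) next
    dd <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
    # displacement k leaves detection (k-1) [0-based]; relative step:
    rel <- (seq_len(n - 1) - 1L) - records$entryStep[r]
    steps <- c(steps, rel); disps <- c(disps, dd)
  }
  if (length(steps) == 0) return(empty)
  agg <- lapply(split(disps, steps), function(v)
    c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)), n = length(v)))
  out <- data.frame(step = as.integer(names(agg)),
                    mean = vapply(agg, `[[`, numeric(1), "mean"),
                    sem = vapply(agg, `[[`, numeric(1), "sem"),
                    n = as.integer(vapply(agg, `[[`, numeric(1), "n")))
  out <- out[order(out$step), , drop = FALSE]
  out$sparse <- out$n < 2
  rownames(out) <- NULL
  out
}

#' Trapping summary: entry percentages and before/within displacements
#'
#' The denominator is the set of clustered trajectories: all trajectories
#' with at least one detection within any surviving cluster footprint
#' during that cluster's lifetime. For each prior-detection filter n, the
#' reported percentage is the share of clustered trajectories certified
#' as entering with at least n detections before entry
#' (entryStep >= n). Mean displacement before entry pools all relative
#' steps < 0 of the records; mean displacement within the cluster pools
#' steps >= 0.
#'
#' @param records trapping records from
#'   \code{\link{findTrappedTrajectories}}.
#' @param ts the matching \code{\link{TrackSet}}.
#' @param scs the \code{\link{StClusterSet}} (defines the denominator).
#' @param nFilters integer vector of prior-detection thresholds.
#' @return list: \code{percentages} (data.frame n, percent; NA when there
#'   are no clustered trajectories), \code{meanBefore}, \code{meanWithin}
#'   (um), \code{nClustered}, \code{nRecords}.
#' @export
trappingSummary <- function(records, ts, scs, nFilters = 1:10) {
  cl <- clusters(scs)
  d <- detections(ts)
  fr <- .footprintRadius(scs)
  clusteredIds <- character(0)
  for (i in seq_len(nrow(cl))) {
    hit <- (d$x - cl$x[i])^2 + (d$y - cl$y[i])^2 <= fr[i]^2 &
           d$t >= cl$tStart[i] & d$t <= cl$tEnd[i]
    clusteredIds <- union(clusteredIds, as.character(unique(d$id[hit])))
  }
  nClustered <- length(clusteredIds)
  if (nClustered == 0) {
    percentages <- data.frame(n = nFilters, percent = NA_real_)
  } else {
    uniq <- records[!duplicated(records$id), , drop = FALSE]
    percentages <- data.frame(
      n = nFilters,
      percent = vapply(nFilters, function(nf)
        100 * sum(uniq$entryStep >= nf) / nClustered, numeric(1)))
  }
  ead <- entryAlignedDisplacements(records, ts)
  wBefore <- ead$step < 0
  wWithin <- ead$step >= 0
  meanBefore <- if (any(wBefore))
    sum(ead$mean[wBefore] * ead$n[wBefore]) / sum(ead$n[wBefore]) else NA_real_
  meanWithin <- if (any(wWithin))
    sum(ead$mean[wWithin] * ead$n[wWithin]) / sum(ead$n[wWithin]) else NA_real_
  list(percentages = percentages, meanBefore = meanBefore,
       meanWithin = meanWithin, nClustered = nClustered,
       nRecords = nrow(records))
}
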