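#' Recruitment kinetics of a fluorescence-intensity trace
#'
#' Quantifies a region-of-interest FI time course around a stimulation
#' event: baseline (mean FI over the \code{baselineWindow} seconds before
#' stimulation), peak (argmax of the moving-average-smoothed FI after
#' stimulation), time to peak, fold change (smoothed peak over baseline)
#' and the post-peak decay slope from a least-squares line over
#' \code{decayWindow} seconds after the peak. A peak landing within half
#' a smoothing window of the trace end is flagged unresolved.
#'
#' @param trace data.frame with columns \code{time} (s, strictly
#'   increasing) and \code{fi} (arbitrary units).
#' @param stimTime stimulation time, seconds; must lie within the trace,
#'   with at least 10 samples after it.
#' @param smoothingWindow moving-average window, seconds.
#' @param baselineWindow pre-stimulation window for the baseline, seconds.
#' @param decayWindow post-peak window for the decay fit, seconds.
#' @return list of class \code{kineticsResult}: \code{baseline},
#'   \code{timeToPeak} (s), \code{peakTime}, \code{foldChange},
#'   \code{decaySlope} (FI/s), \code{unresolvedPeak}.
#' @export
analyzeTrace <- function(trace, stimTime, smoothingWindow = 5,
                         baselineWindow = 30, decayWindow = 100) {
  stopifnot(all(diff(trace$time) > 0), all(is.finite(trace$fi)))
  if (stimTime < min(trace$time) || stimTime > max(trace$time))
    stop("stimTime must lie within the trace")
  if (sum(trace$time > stimTime) < 10)
    stop("need at least 10 samples after stimulation")
  dt <- stats::median(diff(trace$time))
  w <- max(1L, round(smoothingWindow / dt))
  if (w %% 2 == 0) w <- w + 1L
  sm <- as.numeric(stats::filter(trace$fi, rep(1 / w, w), sides = 2))
  # shrink the window at the edges instead of dropping samples
  half <- (w - 1L) / 2L
  n <- length(sm)
  for (i in which(is.na(sm))) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    sm[i] <- mean(trace$fi[lo:hi])
  }
  pre <- trace$time < stimTime & trace$time >= stimTime - baselineWindow
  baseline <- mean(trace$fi[pre])
  post <- which(trace$time >= stimTime)
  iPeak <- post[which.max(sm[post])]
  peakTime <- trace$time[iPeak]
  # no distinct maximum: either the argmax sits at the trace end or the
  # trace never rises above baseline (e.g. a flat trace)
  unresolved <- peakTime > max(trace$time) - smoothingWindow / 2 ||
    sm[iPeak] <= baseline * (1 + 1e-9)
  if (unresolved)
    warning("unresolved peak (at trace end or no rise above baseline)")
  dec <- trace$time >= peakTime & trace$time <= peakTime + decayWindow
  decaySlope <- if (sum(dec) >= 2)
    unname(stats::lm.fit(cbind(1, trace$time[dec]), trace$fi[dec])$coefficients[2])
  else NA_real_
  structure(list(baseline = baseline, timeToPeak = peakTime - stimTime,
                 peakTime = peakTime, foldChange = sm[iPeak] / baseline,
                 decaySlope = decaySlope, unresolvedPeak = unresolved),
            class = "kineticsResult")
}

#' Compare a post-peak decay slope with a photobleaching control
#'
#' Fits the decay slope of the trace and of a bleaching control over the
#' same time window and reports whether the trace decays faster than
#' expected from photobleaching alone (one-sided comparison). With
#' \code{logScale = TRUE} (default, valid when both traces are positive
#' over the window) slopes are fitted on log-FI, i.e. as exponential
#' decay constants, so the comparison is independent of absolute
#' intensity scale.
#'
#' @param trace,bleachTrace data.frames with columns \code{time},
#'   \code{fi}; both must cover \code{window}.
#' @param window numeric(2), fitting window (start, end) in seconds.
#' @param logScale fit on log-FI when possible.
#' @return list: \code{traceSlope}, \code{bleachSlope}, \code{excessDecay}
#'   (TRUE when the trace slope is more negative than the bleach slope),
#'   \code{logScale} actually used.
#' @export
compareDecayToBleach <- function(trace, bleachTrace, window,
                                 logScale = TRUE) {
  sel1 <- trace$time >= window[1] & trace$time <= window[2]
  sel2 <- bleachTrace$time >= window[1] & bleachTrace$time <= window[2]
  if (sum(sel1) < 2 || sum(sel2) < 2)
    stop("window does not overlap both traces")
  useLog <- logScale && all(trace$fi[sel1] > 0) && all(bleachTrace$fi[sel2] > 0)
  y1 <- if (useLog) log(trace$fi[sel1]) else trace$fi[sel1]
  y2 <- if (useLog) log(bleachTrace$fi[sel2]) else bleachTrace$fi[sel2]
  s1 <- unname(stats::lm.fit(cbind(1, trace$time[sel1]), y1)$coefficients[2])
  s2 <- unname(stats::lm.fit(cbind(1, bleachTrace$time[sel2]), y2)$coefficients[2])
  list(traceSlope = s1, bleachSlope = s2,
       excessDecay = s1 < s2, logScale = useLog)
}

#' Rate of cumulative track appearances in time blocks
#'
#' Counts the cumulative number of trajectory first-appearances per um^2
#' of membrane, chunks the cumulative curve into blocks (30 s by default,
#' to avoid under-sampling) and returns the discrete gradient of the
#' blocked counts (central differences; one-sided at the ends), i.e. the
#' appearance rate per block in tracks/um^2/s.
#'
#' @param ts a \code{\link{TrackSet}} with a known ROI area.
#' @param block block length, seconds (> 0); the acquisition must span at
#'   least two blocks.
#' @return data.frame: \code{time} (block centers, s), \code{cumulative}
#'   (tracks/um^2 at the block end), \code{rate} (tracks/um^2/s).
#' @export
cumulativeTrackRate <- function(ts, block = 30) {
  stopifnot(block > 0)
  duration <- acquisitionDuration(ts)
  nBlocks <- floor(duration / block)
  if (nBlocks < 2) stop("acquisition must span at least two blocks")
  d <- detections(ts)
  first <- vapply(split(d$t, d$id), min, numeric(1))
  edges <- seq_len(nBlocks) * block
  cum <- vapply(edges, function(e) sum(first <= e), numeric(1)) / roiArea(ts)
  # central-difference gradient of the blocked cumulative counts
  grad <- numeric(nBlocks)
  grad[1] <- (cum[2] - cum[1]) / block
  grad[nBlocks] <- (cum[nBlocks] - cum[nBlocks - 1]) / block
  if (nBlocks > 2)
    grad[2:(nBlocks - 1)] <- (cum[3:nBlocks] - cum[1:(nBlocks - 2)]) / (2 * block)
  data.frame(time = edges - block / 2, cumulative = cum, rate = grad)
}
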