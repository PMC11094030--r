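#' Mean squared displacement profile of one trajectory
#'
#' Computes the time-origin-averaged MSD at lags 1..maxLag, fits
#' \code{MSD = 4 D tau + c} by least squares over the first
#' \code{fitPoints} lags (the free intercept absorbs localization noise),
#' and integrates the MSD over the reported lag range by the trapezoid
#' rule. For the 2D Brownian case the fitted slope/4 is the diffusion
#' coefficient D. D is floored at \code{dFloor} before taking Log10D.
#'
#' @param traj data.frame with columns \code{x}, \code{y}, \code{t} (one
#'   trajectory, time-ordered, uniform frame interval).
#' @param maxLag largest lag (frames); must be < number of detections.
#'   Default: min(length - 1, aucLags).
#' @param fitPoints number of initial lags used in the linear fit.
#' @param aucLags number of lags over which the AUC is integrated.
#' @param frameTime frame interval, seconds; default inferred from
#'   \code{traj$t}.
#' @param dFloor lower clip for D before Log10, um^2/s.
#' @return list of class \code{msdProfile}: \code{lags} (s), \code{msd}
#'   (um^2), \code{d} (um^2/s), \code{intercept} (um^2), \code{auc}
#'   (um^2 s), \code{log10d}.
#' @export
msdCurve <- function(traj, maxLag = NULL, fitPoints = 4, aucLags = 8,
                     frameTime = NULL, dFloor = 1e-5) {
  n <- nrow(traj)
  if (is.null(frameTime)) {
    dts <- diff(traj$t)
    frameTime <- if (length(dts)) stats::median(dts) else 0.02
  }
  if (is.null(maxLag)) maxLag <- min(n - 1, aucLags)
  if (maxLag >= n) stop("maxLag must be smaller than the trajectory length")
  if (n <= fitPoints) stop("trajectory must be longer than fitPoints")
  msd <- vapply(seq_len(maxLag), function(k) {
    dx <- traj$x[(1 + k):n] - traj$x[1:(n - k)]
    dy <- traj$y[(1 + k):n] - traj$y[1:(n - k)]
    mean(dx^2 + dy^2)
  }, numeric(1))
  lags <- seq_len(maxLag) * frameTime
  kFit <- min(fitPoints, maxLag)
  fit <- stats::lm.fit(cbind(1, lags[1:kFit]), msd[1:kFit])
  d <- max(fit$coefficients[2] / 4, dFloor)
  kA <- min(aucLags, maxLag)
  auc <- if (kA >= 2) sum(diff(lags[1:kA]) * (msd[1:kA][-1] + msd[1:kA][-kA]) / 2)
         else 0
  structure(list(lags = lags, msd = msd, d = unname(d),
                 intercept = unname(fit$coefficients[1]), auc = auc,
                 log10d = log10(unname(d))),
            class = "msdProfile")
}

#' Mobility metrics for a TrackSet
#'
#' Per-track diffusion coefficients from 4-point MSD fits, the Log10D
#' frequency distribution over fixed bins, the mobile-to-immobile ratio
#' (M/IMM; mobile = Log10D above \code{logDThreshold}), the mean MSD
#' curve and the mean AUC of the MSD. Tracks shorter than
#' \code{fitPoints + 2} detections are ignored.
#'
#' @param ts a \code{\link{TrackSet}} (typically after
#'   \code{\link{filterTracks}}).
#' @param logDThreshold mobile/immobile Log10D threshold (log10 um^2/s).
#' @param fitPoints,aucLags,dFloor passed to \code{\link{msdCurve}}.
#' @param breaks fixed Log10D histogram breaks; values outside are clipped
#'   into the end bins so the fractions always sum to 1.
#' @return list of class \code{mobilityMetrics}: \code{perTrack}
#'   (data.frame id, d, log10d, auc), \code{freq} (data.frame bin mid,
#'   fraction), \code{mobileFraction}, \code{mobileImmobileRatio} (Inf
#'   sentinel with a warning when no track is immobile), \code{meanMsd}
#'   (data.frame lag, msd, n), \code{meanAuc}.
#' @export
mobilityMetrics <- function(ts, logDThreshold = -1.45, fitPoints = 4,
                            aucLags = 8, dFloor = 1e-5,
                            breaks = seq(-5.1, 1.1, by = 0.2)) {
  d <- detections(ts)
  trajs <- split(d, d$id)
  trajs <- trajs[vapply(trajs, nrow, integer(1)) >= fitPoints + 2]
  if (length(trajs) == 0) stop("no trajectory long enough for the MSD fit")
  profs <- lapply(trajs, msdCurve, fitPoints = fitPoints, aucLags = aucLags,
                  frameTime = ts@frameTime, dFloor = dFloor)
  perTrack <- data.frame(
    id = names(trajs),
    d = vapply(profs, `[[`, numeric(1), "d"),
    log10d = vapply(profs, `[[`, numeric(1), "log10d"),
    auc = vapply(profs, `[[`, numeric(1), "auc"),
    row.names = NULL
  )
  clipped <- pmin(pmax(perTrack$log10d, breaks[1] + 1e-12),
                  breaks[length(breaks)] - 1e-12)
  h <- graphics::hist(clipped, breaks = breaks, plot = FALSE)
  freq <- data.frame(mid = h$mids, fraction = h$counts / nrow(perTrack))
  mobile <- sum(perTrack$log10d > logDThreshold)
  immobile <- nrow(perTrack) - mobile
  ratio <- if (immobile == 0) {
    warning("no immobile tracks; M/IMM reported as Inf")
    Inf
  } else mobile / immobile
  maxK <- max(vapply(profs, function(p) length(p$msd), integer(1)))
  meanMsd <- data.frame(
    lag = seq_len(maxK) * ts@frameTime,
    msd = vapply(seq_len(maxK), function(k) {
      v <- unlist(lapply(profs, function(p) p$msd[k]))
      mean(v, na.rm = TRUE)
    }, numeric(1)),
    n = vapply(seq_len(maxK), function(k) {
      sum(vapply(profs, function(p) length(p$msd) >= k, logical(1)))
    }, numeric(1))
  )
  structure(list(perTrack = perTrack, freq = freq,
                 mobileFraction = mobile / nrow(perTrack),
                 mobileImmobileRatio = ratio,
                 meanMsd = meanMsd, meanAuc = mean(perTrack$auc)),
            class = "mobilityMetrics")
}

#' Root-mean-square diffusion reach in 2D
#'
#' The RMS displacement of a 2D Brownian particle after time \code{t},
#' \code{sqrt(4 D t)} -- a quick estimate of how far a membrane protein
#' samples laterally (e.g. 0.57 um in 4 s at D = 0.02 um^2/s, enough to
#' cross the inter-cluster spacing).
#'
#' @param d diffusion coefficient, um^2/s.
#' @param t elapsed time, s.
#' @return reach in micrometres.
#' @export
diffusionReach <- function(d, t) sqrt(4 * d * t)
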