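#' Configuration for the synthetic sptPALM trajectory generator
#'
#' Bundles the acquisition, diffusion, clustering and photophysics
#' parameters of the generative model. Defaults emulate a 50 Hz sptPALM
#' acquisition of a neurosecretory-cell membrane: slow membrane diffusion,
#' sub-100-nm nanoclusters at sub-1/um^2 density, a step increase in the
#' molecular appearance rate at stimulation, Bernoulli capture on cluster
#' crossing with reflecting confinement, geometric photobleaching and
#' Gaussian localization noise.
#'
#' @param roiSide side of the square region of interest, micrometres.
#' @param frameTime frame interval, seconds (0.02 = 50 Hz).
#' @param duration acquisition duration, seconds.
#' @param clusterDensity nanocluster density, clusters per square
#'   micrometre; ignored when \code{nClusters} is given.
#' @param nClusters optional fixed number of clusters.
#' @param clusterRadius nanocluster radius, micrometres.
#' @param clusterBirthTime time at which clusters appear, seconds (0 =
#'   present throughout; set to \code{stimTime} to model
#'   stimulation-induced cluster formation).
#' @param clusterDeathTime time at which clusters disappear (clipped to
#'   \code{duration}).
#' @param dFree free (membrane) diffusion coefficient, um^2/s.
#' @param dConfined in-cluster diffusion coefficient, um^2/s; must not
#'   exceed \code{dFree}.
#' @param recruitmentRatePre,recruitmentRatePost molecular appearance
#'   rates before/after \code{stimTime}, appearances per um^2 per s.
#' @param stimTime stimulation time, seconds.
#' @param trapProbability probability of capture at each outside-to-inside
#'   crossing of a live cluster footprint (also applied to molecules that
#'   appear directly inside a live cluster).
#' @param clusterAppearanceBoost relative appearance intensity inside
#'   live cluster footprints (1 = spatially uniform appearance). Cluster
#'   sites recruit directly from solution as well as laterally, so their
#'   appearance density is enhanced; the total appearance rate over the
#'   ROI is unchanged, only the spatial distribution is reshaped.
#' @param escapeRate rate of escape from the trapped state, per second.
#' @param bleachRate photobleaching rate, per second; detections per track
#'   are geometric with per-frame survival exp(-bleachRate*frameTime).
#' @param localizationSigma isotropic Gaussian localization error,
#'   micrometres.
#' @param seed integer seed; mandatory, all randomness derives from it.
#'
#' @return a list of class \code{simConfig}.
#' @export
simConfig <- function(roiSide = 10, frameTime = 0.02, duration = 60,
                      clusterDensity = 0.54, nClusters = NULL,
                      clusterRadius = 0.083,
                      clusterBirthTime = 0, clusterDeathTime = Inf,
                      dFree = 0.045, dConfined = 0.005,
                      recruitmentRatePre = 0.05, recruitmentRatePost = 0.2,
                      stimTime = 30, trapProbability = 0.5,
                      clusterAppearanceBoost = 20,
                      escapeRate = 0, bleachRate = 2.5,
                      localizationSigma = 0.02, seed = NULL) {
  cfg <- list(roiSide = roiSide, frameTime = frameTime, duration = duration,
              clusterDensity = clusterDensity, nClusters = nClusters,
              clusterRadius = clusterRadius,
              clusterBirthTime = clusterBirthTime,
              clusterDeathTime = clusterDeathTime,
              dFree = dFree, dConfined = dConfined,
              recruitmentRatePre = recruitmentRatePre,
              recruitmentRatePost = recruitmentRatePost,
              stimTime = stimTime, trapProbability = trapProbability,
              clusterAppearanceBoost = clusterAppearanceBoost,
              escapeRate = escapeRate, bleachRate = bleachRate,
              localizationSigma = localizationSigma, seed = seed)
  validateSimConfig(cfg)
  class(cfg) <- "simConfig"
  cfg
}

validateSimConfig <- function(cfg) {
  stopifnot(cfg$roiSide > 0, cfg$frameTime > 0)
  nonneg <- c("clusterDensity", "clusterRadius", "dFree", "dConfined",
              "recruitmentRatePre", "recruitmentRatePost", "escapeRate",
              "bleachRate", "localizationSigma")
  for (f in nonneg)
    if (!is.null(cfg[[f]]) && cfg[[f]] < 0)
      stop(sprintf("'%s' must be >= 0", f))
  if (cfg$dConfined > cfg$dFree)
    stop("dConfined must not exceed dFree")
  if (cfg$trapProbability < 0 || cfg$trapProbability > 1)
    stop("trapProbability must be in [0, 1]")
  if (!is.null(cfg$clusterAppearanceBoost) && cfg$clusterAppearanceBoost <= 0)
    stop("clusterAppearanceBoost must be > 0")
  if (cfg$clusterRadius > cfg$roiSide / 2)
    stop("clusterRadius exceeds half the ROI side")
  invisible(TRUE)
}

#' Generate a nanocluster layout
#'
#' Places clusters either uniformly at random (Poisson count with mean
#' density * area, unless \code{nClusters} is fixed) or on a regular grid
#' at the configured density. Cluster lifetimes come from
#' \code{clusterBirthTime}/\code{clusterDeathTime} (death clipped to the
#' acquisition duration).
#'
#' @param config a \code{\link{simConfig}}.
#' @param mode \code{"uniform"} (random placement) or \code{"grid"}
#'   (regular lattice with spacing 1/sqrt(density)).
#' @return data.frame with columns \code{cluster}, \code{x}, \code{y},
#'   \code{radius}, \code{birth}, \code{death}.
#' @export
simulateClusterField <- function(config, mode = c("uniform", "grid")) {
  mode <- match.arg(mode)
  validateSimConfig(config)
  L <- config$roiSide
  birth <- min(config$clusterBirthTime, config$duration)
  death <- min(config$clusterDeathTime, config$duration)
  if (mode == "grid") {
    if (config$clusterDensity <= 0)
      return(data.frame(cluster = integer(), x = numeric(), y = numeric(),
                        radius = numeric(), birth = numeric(), death = numeric()))
    spacing <- 1 / sqrt(config$clusterDensity)
    centers <- seq(spacing / 2, L, by = spacing)
    g <- expand.grid(x = centers, y = centers)
    n <- nrow(g)
    return(data.frame(cluster = seq_len(n), x = g$x, y = g$y,
                      radius = rep(config$clusterRadius, n),
                      birth = rep(birth, n), death = rep(death, n)))
  }
  n <- if (!is.null(config$nClusters)) config$nClusters
       else stats::rpois(1, config$clusterDensity * L^2)
  data.frame(cluster = seq_len(n),
             x = stats::runif(n, 0, L), y = stats::runif(n, 0, L),
             radius = rep(config$clusterRadius, n),
             birth = rep(birth, n), death = rep(death, n))
}

# reflect a coordinate into [0, L] (reflecting ROI boundary)
.reflect <- function(z, L) {
  z <- z %% (2 * L)
  ifelse(z > L, 2 * L - z, z)
}

#' Generate a synthetic TrackSet with ground truth
#'
#' Molecules appear on the membrane as a Poisson process whose rate steps
#' from \code{recruitmentRatePre} to \code{recruitmentRatePost} at
#' \code{stimTime}, diffuse by 2D Brownian motion (per-axis step variance
#' 2*dFree*frameTime), and on each outside-to-inside crossing of a live
#' cluster footprint are captured with probability \code{trapProbability}.
#' Captured molecules switch to \code{dConfined} and reflect at the
#' cluster boundary until escape (rate \code{escapeRate}) or bleaching.
#' Track lengths are geometric (bleaching); every detection is perturbed
#' by isotropic Gaussian noise of sd \code{localizationSigma}. Output is
#' reproducible bit-for-bit given \code{config$seed}.
#'
#' @param config a \code{\link{simConfig}}; \code{seed} is mandatory.
#' @param clusterField optional pre-built cluster layout (as returned by
#'   \code{\link{simulateClusterField}}); by default one is drawn from the
#'   same seeded stream.
#' @param clusterMode placement mode passed to
#'   \code{\link{simulateClusterField}} when no layout is supplied.
#' @return list with elements \code{tracks} (a \code{\link{TrackSet}}) and
#'   \code{truth} (list: \code{clusters} layout, \code{tracks} data.frame
#'   with per-trajectory labels \code{trapped}, \code{entryStep} (0-based
#'   index of the first in-cluster detection), \code{hostCluster},
#'   \code{appearance} time).
#' @export
simulateTracks <- function(config, clusterField = NULL,
                           clusterMode = "uniform") {
  validateSimConfig(config)
  if (is.null(config$seed)) stop("config$seed is required for reproducibility")
  if (config$duration <= 0) stop("duration must be > 0")
  set.seed(config$seed)
  dt <- config$frameTime
  L <- config$roiSide
  nFrames <- floor(config$duration / dt)
  if (is.null(clusterField))
    clusterField <- simulateClusterField(config, mode = clusterMode)

  # appearance times: piecewise-constant Poisson process
  tPre <- min(config$stimTime, config$duration)
  nPre <- stats::rpois(1, config$recruitmentRatePre * L^2 * tPre)
  tPost <- max(config$duration - tPre, 0)
  nPost <- stats::rpois(1, config$recruitmentRatePost * L^2 * tPost)
  appear <- sort(c(stats::runif(nPre, 0, tPre),
                   stats::runif(nPost, tPre, config$duration)))
  nMol <- length(appear)

  pBleach <- 1 - exp(-config$bleachRate * dt)
  pEscape <- 1 - exp(-config$escapeRate * dt)
  sFree <- sqrt(2 * config$dFree * dt)
  sConf <- sqrt(2 * config$dConfined * dt)
  nc <- nrow(clusterField)
  cx <- clusterField$x; cy <- clusterField$y
  cr <- clusterField$radius; cb <- clusterField$birth; cd <- clusterField$death

  detList <- vector("list", nMol)
  trapped <- logical(nMol)
  entryStep <- rep(NA_integer_, nMol)
  hostCluster <- rep(NA_integer_, nMol)

  for (m in seq_len(nMol)) {
    f0 <- floor(appear[m] / dt)
    maxDet <- nFrames - f0
    if (maxDet < 1) { detList[[m]] <- NULL; next }
    # geometric number of detections (bleach-limited), capped at acquisition end
    nDet <- if (pBleach > 0) min(1L + stats::rgeom(1, pBleach), maxDet) else maxDet
    x <- numeric(nDet); y <- numeric(nDet)
    state <- 0L  # 0 = free, 1 = trapped
    host <- NA_integer_
    tNow <- f0 * dt
    live <- if (nc > 0) which(cb <= tNow & tNow <= cd) else integer(0)
    # appearance position: cluster sites recruit directly from solution,
    # so their appearance intensity is boosted by clusterAppearanceBoost
    # relative to the rest of the membrane (total rate unchanged)
    beta <- config$clusterAppearanceBoost
    if (is.null(beta)) beta <- 1
    fLive <- if (length(live)) min(sum(pi * cr[live]^2) / L^2, 1) else 0
    wClus <- beta * fLive / (1 + (beta - 1) * fLive)
    bornIn <- length(live) > 0 && stats::runif(1) < wClus
    if (bornIn) {
      ci <- if (length(live) > 1) live[sample.int(length(live), 1)] else live
      rr <- cr[ci] * sqrt(stats::runif(1))
      th <- stats::runif(1, 0, 2 * pi)
      x[1] <- .reflect(cx[ci] + rr * cos(th), L)
      y[1] <- .reflect(cy[ci] + rr * sin(th), L)
    } else {
      x[1] <- stats::runif(1, 0, L); y[1] <- stats::runif(1, 0, L)
    }
    # any appearance inside a live footprint (enriched or by chance) is a
    # direct-recruitment event and rolls the same capture probability
    inside0 <- FALSE
    if (nc > 0 && length(live) > 0) {
      d2 <- (x[1] - cx)^2 + (y[1] - cy)^2
      hit0 <- live[d2[live] <= cr[live]^2]
      inside0 <- length(hit0) > 0
      if (inside0 && stats::runif(1) < config$trapProbability) {
        state <- 1L
        host <- hit0[which.min(d2[hit0])]
        trapped[m] <- TRUE
        entryStep[m] <- 0L    # born inside the cluster
        hostCluster[m] <- host
      }
    }
    wasInside <- inside0 || state == 1L
    if (nDet > 1) for (k in 2:nDet) {
      tk <- (f0 + k - 1) * dt
      if (state == 0L) {
        x[k] <- .reflect(x[k - 1] + stats::rnorm(1, 0, sFree), L)
        y[k] <- .reflect(y[k - 1] + stats::rnorm(1, 0, sFree), L)
        if (nc > 0) {
          d2 <- (x[k] - cx)^2 + (y[k] - cy)^2
          live <- cb <= tk & tk <= cd
          hit <- which(live & d2 <= cr^2)
          isInside <- length(hit) > 0
          if (isInside && !wasInside &&
              stats::runif(1) < config$trapProbability) {
            state <- 1L
            host <- hit[which.min(d2[hit])]
            if (!trapped[m]) {
              trapped[m] <- TRUE
              entryStep[m] <- k - 1L   # 0-based detection index
              hostCluster[m] <- host
            }
          }
          wasInside <- isInside
        }
      } else {
        # confined diffusion, reflecting at the host cluster boundary
        px <- x[k - 1] + stats::rnorm(1, 0, sConf)
        py <- y[k - 1] + stats::rnorm(1, 0, sConf)
        dx <- px - cx[host]; dy <- py - cy[host]
        r <- sqrt(dx^2 + dy^2)
        if (r > cr[host]) {      # radial reflection into the disk
          rNew <- max(2 * cr[host] - r, 0)
          px <- cx[host] + dx / r * rNew
          py <- cy[host] + dy / r * rNew
        }
        x[k] <- px; y[k] <- py
        clusterDied <- tk > cd[host]
        if (clusterDied || (pEscape > 0 && stats::runif(1) < pEscape)) {
          state <- 0L
          wasInside <- TRUE
        }
      }
    }
    if (config$localizationSigma > 0) {
      x <- x + stats::rnorm(nDet, 0, config$localizationSigma)
      y <- y + stats::rnorm(nDet, 0, config$localizationSigma)
    }
    frames <- f0 + seq_len(nDet) - 1L
    detList[[m]] <- data.frame(id = m, x = x, y = y,
                               frame = as.integer(frames),
                               t = frames * dt)
  }

  keep <- !vapply(detList, is.null, logical(1))
  det <- if (any(keep)) do.call(rbind, detList[keep])
         else data.frame(id = integer(), x = numeric(), y = numeric(),
                         frame = integer(), t = numeric())
  ts <- methods::new("TrackSet", detections = det, frameTime = dt,
                     duration = config$duration, roiArea = L^2,
                     metadata = list(seed = config$seed))
  truthTracks <- data.frame(id = seq_len(nMol), appearance = appear,
                            trapped = trapped, entryStep = entryStep,
                            hostCluster = hostCluster)[keep, , drop = FALSE]
  list(tracks = ts,
       truth = list(clusters = clusterField, tracks = truthTracks))
}

#' Write or read simulation ground truth as JSON
#'
#' Serializes the ground-truth component of \code{\link{simulateTracks}}
#' (cluster layout and per-trajectory labels) so synthetic datasets can
#' be stored alongside their TRXYT files.
#'
#' @param truth the \code{truth} list from \code{\link{simulateTracks}}.
#' @param path output/input JSON path.
#' @return \code{writeGroundTruth}: \code{path} invisibly;
#'   \code{readGroundTruth}: the truth list.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(clusters = as.data.frame(raw$clusters),
       tracks = as.data.frame(raw$tracks))
}

#' Generate a synthetic fluorescence-intensity trace
#'
#' Builds \code{trace = baseline * curve(t) * exp(-bleachRate * t) +
#' Gaussian noise}, emulating a TIRF region-of-interest intensity time
#' course with photobleaching. Deterministic given \code{seed}.
#'
#' @param times numeric vector of sample times, seconds.
#' @param baseline positive baseline intensity (arbitrary units).
#' @param foldCurve optional function of time returning the model-derived
#'   relative intensity (default: flat, 1).
#' @param noiseSd Gaussian noise sd, intensity units (>= 0).
#' @param bleachRate photobleaching decay rate, per second (>= 0).
#' @param seed integer seed (required when \code{noiseSd > 0}).
#' @return data.frame with columns \code{time} and \code{fi}.
#' @export
simulateIntensityTrace <- function(times, baseline, foldCurve = NULL,
                                   noiseSd = 0, bleachRate = 0, seed = NULL) {
  stopifnot(baseline > 0, noiseSd >= 0)
  if (bleachRate < 0) stop("bleachRate must be >= 0")
  curve <- if (is.null(foldCurve)) rep(1, length(times)) else foldCurve(times)
  fi <- baseline * curve * exp(-bleachRate * times)
  if (noiseSd > 0) {
    if (is.null(seed)) stop("seed is required when noiseSd > 0")
    set.seed(seed)
    fi <- fi + stats::rnorm(length(times), 0, noiseSd)
  }
  data.frame(time = times, fi = fi)
}
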