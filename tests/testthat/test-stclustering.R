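test_that("pseudo-spatial transform maps the time window onto epsilon", {
  det <- data.frame(x = c(1, 1), y = c(2, 2), t = c(0, 10))
  p <- pseudoSpatialTransform(det, epsilon = 0.05, timeWindow = 10)
  expect_equal(sqrt(sum((p[2, ] - p[1, ])^2)), 0.05)
  det$t <- c(0, 5)
  p <- pseudoSpatialTransform(det, 0.05, 10)
  expect_equal(sqrt(sum((p[2, ] - p[1, ])^2)), 0.025)
  # uniform time shift leaves pairwise distances unchanged
  set.seed(5)
  det <- data.frame(x = runif(50), y = runif(50), t = runif(50, 0, 100))
  d1 <- dist(pseudoSpatialTransform(det, 0.05, 10))
  det$t <- det$t + 37.3
  d2 <- dist(pseudoSpatialTransform(det, 0.05, 10))
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-12)
})

test_that("dbscan3d handles degenerate inputs", {
  pts <- matrix(runif(9), 3, 3)
  expect_true(all(dbscan3d(pts, 1e-6, 8) == -1L))
  co <- matrix(rep(c(0.5, 0.5, 0.5), 8), ncol = 3, byrow = TRUE)
  expect_true(all(dbscan3d(co, 0.05, 8) == 1L))
  expect_identical(dbscan3d(co[0, , drop = FALSE], 0.05, 8), integer(0))
})

test_that("dbscan3d labels match the brute-force oracle", {
  set.seed(17)
  for (rep in 1:6) {
    # mixtures of dense blobs and uniform noise exercise border cases
    nb <- sample(1:5, 1)
    blob <- do.call(rbind, lapply(seq_len(nb), function(i) {
      c0 <- runif(3)
      cbind(rnorm(30, c0[1], 0.02), rnorm(30, c0[2], 0.02),
            rnorm(30, c0[3], 0.02))
    }))
    nNoise <- sample(50:350, 1)
    pts <- rbind(blob, matrix(runif(3 * nNoise, 0, 1), ncol = 3))
    stopifnot(nrow(pts) <= 500)
    eps <- runif(1, 0.03, 0.1)
    minPts <- sample(3:8, 1)
    expect_identical(dbscan3d(pts, eps, minPts),
                     oracleDbscan(pts, eps, minPts))
  }
})

test_that("raising minPoints never increases the cluster count", {
  set.seed(19)
  pts <- rbind(matrix(rnorm(300, 0.5, 0.03), ncol = 3),
               matrix(runif(300), ncol = 3))
  counts <- vapply(2:10, function(mp) {
    labs <- dbscan3d(pts, 0.06, mp)
    length(unique(labs[labs > 0]))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("cluster summaries: density, circle radius, screening", {
  # 3 trajectories of 8 co-located detections -> one cluster in 10 um^2
  mk <- function(id, x0, t0) data.frame(
    id = id, x = x0 + rep(0, 8), y = 0.5, frame = round(t0 / 0.02) + 0:7,
    t = t0 + (0:7) * 0.02)
  ts <- makeTrackSet(list(mk(1, 0.5, 0), mk(2, 0.5, 0.2), mk(3, 0.5, 0.4)),
                     roiArea = 10)
  scs <- clusterTracks(ts, clusteringParams("boosh"))
  expect_identical(nrow(clusters(scs)), 1L)
  cm <- clusterMetrics(scs)
  expect_equal(cm$density, 0.1)

  # members evenly on a circle of radius r -> RMS radius r
  r <- 0.03
  ang <- seq(0, 2 * pi, length.out = 25)[-25]
  circ <- lapply(1:3, function(i) {
    a <- ang[seq(i, 24, by = 3)]
    data.frame(id = i, x = 0.5 + r * cos(a), y = 0.5 + r * sin(a),
               frame = round(((i - 1) * 0.2) / 0.02) + seq_along(a) - 1,
               t = (i - 1) * 0.2 + (seq_along(a) - 1) * 0.02)
  })
  scs2 <- clusterTracks(makeTrackSet(circ, roiArea = 10),
                        clusteringParams("boosh", minTrajLength = 8))
  expect_identical(nrow(clusters(scs2)), 1L)
  expect_equal(clusters(scs2)$radius, r, tolerance = 1e-9)

  # a cluster wider than the size screen is discarded
  wide <- lapply(1:3, function(i)
    data.frame(id = i, x = 0.5 + seq(0, 0.6, by = 0.04),
               y = 0.5, frame = round(((i - 1) * 0.32) / 0.02) + 0:15,
               t = (i - 1) * 0.32 + (0:15) * 0.02))
  scs3 <- clusterTracks(makeTrackSet(wide, roiArea = 10),
                        clusteringParams("boosh"))
  expect_identical(nrow(clusters(scs3)), 0L)
})

test_that("clustering is invariant to translation and time shift", {
  sim <- simulateTracks(simConfig(seed = 23, duration = 20,
                                  trapProbability = 1, clusterDensity = 1))
  ts <- sim$tracks
  p <- clusteringParams("boosh")
  ref <- clusterTracks(ts, p)
  d <- detections(ts)
  d$x <- d$x + 3.7; d$y <- d$y - 1.2; d$t <- d$t + 11
  ts2 <- methods::new("TrackSet", detections = d, frameTime = 0.02,
                      duration = 31, roiArea = 100, metadata = list())
  shifted <- clusterTracks(ts2, p)
  expect_identical(nrow(clusters(shifted)), nrow(clusters(ref)))
  expect_equal(clusters(shifted)$x, clusters(ref)$x + 3.7, tolerance = 1e-9)
  expect_equal(clusters(shifted)$tStart, clusters(ref)$tStart + 11,
               tolerance = 1e-9)
  expect_equal(clusters(shifted)$radius, clusters(ref)$radius,
               tolerance = 1e-9)
})

test_that("planted nanoclusters are recovered (Jaccard >= 0.5) at the
          populated-site density", {
  # 0.54 clusters/um^2 field with 10 s cluster lifetimes; enriched
  # in-cluster recruitment gives each site a few trapped trajectories,
  # as in the measured per-cluster trajectory rates
  cfg <- simConfig(seed = 29, roiSide = 7, duration = 20, nClusters = 26,
                   clusterBirthTime = 2, clusterDeathTime = 12,
                   clusterDensity = 0.54, trapProbability = 1,
                   clusterAppearanceBoost = 300,
                   escapeRate = 0, bleachRate = 2.5,
                   recruitmentRatePre = 0.3, recruitmentRatePost = 0.3,
                   stimTime = 100, localizationSigma = 0.02)
  sim <- simulateTracks(cfg)
  tsF <- filterTracks(sim$tracks)
  scs <- clusterTracks(tsF, clusteringParams("boosh", minPoints = 8))
  lay <- sim$truth$clusters
  asg <- scs@assignments
  d <- detections(tsF)
  insideOf <- function(i, dd) {
    (dd$x - lay$x[i])^2 + (dd$y - lay$y[i])^2 <= lay$radius[i]^2 &
      dd$t >= 2 & dd$t <= 12
  }
  support <- vapply(seq_len(nrow(lay)),
                    function(i) sum(insideOf(i, d)), numeric(1))
  nTrajIn <- vapply(seq_len(nrow(lay)), function(i)
    length(unique(d$id[insideOf(i, d)])), numeric(1))
  # sites that actually accumulated a detectable cluster (>= minPoints
  # detections from >= clusterThreshold trajectories)
  eligible <- support >= 8 & nTrajIn >= 3
  expect_gt(sum(eligible), 10)
  # a planted site counts as recovered when one detected cluster covers
  # its member detections with Jaccard >= 0.5
  recovered <- vapply(seq_len(nrow(lay)), function(i) {
    tru <- which(insideOf(i, asg))
    if (!length(tru)) return(FALSE)
    labs <- asg$cluster[tru]; labs <- labs[labs > 0]
    if (!length(labs)) return(FALSE)
    best <- as.integer(names(which.max(table(labs))))
    mem <- which(asg$cluster == best)
    length(intersect(tru, mem)) / length(union(tru, mem)) >= 0.5
  }, logical(1))
  expect_gte(mean(recovered[eligible]), 0.8)
  # recovered-site density agrees with the populated-site density
  densTrue <- sum(eligible) / 49
  densRec <- sum(recovered & eligible) / 49
  expect_lt(abs(densRec - densTrue), 0.2 * densTrue)
})

test_that("hotspot definition: co-location with disjoint lifetimes", {
  tab <- function(...) data.frame(...)
  one <- makeClusterSet(tab(cluster = 1, x = 1, y = 1, radius = 0.1,
                            tStart = 0, tEnd = 5), roiArea = 10)
  expect_equal(detectHotspots(one), 0)
  two <- makeClusterSet(tab(cluster = 1:2, x = c(1, 1.05), y = 1,
                            radius = 0.1, tStart = c(0, 10),
                            tEnd = c(5, 15)), roiArea = 10)
  expect_equal(detectHotspots(two), 100)
  far <- makeClusterSet(tab(cluster = 1:2, x = c(1, 2), y = 1,
                            radius = 0.1, tStart = c(0, 10),
                            tEnd = c(5, 15)), roiArea = 10)
  expect_equal(detectHotspots(far), 0)
  # overlapping in time at the same spot: not a hotspot
  overlap <- makeClusterSet(tab(cluster = 1:2, x = c(1, 1.05), y = 1,
                                radius = 0.1, tStart = c(0, 3),
                                tEnd = c(5, 15)), roiArea = 10)
  expect_equal(detectHotspots(overlap), 0)
})

test_that("trajectory rates before/during follow the counting rule", {
  scs <- makeClusterSet(data.frame(cluster = 1, x = 1, y = 1,
                                   radius = 0.1, tStart = 10, tEnd = 12),
                        roiArea = 100)
  mkDet <- function(id, t0) data.frame(id = id, x = 1, y = 1,
                                       frame = round(t0 / 0.02),
                                       t = t0)
  # 4 trajectories during the 2 s lifetime, 1 in the 2 s before
  ts <- makeTrackSet(list(mkDet(1, 10.5), mkDet(2, 11), mkDet(3, 11.5),
                          mkDet(4, 12), mkDet(5, 9)), duration = 15)
  r <- trajectoryRates(scs, ts)
  expect_equal(r$rateDuring, 2.0)
  expect_equal(r$rateBefore, 0.5)

  # nothing near the footprint
  tsFar <- makeTrackSet(list(mkDet(1, 10.5)), duration = 15)
  tsFar@detections$x <- 5
  rFar <- trajectoryRates(scs, tsFar)
  expect_equal(rFar$rateDuring, 0)
  expect_equal(rFar$rateBefore, 0)

  # clipped before-window is normalized by its actual length
  scsEarly <- makeClusterSet(data.frame(cluster = 1, x = 1, y = 1,
                                        radius = 0.1, tStart = 1,
                                        tEnd = 3), roiArea = 100)
  rEarly <- trajectoryRates(scsEarly, makeTrackSet(list(mkDet(1, 0.5)),
                                                   duration = 15))
  expect_equal(rEarly$rateBefore, 1)   # 1 trajectory / 1 s actual window

  zero <- makeClusterSet(data.frame(cluster = 1, x = 1, y = 1,
                                    radius = 0.1, tStart = 5, tEnd = 5),
                         roiArea = 100)
  expect_warning(rz <- trajectoryRates(zero, ts), "zero-lifetime")
  expect_true(is.na(rz$rateDuring))
})

test_that("detected clusters recruit faster during their lifetime", {
  cfg <- simConfig(seed = 37, duration = 120, stimTime = 40,
                   clusterBirthTime = 40, clusterDensity = 1,
                   trapProbability = 0.9, escapeRate = 0,
                   recruitmentRatePre = 0.1, recruitmentRatePost = 0.25,
                   bleachRate = 1.5)
  sim <- simulateTracks(cfg)
  tsF <- filterTracks(sim$tracks)
  scs <- clusterTracks(tsF, clusteringParams("boosh"))
  expect_gt(nrow(clusters(scs)), 3)
  r <- trajectoryRates(scs, tsF)
  ok <- stats::complete.cases(r)
  expect_gt(mean(r$rateDuring[ok] > r$rateBefore[ok]), 0.5)
})
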