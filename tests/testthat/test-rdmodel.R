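test_that("geometry arithmetic matches the printed design values", {
  g <- buildGeometry(0.54, clusterRadius = 0.083)
  expect_equal(g@area, 1 / 0.54, tolerance = 1e-12)
  expect_equal(round(g@area, 2), 1.85)
  expect_equal(round(g@side, 2), 1.36)
  g2 <- buildGeometry(3.1, clusterRadius = 0.096)
  expect_equal(round(g2@side, 3), 0.568)
  g3 <- buildGeometry(1, clusterRadius = 0.083)
  expect_equal(g3@side, 1)
  expect_equal(g3@df, 190)
  expect_error(buildGeometry(0.5, clusterRadius = 1), "exceeds")
})

test_that("equilibrium off-rate follows the steady-state condition", {
  expect_equal(equilibriumKb(10, 4.85, 30, 0.09), 0.1455)
  expect_equal(equilibriumKb(1, 7, 7, 0.09), 0.09)   # rMem = dMem
  expect_error(equilibriumKb(10, 4.85, 0, 0.09), "dMem")
})

test_that("unit conversions are exact and invertible", {
  g <- buildGeometry(0.54, clusterRadius = 0.083)
  expect_equal(convertUnits(1, "uM", "copies_per_um3", g), 602.214)
  expect_equal(convertUnits(10, "copies_per_um2", "copies", g),
               10 * g@area, tolerance = 1e-12)
  expect_equal(round(convertUnits(10, "copies_per_um2", "copies", g), 1),
               18.5)
  x <- 3.7
  for (u in c("copies_per_um3", "copies_per_um2", "copies")) {
    expect_equal(convertUnits(convertUnits(x, "uM", u, g), u, "uM", g), x,
                 tolerance = 1e-12)
  }
  expect_error(convertUnits(1, "uM", "furlongs", g), "unknown units")
  expect_error(convertUnits(1, "uM", "copies"), "geometry")
})

test_that("the pre-cluster equilibrium is stationary for the ODE", {
  m <- dynaminModel("dyn1bb-pre")
  m$init$aClus <- 0
  s <- simulateODE(m, tEnd = 400, times = seq(0, 400, by = 10))
  ref <- s@states[1, ]
  dev <- sweep(abs(sweep(s@states, 2, ref)), 2, pmax(abs(ref), 1e-12), "/")
  expect_lt(max(dev[, ref > 0]), 1e-6)
})

test_that("total dynamin and the recruiter pool obey their conservation laws", {
  m <- dynaminModel("dyn1bb-post")
  s <- simulateODE(m, tEnd = 4)
  cc <- stateCopies(s)
  dynTot <- cc[, "Dsol"] + cc[, "Dmem"] + cc[, "Dclus"] + cc[, "D2dclus"]
  expect_lt(diff(range(dynTot)) / dynTot[1], 1e-9)
  # free recruiter + membrane dynamin never increases once clusters exist
  rPool <- cc[, "Rmem"] + cc[, "Dmem"]
  expect_true(all(diff(rPool) <= 1e-9 * rPool[1]))
})

test_that("perturbed reversible binding relaxes at the linearized rate", {
  m <- dynaminModel("dyn1bb-pre")
  m$init$aClus <- 0
  m$rates$kMem <- 0; m$rates$kDyn <- 0
  # unperturbed equilibrium concentrations in uM
  eq <- c(Dsol = m$init$dSol,
          Rmem = m$init$rMem / (1.9 * 602.214),
          Dmem = m$init$dMem / (1.9 * 602.214))
  init <- m$init
  init$dMem <- init$dMem * 1.01       # small perturbation
  s <- simulateODE(init = init, rates = m$rates, geometry = m$geometry,
                   tEnd = 15, times = seq(0, 15, by = 0.05))
  dev <- s@states[, "Dmem"] - s@states[nrow(s@states), "Dmem"]
  # relaxation rate of A + B <=> C linearized about equilibrium
  lamTheory <- m$rates$kFrev * (eq[["Dsol"]] + eq[["Rmem"]]) + m$rates$kB
  sel <- seq_len(40)
  fit <- stats::lm(log(dev[sel]) ~ s@times[sel])
  expect_equal(-unname(stats::coef(fit)[2]), lamTheory, tolerance = 0.01)
})

test_that("stimulation transform conserves copies and updates geometry", {
  m <- dynaminModel("dyn1bb-pre")
  same <- applyStimulation(m, postDensity = 0.54, clusterRadius = 0.083,
                           densityScale = 1, kMemPost = m$rates$kMem)
  expect_equal(same$init, m$init)
  expect_equal(same$rates, m$rates)
  expect_equal(same$geometry@side, m$geometry@side)

  m10 <- m; m10$init$dMem <- 10
  post <- applyStimulation(m10, densityScale = 3)
  expect_equal(post$geometry@side, 1 / sqrt(3.1))
  expect_equal(round(post$geometry@side, 3), 0.568)
  expect_equal(post$init$dMem, 30)
  expect_equal(m10$init$dSol - post$init$dSol, 20 / (1.9 * 602.214),
               tolerance = 1e-12)
  # total copies per unit membrane area are conserved
  tot <- function(mm) mm$geometry@vOverA * 602.214 * mm$init$dSol +
    mm$init$dMem
  expect_equal(tot(post), tot(m10), tolerance = 1e-12)

  big <- m; big$init$dSol <- 0.01
  expect_error(applyStimulation(big, densityScale = 50), "negative")
})

test_that("observables: normalization, lateral fraction, monotonicity", {
  m <- dynaminModel("dyn1bb-post")
  s <- simulateODE(m, tEnd = 4)
  ob <- observables(s)
  expect_equal(ob$relDensity[1], 1)
  expect_true(all(ob$fraction2D >= 0 & ob$fraction2D <= 1))

  # switching the purely-2D channels off leaves only 3D arrival
  m3d <- m
  m3d$rates$kMem2D <- 0; m3d$rates$kDyn2D <- 0
  ob3d <- observables(simulateODE(m3d, tEnd = 4))
  expect_true(all(ob3d$fraction2D == 0))

  # more membrane-bound dynamin shifts recruitment to the 2D route
  peakF2d <- vapply(c(10, 30, 60), function(dm) {
    mm <- m; mm$init$dMem <- dm
    max(observables(simulateODE(mm, tEnd = 4))$fraction2D)
  }, numeric(1))
  expect_true(all(diff(peakF2d) > 0))

  # stimulation increases the lateral share for the short-tail preset
  obPre <- observables(simulateODE(dynaminModel("dyn1bb-pre"), tEnd = 4))
  expect_gte(max(ob$fraction2D), max(obPre$fraction2D))
})

test_that("relative intensity offset selection solves the fold equation", {
  tr <- data.frame(time = 0:10, fi = c(1, 1.2, 1.5, 2, 1.8, 1.6, 1.5,
                                       1.4, 1.3, 1.2, 1.1))
  expect_equal(relIntensity(tr, 0)$relIntensity, tr$fi / tr$fi[1])
  expect_equal(chooseOffset(data.frame(time = 0:1, fi = c(1, 2)), 3), 0.5)
  d <- chooseOffset(tr, 5)
  expect_equal(max(relIntensity(tr, d)$relIntensity), 5, tolerance = 1e-9)
  expect_error(chooseOffset(tr, 1.5), "foldTarget")
  expect_error(relIntensity(tr, 2), "delta")
})

test_that("chi-square objective closed forms and guards", {
  x <- sin(1:20)
  expect_equal(chi2Objective(x, x, rep(1, 20)), 0)
  expect_equal(chi2Objective(x + 0.3, x, rep(1, 20)), 20 * 0.09,
               tolerance = 1e-12)
  expect_error(chi2Objective(x, x, rep(0, 20)), "zero")
  expect_error(chi2Objective(x, x[1:3], rep(1, 3)), "time grid")
})

test_that("the GA minimizes a known function reproducibly", {
  obj <- function(p) (p[["a"]] - 0.3)^2 + (p[["b"]] + 2)^2
  ranges <- list(a = c(-1, 1), b = c(-5, 5))
  fit <- fitGA(obj, ranges, popSize = 30, generations = 40, seed = 9)
  expect_lt(abs(fit$par[["a"]] - 0.3), 0.05)
  expect_lt(abs(fit$par[["b"]] + 2), 0.05)
  fit2 <- fitGA(obj, ranges, popSize = 30, generations = 40, seed = 9)
  expect_identical(fit$par, fit2$par)
  expect_true(all(diff(fit$trace) <= 0))    # elitism: monotone best
  expect_error(fitGA(obj, ranges, seed = NULL), "seed")
  expect_error(fitGA(obj, list(a = c(1, 1)), seed = 1), "non-degenerate")
})

test_that("SSA: frozen limits, exact conservation and titration control", {
  m <- dynaminModel("dyn1bb-pre")
  zero <- m
  zero$rates <- list(kFrev = 0, kB = 0, kMem = 0, kDyn = 0)
  s0 <- simulateSSA(zero, tEnd = 2, seed = 3)
  expect_true(all(apply(s0$copies, 2, function(v) all(v == v[1]))))
  expect_identical(s0$events, 0L)

  s1 <- simulateSSA(m, tEnd = 4, seed = 5)
  dynTot <- s1$copies[, "Dsol"] + s1$copies[, "Dmem"] +
    s1$copies[, "Dclus"] + s1$copies[, "D2dclus"]
  expect_true(all(dynTot == dynTot[1]))     # exact without titration

  withTit <- simulateSSA(m, tEnd = 0.25, seed = 7, titration = c(100, 10))
  dsolUM <- withTit$copies[, "Dsol"] / (602.214 * m$geometry@volume)
  expect_lt(abs(mean(dsolUM[-1]) - 10), 0.5)
})

test_that("SSA fluctuates about the equilibrium without drift", {
  m <- dynaminModel("dyn1bb-pre")
  g <- m$geometry
  init <- m$init
  init$aClus <- 0
  # integer-rounded pools with the matching equilibrium off-rate
  init$rMem <- round(init$rMem * g@area) / g@area
  init$dMem <- round(init$dMem * g@area) / g@area
  init$dSol <- round(init$dSol * 602.214 * g@volume) / (602.214 * g@volume)
  rates <- m$rates
  rates$kB <- equilibriumKb(init$dSol, init$rMem, init$dMem, rates$kFrev)
  finals <- vapply(1:48, function(s) {
    r <- simulateSSA(init = init, rates = rates, geometry = g,
                     tEnd = 10, seed = 400 + s,
                     recordTimes = c(0, 10))
    r$copies[2, "Dmem"]
  }, numeric(1))
  se <- stats::sd(finals) / sqrt(48)
  expect_lt(abs(mean(finals) - round(m$init$dMem * g@area)), 3 * se)
})

test_that("SSA ensemble mean tracks the ODE at enlarged copy numbers", {
  m <- dynaminModel("dyn1bb-pre")
  gBig <- buildGeometry(0.054, clusterRadius = 0.083)   # 10x area
  init <- m$init
  init$rMem <- round(init$rMem * gBig@area) / gBig@area
  init$dMem <- round(init$dMem * gBig@area) / gBig@area
  init$aClus <- round(init$aClus * gBig@clusterArea) / gBig@clusterArea
  init$dSol <- round(init$dSol * 602.214 * gBig@volume) /
    (602.214 * gBig@volume)
  rates <- m$rates
  rates$kB <- equilibriumKb(init$dSol, init$rMem, init$dMem, rates$kFrev)
  runs <- vapply(1:48, function(s)
    ssaDynCopies(simulateSSA(init = init, rates = rates, geometry = gBig,
                             tEnd = 4, seed = s)),
    numeric(81))
  mu <- rowMeans(runs)
  se <- apply(runs, 1, stats::sd) / sqrt(48)
  ode <- simulateODE(init = init, rates = rates, geometry = gBig,
                     times = seq(0, 4, length.out = 81), tEnd = 4)
  target <- observables(ode)$dynCopies
  expect_lt(max(abs(mu - target)[-1] / se[-1]), 3)
})

test_that("membrane PDE reduces to the ODE in the fast-diffusion limit", {
  m <- dynaminModel("dyn1bb-post")
  p <- simulateMembranePDE(m, tEnd = 4, dMem = 50, dt = 0.01)
  ode <- simulateODE(m, times = p$times, tEnd = 4)
  cc <- stateCopies(ode)
  for (sp in colnames(cc)) {
    rel <- max(abs(p$copies[, sp] - cc[, sp]) / pmax(abs(cc[, sp]), 1e-6))
    expect_lt(rel, 0.02)
  }
})

test_that("pure diffusion of a Gaussian bump follows the heat kernel", {
  m <- dynaminModel("dyn1bb-pre")
  zero <- m
  zero$rates <- list(kFrev = 0, kB = 0, kMem = 0, kDyn = 0)
  L <- m$geometry@side
  nx <- round(L / 0.015)
  hcell <- L / nx
  xc <- (seq_len(nx) - 0.5) * hcell - L / 2
  gx <- matrix(xc, nx, nx); gy <- t(gx)
  s0 <- 0.05
  bump <- 100 * exp(-(gx^2 + gy^2) / (2 * s0^2))
  dMem <- 0.02
  p <- simulateMembranePDE(zero, tEnd = 1, dMem = dMem, dt = 0.005,
                           initFields = list(Dmem = bump))
  # infinite-plane solution: peak height scales as s0^2/(s0^2 + 2 D t)
  peakTheory <- 100 * s0^2 / (s0^2 + 2 * dMem * 1)
  expect_lt(abs(max(p$fields$Dmem) - peakTheory) / peakTheory, 0.05)
})

test_that("a depletion halo forms around the growing cluster", {
  m <- dynaminModel("dyn1bb-post")
  p <- simulateMembranePDE(m, tEnd = 4, dMem = 0.045)
  inside <- mean(p$fields$Dmem[p$mask])
  outside <- mean(p$fields$Dmem[!p$mask])
  expect_lt(inside, outside)
  expect_error(simulateMembranePDE(m, grid = 0.06), "grid too coarse")
})

test_that("every simulator is stationary at the cluster-free equilibrium", {
  m <- dynaminModel("dyn1bb-pre")
  m$init$aClus <- 0
  sOde <- simulateODE(m, tEnd = 50, times = c(0, 50))
  expect_equal(sOde@states[2, ], sOde@states[1, ], tolerance = 1e-7)
  p <- simulateMembranePDE(m, tEnd = 2, dMem = 0.045, dt = 0.01)
  expect_equal(unname(p$copies[nrow(p$copies), ]), unname(p$copies[1, ]),
               tolerance = 1e-6)
})
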