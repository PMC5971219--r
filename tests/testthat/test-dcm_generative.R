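test_that("neural derivative implements the bilinear form", {
  spec <- tinyTruth()
  z <- c(0.5, -0.2, 0.1)
  u <- c(1, 0.5)
  Aeff <- spec@A + u[1] * spec@B$V + u[2] * spec@B$NV
  expect_equal(neuralDerivative(z, u, spec),
               drop(Aeff %*% z + spec@C %*% u), tolerance = 1e-12)
  # B = 0: the system is jointly linear in (z, u)
  spec0 <- dcmSpec(spec@regions, spec@A,
                   list(V = 0 * spec@A, NV = 0 * spec@A), spec@C,
                   spec@inputs)
  z2 <- c(-0.3, 0.4, 0.9); u2 <- c(0.2, -0.1)
  expect_equal(neuralDerivative(z + z2, u + u2, spec0),
               neuralDerivative(z, u, spec0) +
                 neuralDerivative(z2, u2, spec0), tolerance = 1e-9)
  expect_error(neuralDerivative(c(1, 2), u, spec), "dimension")
})

test_that("integrated neural states match the matrix-exponential oracle", {
  # constant input: dz/dt = (A + u B) z + C u has the closed form
  # z(t) = Aeff^-1 (expm(Aeff t) - I) C u from rest
  spec <- tinyTruth()
  hemo <- hemodynamicParameters(3)
  u <- matrix(1, 2, 301)   # both inputs on, constant
  sim <- integrateDcm(spec, hemo, NULL, u, u_rate = 10, duration = 30,
                      dt = 0.02, out_rate = 10)
  Aeff <- spec@A + spec@B$V + spec@B$NV
  cu <- drop(spec@C %*% c(1, 1))
  for (tt in c(5, 15, 30)) {
    zExact <- drop(solve(Aeff, (as.matrix(Matrix::expm(Aeff * tt)) -
                                  diag(3)) %*% cu))
    zNum <- sim$z[, which.min(abs(sim$time - tt))]
    expect_equal(unname(zNum), unname(zExact), tolerance = 1e-6)
  }
})

test_that("balloon dynamics rest at the fixed point and peak plausibly", {
  p <- hemodynamicParameters(1)
  d0 <- hemodynamicDerivative(list(s = 0, f = 1, v = 1, q = 1), z = 0, p)
  expect_equal(unlist(d0), c(ds = 0, df = 0, dv = 0, dq = 0))
  # oxygen-extraction term normalised at rest flow
  ext <- (1 - (1 - p$E0)^(1 / 1)) / p$E0
  expect_equal(ext, 1)
  # a brief neuronal burst drives flow up with a peak 3-8 s later
  spec <- dcmSpec("R1", matrix(-0.5, 1, 1), list(inp = matrix(0, 1, 1)),
                  matrix(1, 1, 1), "inp")
  u <- matrix(0, 1, 401)
  u[1, 11:20] <- 1   # 1 s burst at t = 1
  sim <- integrateDcm(spec, hemodynamicParameters(1), NULL, u, 10, 40,
                      dt = 0.05, out_rate = 10)
  fpk <- sim$time[which.max(sim$f[1, ])]
  expect_gt(max(sim$f), 1)
  expect_true(fpk >= 1 + 3 && fpk <= 1 + 8)
  expect_lt(abs(sim$f[1, length(sim$time)] - 1), 0.05)  # returns to rest
})

test_that("chromophore mapping and its sign pattern during activation", {
  p <- hemodynamicParameters(1, HbT0 = 100, HbR0 = 40)
  expect_equal(chromophoreChanges(1, 1, p), list(dHc = 0, dQc = 0))
  ch <- chromophoreChanges(1.1, 0.9, p)
  expect_equal(ch$dQc, -4, tolerance = 1e-10)
  expect_equal(ch$dHc, 14, tolerance = 1e-10)
  # canonical response: oxy up, deoxy down
  spec <- dcmSpec("R1", matrix(-0.5, 1, 1), list(inp = matrix(0, 1, 1)),
                  matrix(1, 1, 1), "inp")
  u <- matrix(0, 1, 401); u[1, 11:100] <- 1
  sim <- integrateDcm(spec, hemodynamicParameters(1), NULL, u, 10, 40,
                      dt = 0.05, out_rate = 10)
  pk <- which.max(sim$dHc[1, ])
  expect_gt(sim$dHc[1, pk], 0)
  expect_lt(sim$dQc[1, pk], 0)
})

test_that("fNIRS observation is linear in chromophores and in k", {
  fx <- getFixture()
  om <- fx$obsModel
  n <- ncol(om$S0[["770"]])
  dH <- matrix(rnorm(n * 5), n, 5)
  dQ <- matrix(rnorm(n * 5), n, 5)
  y <- observeFnirs(dH, dQ, om)
  expect_identical(dim(y), c(18L, 5L))
  expect_equal(observeFnirs(0 * dH, 0 * dQ, om), 0 * y)
  om2 <- om; om2$k <- 2 * om$k
  expect_equal(observeFnirs(dH, dQ, om2), 2 * y, tolerance = 1e-12)
  # single region / channel, unit factors: y = epsH*dH + epsQ*dQ = 2 + 1
  om1 <- fnirsObservationModel(list(`770` = matrix(1, 1, 1),
                                    `850` = matrix(1, 1, 1)),
                               extinction = matrix(1, 2, 2), k = 1)
  expect_equal(drop(observeFnirs(matrix(2), matrix(1), om1)), c(3, 3))
  om1$k <- -1
  expect_error(observeFnirs(matrix(2), matrix(1), om1), "positive")
})

test_that("BOLD observation matches the static equation", {
  expect_equal(observeBold(1, 1), 0)
  # hand-computed at (v, q) = (1.1, 0.9), defaults V0=.04, E0=.32
  k1 <- 7 * 0.32; k2 <- 2; k3 <- 2 * 0.32 - 0.2
  yhand <- 0.04 * (k1 * 0.1 + k2 * (1 - 0.9 / 1.1) + k3 * (1 - 1.1))
  expect_equal(observeBold(1.1, 0.9), yhand, tolerance = 1e-12)
  expect_gt(observeBold(1, 0.9), observeBold(1, 1))  # monotone in -q
})

test_that("integrator is stable at rest and converges under step halving", {
  spec <- tinyTruth()
  hemo <- hemodynamicParameters(3)
  u0 <- matrix(0, 2, 601)
  sim0 <- integrateDcm(spec, hemo, NULL, u0, 10, 60, dt = 0.1, out_rate = 10)
  expect_lt(max(abs(sim0$z)), 1e-9)
  expect_lt(max(abs(sim0$dHc)), 1e-9)
  # smooth input, dt halving
  tgrid <- seq(0, 60, by = 0.1)
  uS <- rbind(exp(-(tgrid - 15)^2 / 18), exp(-(tgrid - 35)^2 / 30))
  s1 <- integrateDcm(spec, hemo, NULL, uS, 10, 60, dt = 0.1, out_rate = 10)
  s2 <- integrateDcm(spec, hemo, NULL, uS, 10, 60, dt = 0.05, out_rate = 10)
  rel <- max(abs(s1$dHc - s2$dHc)) / max(abs(s2$dHc))
  expect_lt(rel, 1e-4)
  # divergence guard
  specBad <- dcmSpec(spec@regions, diag(3) * 2, spec@B, spec@C, spec@inputs)
  expect_error(integrateDcm(specBad, hemo, NULL, uS, 10, 60, dt = 0.1,
                            out_rate = 10), "diverged")
  expect_error(integrateDcm(spec, hemo, NULL, uS, 10, 60, dt = 0.2,
                            out_rate = 10), "dt")
})

test_that("DCM specifications round-trip through JSON", {
  spec <- tinyTruth()
  tf <- tempfile(fileext = ".json")
  writeDcmJSON(spec, tf)
  back <- readDcmJSON(tf)
  expect_equal(back@A, spec@A)
  expect_equal(back@B$NV, spec@B$NV)
  expect_equal(back@C, spec@C)
  expect_identical(dcmStructure(back)$B$NV, dcmStructure(spec)$B$NV)
})
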