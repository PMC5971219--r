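test_that("optical coefficient tables are validated and kappa is derived", {
  co <- defaultOpticalCoefficients()
  expect_true(all(co$table$mua > 0) && all(co$table$mus > 0))
  expect_gte(co$A_boundary, 1)
  opt <- fnirsDCM:::coeffsForWavelength(co, c(1, 2, 3), 770)
  expect_equal(opt$kappa, 1 / (3 * (opt$mua + opt$mus)))
  expect_error(fnirsDCM:::coeffsForWavelength(co, c(1, 4), 770), "4")
  expect_error(opticalCoefficients(data.frame(tissue = 1, wavelength = 770,
                                              mua = -1, mus = 1)), "positive")
})

test_that("element mass matrix matches the closed-form P1 expression", {
  # single tetrahedron, mua-only medium: diagonal mua*V/10, off mua*V/20
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  elements <- matrix(1:4, 1, 4)
  mesh <- new("HeadMesh", nodes = nodes, elements = elements,
              elementLabel = 1L,
              boundaryFaces = matrix(integer(0), 0, 3))
  mua <- 0.25
  co <- opticalCoefficients(data.frame(tissue = 1, wavelength = 770,
                                       mua = mua, mus = 1e12))  # kappa ~ 0
  K <- as.matrix(assembleSystem(mesh, co, 770)$K)
  V <- 1 / 6
  expect_equal(diag(K), rep(mua * V / 10, 4), tolerance = 1e-9)
  expect_equal(K[1, 2], mua * V / 20, tolerance = 1e-9)
})

test_that("assembled diffusion system is symmetric positive definite", {
  mesh <- buildLayeredSlabMesh(c(30, 30, 21), c(5, 2, 14), 7)  # small
  sys <- assembleSystem(mesh, defaultOpticalCoefficients(), 770)
  K <- as.matrix(sys$K)
  expect_lt(max(abs(K - t(K))), 1e-12)
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("fluence solves are linear in source power and decay laterally", {
  mesh <- smallMesh(5)
  sys <- assembleSystem(mesh, homogeneousOptics(), 770)
  f1 <- solveFluence(sys, c(20, 20, 0), source_power = 1)
  f2 <- solveFluence(sys, c(20, 20, 0), source_power = 2)
  expect_equal(f2$values, 2 * f1$values, tolerance = 1e-12)
  at <- function(p) {
    i <- which.min(colSums((t(mesh@nodes) - p)^2))
    f1$values[i]
  }
  expect_gt(at(c(30, 20, 5)), at(c(40, 20, 5)))  # 10 mm vs 20 mm offset
  expect_error(solveFluence(sys, c(500, 500, -50)), "outside")
})

test_that("analytic semi-infinite fluence has the image-source structure", {
  mua <- 0.01; mus <- 1.0; A <- 2.82
  kappa <- 1 / (3 * (mua + mus))
  # effective attenuation from the printed diffusion-coefficient definition
  expect_equal(sqrt(mua / kappa), sqrt(3 * 0.01 * 1.01), tolerance = 1e-12)
  # decay to zero at large lateral distance
  expect_lt(analyticSemiInfiniteFluence(300, 5, mua, mus, A),
            1e-12 * analyticSemiInfiniteFluence(10, 5, mua, mus, A))
  # vanishes on the extrapolated boundary plane z = -zb
  zb <- 2 * A * kappa
  expect_equal(analyticSemiInfiniteFluence(7, -zb, mua, mus, A), 0,
               tolerance = 1e-15)
  expect_error(analyticSemiInfiniteFluence(0, 1 / mus, mua, mus, A),
               "source point")
})

test_that("sensitivity rows are reciprocal, near-nonnegative, and complete", {
  mesh <- smallMesh(2.5)  # fine enough that the far field stays positive
  sys <- assembleSystem(mesh, defaultOpticalCoefficients(), 770)
  f <- solveFluence(sys, c(10, 10, 0))
  a <- solveFluence(sys, c(30, 30, 0))
  I <- sum(a$load * f$values)
  s1 <- computeSensitivity(f, a, I)
  s2 <- computeSensitivity(a, f, I)
  expect_lt(max(abs(s1 - s2)) / max(abs(s1)), 1e-8)
  # tiny residual far-field undershoot from the P1 discretisation only
  expect_gt(min(s1), -1e-6 * max(s1))
  # node condensation preserves the element total
  sel <- computeSensitivity(f, a, I, granularity = "element")
  expect_equal(sum(s1), sum(sel), tolerance = 1e-10)
  expect_error(computeSensitivity(f, a, -1), "positive")
})

test_that("channel sensitivity matrix reuses solves across channels", {
  fx <- getFixture()
  S <- fx$S
  expect_identical(nrow(S@S0[["770"]]), 9L)
  expect_identical(nrow(S@S0[["850"]]), 9L)
  expect_identical(attr(fx$S, "n_solves"), 16L)  # (4+4) per wavelength
  # scalp nodes under a channel outweigh the deepest nodes
  mesh <- fx$mesh
  deep <- which(mesh@nodes[, 3] >= 25)
  shallow <- which(mesh@nodes[, 3] <= 5)
  for (ch in c(1, 5, 9)) {
    row <- S@S0[["770"]][ch, ]
    expect_gt(max(row[shallow]), max(row[deep]))
  }
})

test_that("region condensation is additive and complete", {
  fx <- getFixture()
  S <- fx$S
  all_nodes <- seq_len(ncol(S@S0[["770"]]))
  Sall <- regionSensitivity(S, list(everything = all_nodes))
  expect_equal(Sall@regionSensitivity[["770"]][, 1],
               rowSums(S@S0[["770"]]), tolerance = 1e-12)
  r1 <- 1:100; r2 <- 101:200
  Sparts <- regionSensitivity(S, list(a = r1, b = r2, ab = c(r1, r2)))
  m <- Sparts@regionSensitivity[["850"]]
  expect_equal(m[, "ab"], m[, "a"] + m[, "b"], tolerance = 1e-12)
  expect_error(regionSensitivity(S, list(empty = integer(0))), "empty")
  # the region under a channel's midpoint dominates that channel's row
  reg <- fx$regions
  m770 <- fx$S@regionSensitivity[["770"]]
  expect_equal(unname(which.max(m770["S1-D4", ])),
               unname(which(names(reg) == "IFG")))
})
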