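test_that("the 13-model space satisfies the published structural census", {
  space <- buildModelSpace()
  census <- modelSpaceCensus(space)
  expect_identical(unname(census), c(13, 91, 26, 8, 8))
  # shared skeleton: inputs drive STS only; A is the fixed bidirectional set
  for (m in space) {
    st <- dcmStructure(m)
    expect_identical(unname(which(st$C[, "V"])), which(m@regions == "STS"))
    expect_identical(unname(which(st$C[, "NV"])), which(m@regions == "STS"))
    offdiag <- st$A & !diag(3)
    expect_identical(sum(offdiag), 4L)
    # B only on inter-regional A connections
    for (b in st$B) expect_true(all(offdiag[b]))
  }
  # model 8: NV modulation on STS -> IFG, nothing else
  st8 <- dcmStructure(space[["model_8"]])
  expect_identical(sum(st8$B$V), 0L)
  expect_identical(which(st8$B$NV, arr.ind = TRUE)[1, ],
                   c(row = 1L, col = 2L))  # (IFG, STS): STS -> IFG
  expect_identical(space[["model_8"]]@regions[c(1, 2)], c("IFG", "STS"))
  # ordered enumeration: 2-5 V-only, 6-9 NV-only, 10-13 both
  conn <- modulableConnections()
  for (k in 1:4) {
    stV <- dcmStructure(space[[1 + k]])
    expect_identical(sum(stV$B$V), 1L)
    expect_identical(sum(stV$B$NV), 0L)
    expect_true(stV$B$V[conn$to[k], conn$from[k]])
    stBoth <- dcmStructure(space[[9 + k]])
    expect_true(stBoth$B$V[conn$to[k], conn$from[k]] &&
                  stBoth$B$NV[conn$to[k], conn$from[k]])
  }
})

test_that("fixed-effects BMS normalises, ranks, and shifts invariantly", {
  Fv <- c(m1 = 10, m2 = 10, m3 = 10)
  r <- bms(Fv)
  expect_equal(r$table$prob, rep(1 / 3, 3), tolerance = 1e-12)
  expect_identical(r$best, 1L)   # tie -> lowest index
  Fv2 <- c(0, 20, 0)
  r2 <- bms(Fv2)
  expect_gt(r2$table$prob[2], 0.999)
  # invariance to adding a constant
  r3 <- bms(Fv2 + 1234.5)
  expect_equal(r3$table$prob, r2$table$prob, tolerance = 1e-12)
  expect_equal(sum(r3$table$prob), 1, tolerance = 1e-12)
  expect_error(bms(list(NULL, NULL)), "missing fit")
})

test_that("BMA mixture moments follow the standard identities", {
  mkfit <- function(mu, va, F) {
    new("PosteriorFit", mean = mu, cov = diag(va, length(mu)),
        hyper = c(group1 = 0), F = F, accuracy = F, complexity = 0,
        trace = F, prediction = matrix(0, 1, 1), priors = list())
  }
  # single model with probability ~1
  f1 <- mkfit(c(a = 1, b = 2), 0.1, 100)
  f2 <- mkfit(c(a = -1, b = 0), 0.1, 0)
  r <- bms(list(f1, f2))
  out <- bma(list(f1, f2), r)
  expect_equal(out$mean[out$parameter == "a"], 1, tolerance = 1e-6)
  # equal-probability two-point mixture: mean 0, variance a^2
  g1 <- mkfit(c(x = 0.7), 0, 50)
  g2 <- mkfit(c(x = -0.7), 0, 50)
  rb <- bms(list(g1, g2))
  ob <- bma(list(g1, g2), rb)
  expect_equal(ob$mean, 0, tolerance = 1e-12)
  expect_equal(ob$variance, 0.49, tolerance = 1e-12)
  # absent parameter enters as point mass at zero
  h1 <- mkfit(c(x = 1, extra = 2), 0.01, 10)
  h2 <- mkfit(c(x = 1), 0.01, 10)
  oh <- bma(list(h1, h2), bms(list(h1, h2)))
  expect_equal(oh$mean[oh$parameter == "extra"], 1, tolerance = 1e-9)
  expect_gte(min(oh$variance), 0)
})

test_that("Pearson correlation matches the textbook formula", {
  x <- c(2, 4, 5, 7, 8, 11, 12, 14, 15, 18, 19, 21, 24)
  y <- 2 * x + 1
  expect_equal(pearson(x, y)$r, 1, tolerance = 1e-12)
  # orthogonal after centring
  xo <- c(-1, 0, 1)
  yo <- c(1, -2, 1)
  expect_lt(abs(pearson(xo, yo)$r), 1e-12)
  set.seed(2)
  yn <- y + rnorm(13, 0, 4)
  byHand <- sum((x - mean(x)) * (yn - mean(yn))) /
    sqrt(sum((x - mean(x))^2) * sum((yn - mean(yn))^2))
  pr <- pearson(x, yn)
  expect_equal(pr$r, byHand, tolerance = 1e-12)
  expect_true(pr$p > 0 && pr$p < 1)
  expect_error(pearson(rep(1, 5), 1:5), "variance")
})

test_that("bisquare robust regression resists a gross outlier", {
  set.seed(14)
  x <- seq(1, 20)
  y <- 2 + 0.5 * x + rnorm(20, 0, 0.2)
  clean <- robustRegression(x, y)
  ols <- coef(lm(y ~ x))
  expect_equal(clean$slope, unname(ols[2]), tolerance = 1e-3)
  expect_true(all(clean$weights >= 0 & clean$weights <= 1))
  # inject an outlier
  y2 <- y; y2[20] <- y2[20] - 30
  rob <- robustRegression(x, y2)
  olsBad <- unname(coef(lm(y2 ~ x))[2])
  expect_lt(abs(rob$slope - ols[2]) / ols[2], 0.05)
  expect_gt(abs(olsBad - ols[2]) / ols[2], 0.2)
  expect_lt(rob$weights[20], 0.1)
  expect_true(rob$R2 > 0 && rob$R2 <= 1)
  expect_true(rob$Fstat > 0)
})

test_that("bootstrap slope intervals are seeded, consistent, and shrink", {
  set.seed(41)
  x <- rnorm(20); y <- 1 + 0.8 * x + rnorm(20, 0, 0.3)
  b1 <- bootstrapRegression(x, y, n_boot = 200, seed = 99)
  b2 <- bootstrapRegression(x, y, n_boot = 200, seed = 99)
  expect_identical(b1$ci, b2$ci)
  expect_true(b1$ci[1] <= b1$slope && b1$slope <= b1$ci[2])
  xl <- rnorm(200); yl <- 1 + 0.8 * xl + rnorm(200, 0, 0.3)
  bl <- bootstrapRegression(xl, yl, n_boot = 200, seed = 99)
  expect_lt(diff(bl$ci), diff(b1$ci))
  expect_error(bootstrapRegression(x, y), "seed")
})
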