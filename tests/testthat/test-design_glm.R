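test_that("block design meets the session's trial structure", {
  d <- buildBlockDesign(seed = 11)
  expect_identical(nrow(d$events), 24L)
  expect_identical(as.integer(table(d$events$condition)[c("V", "NV")]),
                   c(12L, 12L))
  on <- d$events$onset
  expect_true(all(diff(on) >= 9 + 13))           # gaps >= duration + rest
  expect_true(all(on + d$events$duration <= 690))
  # determinism
  d2 <- buildBlockDesign(seed = 11)
  expect_identical(d$events, d2$events)
  d3 <- buildBlockDesign(seed = 12)
  expect_false(identical(d$events$onset, d3$events$onset))
  expect_error(buildBlockDesign(n_per_condition = 50, seed = 1),
               "infeasible")
  expect_error(buildBlockDesign(), "seed")
})

test_that("canonical HRF basis has the expected shape and derivatives", {
  b <- canonicalHrfBasis(10)
  t <- attr(b, "time")
  dt <- t[2] - t[1]
  expect_gt(sum(b[, "canonical"]) * dt, 0)
  # undershoot region negative
  expect_lt(min(b[t > 10 & t < 25, "canonical"]), 0)
  # peak between 5 and 7 s
  expect_true(t[which.max(b[, "canonical"])] >= 5 &&
                t[which.max(b[, "canonical"])] <= 7)
  # temporal derivative integrates to ~0
  expect_lt(abs(sum(b[, "temporal"])), 0.01 * abs(sum(b[, "canonical"])))
  expect_error(canonicalHrfBasis(-1), "positive")
})

test_that("design matrix encodes impulses convolved with the basis", {
  d <- buildBlockDesign(seed = 11)
  X <- buildDesignMatrix(d)
  expect_identical(ncol(X), 7L)  # 2 conditions x 3 bases + constant
  expect_true("constant" %in% colnames(X))
  expect_lt(max(abs(colMeans(X[, 1:6]))), 1e-12)
  # a single event's canonical column is the shifted HRF
  d1 <- d
  d1$events <- data.frame(condition = "V", onset = 10, duration = 9)
  b <- canonicalHrfBasis(10)
  X1 <- buildDesignMatrix(d1, b)
  col <- X1[, "V_canonical"] - mean(X1[, "V_canonical"]) + mean(X1[, "V_canonical"])
  onsetSample <- 10 * 10 + 1
  raw <- X1[, "V_canonical"] + mean(b[, "canonical"]) * 0  # centred copy
  shifted <- numeric(nrow(X1))
  shifted[onsetSample:(onsetSample + nrow(b) - 1)] <- b[, "canonical"]
  expect_equal(X1[, "V_canonical"], shifted - mean(shifted), tolerance = 1e-8)
  # empty design -> constant only
  d0 <- d
  d0$events <- d$events[0, ]
  X0 <- buildDesignMatrix(d0)
  expect_identical(colnames(X0), "constant")
})

test_that("GLM recovers noiseless coefficients and nulls calibrate", {
  d <- buildBlockDesign(seed = 11)
  X <- buildDesignMatrix(d)
  beta <- c(2, -1, 0.5, 1, 0, 0.2, 3)
  y <- drop(X %*% beta)
  fit <- fitGlm(y, X)
  expect_equal(unname(drop(fit$beta)), beta, tolerance = 1e-10)
  expect_lt(max(abs(fit$residuals)), 1e-9)
  # residual orthogonality on noisy data
  set.seed(21)
  yn <- y + rnorm(length(y))
  fitn <- fitGlm(yn, X)
  expect_lt(max(abs(crossprod(X, fitn$residuals))) /
              max(abs(crossprod(X, yn))), 1e-8)
  # mean shift hits only the constant
  fits <- fitGlm(yn + 10, X)
  expect_equal(drop(fits$beta[1:6, ]), drop(fitn$beta[1:6, ]),
               tolerance = 1e-8)
  expect_equal(unname(drop(fits$beta["constant", ])),
               unname(drop(fitn$beta["constant", ])) + 10, tolerance = 1e-8)
  # Monte-Carlo null for the V-vs-baseline contrast
  cv <- as.numeric(colnames(X) == "V_canonical")
  set.seed(22)
  tnull <- replicate(20, fitGlm(rnorm(nrow(X)), X, contrasts = cv)$t[1, 1])
  expect_true(all(abs(tnull) < 5))
})

test_that("eigenvariate summarises region signals up to scale and sign", {
  set.seed(31)
  base <- sin(seq(0, 6 * pi, length.out = 200))
  # single signal: proportional to its mean-centred course
  e1 <- extractEigenvariate(matrix(base, 1))
  expect_gt(abs(cor(e1, base)), 1 - 1e-10)
  # identical signals: explains all variance
  e2 <- extractEigenvariate(rbind(base, base))
  expect_equal(attr(e2, "varianceExplained"), 1, tolerance = 1e-12)
  # invariance to signal ordering
  sig <- rbind(base + rnorm(200, 0, .1), base + rnorm(200, 0, .1),
               -base + rnorm(200, 0, .1))
  ea <- extractEigenvariate(sig)
  eb <- extractEigenvariate(sig[c(3, 1, 2), ])
  expect_lt(max(abs(ea - eb)), 1e-9)
  # radius selection
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(10, 0, 0))
  er <- extractEigenvariate(sig, positions = pos, centre = c(0, 0, 0),
                            radius = 4)
  expect_error(extractEigenvariate(sig, positions = pos,
                                   centre = c(99, 99, 99), radius = 4),
               "no signals within")
})

test_that("design CSV round trip preserves the event table", {
  d <- buildBlockDesign(seed = 11)
  tf <- tempfile(fileext = ".csv")
  writeDesignCSV(d, tf)
  back <- readDesignCSV(tf)
  expect_equal(back$events$onset, d$events$onset, tolerance = 1e-9)
  expect_identical(back$events$condition, d$events$condition)
  expect_identical(back$session_length, d$session_length)
})
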