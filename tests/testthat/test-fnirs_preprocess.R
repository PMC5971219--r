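test_that("optical density conversion is exact and invertible", {
  set.seed(3)
  I <- matrix(exp(rnorm(40, 0, 0.1)), 4, 10)
  s <- channelTimeSeries(I, 10, "intensity")
  od <- intensityToOD(s)
  # constant intensity -> zero OD
  sc <- channelTimeSeries(matrix(7, 2, 8), 10, "intensity")
  expect_equal(seriesValues(intensityToOD(sc)), matrix(0, 2, 8))
  # I = I0/e -> OD = 1
  se <- channelTimeSeries(cbind(rep(1, 3), rep(1, 3), rep(exp(-1), 3)), 10,
                          "intensity")
  ode <- intensityToOD(se, baseline_window = 1:2)
  expect_equal(seriesValues(ode)[, 3], rep(1, 3), tolerance = 1e-12)
  # round trip
  back <- odToIntensity(od, attr(od, "I0"))
  expect_equal(seriesValues(back), I, tolerance = 1e-12)
  bad <- channelTimeSeries(matrix(c(1, -2, 3, 4), 2, 2), 10, "intensity")
  expect_error(intensityToOD(bad), "channel 2, sample 1")
})

test_that("MBLL round trip recovers concentrations exactly at DPF 5.13", {
  set.seed(8)
  n <- 50
  hbo <- matrix(rnorm(3 * n), 3, n)
  hbr <- matrix(rnorm(3 * n), 3, n)
  conc <- channelTimeSeries(rbind(hbo, hbr), 10, "concentration",
                            c(rep("HbO", 3), rep("HbR", 3)))
  od <- mbllForward(conc, distance = 20, dpf = 5.13)
  rec <- mbll(od, distance = 20, dpf = 5.13)
  expect_equal(seriesValues(rec)[1:3, ], hbo, tolerance = 1e-10)
  expect_equal(seriesValues(rec)[4:6, ], hbr, tolerance = 1e-10)
  # zero OD -> zero concentration
  z <- channelTimeSeries(matrix(0, 2, 5), 10, "optical_density",
                         c("770", "850"))
  expect_equal(seriesValues(mbll(z)), matrix(0, 2, 5))
  # doubling DPF halves recovered concentrations
  rec2 <- mbll(od, distance = 20, dpf = 2 * 5.13)
  expect_equal(seriesValues(rec2), seriesValues(rec) / 2, tolerance = 1e-10)
  # uninformative wavelength pair is rejected
  eps <- matrix(c(1, 1, 1, 1 + 1e-9), 2, 2)
  expect_error(mbll(od, extinction = eps), "uninformative")
})

test_that("Butterworth cascade attenuates stopbands and passes the rest", {
  # designed response: >20 dB down at 0.10 Hz, <1 dB change at 0.03 Hz
  g <- filterResponse(c(0.03, 0.10, 1.2), fs = 10)
  expect_gt(-20 * log10(g[2]), 20)
  expect_lt(abs(20 * log10(g[1])), 1)
  expect_gt(-20 * log10(g[3]), 20)
  # constant offset removed by the high-pass
  s <- channelTimeSeries(matrix(5, 2, 2000), 10, "concentration")
  f <- temporalFilter(s)
  expect_lt(max(abs(rowMeans(seriesValues(f)))), 5 * 1e-6)
  expect_error(temporalFilter(s, stopbands = list(c(4, 6))), "Nyquist")
})

test_that("filtering is linear on time series", {
  set.seed(5)
  x <- matrix(rnorm(2000), 2, 1000)
  y <- matrix(rnorm(2000), 2, 1000)
  fx <- seriesValues(temporalFilter(channelTimeSeries(x, 10, "concentration")))
  fy <- seriesValues(temporalFilter(channelTimeSeries(y, 10, "concentration")))
  fxy <- seriesValues(temporalFilter(channelTimeSeries(2 * x - 3 * y, 10,
                                                       "concentration")))
  expect_equal(fxy, 2 * fx - 3 * fy, tolerance = 1e-9)
})

test_that("moving-SD artifact detection flags a step and respects offsets", {
  # hand-computed toy: 10 Hz, 1 s window (10 samples), 10 uM step at t=1.5s
  x <- c(rep(0, 15), rep(10, 15))
  s <- channelTimeSeries(matrix(x, 1), 10, "concentration")
  mask <- detectArtifacts(s, window = 1, threshold = 3)
  # moving SD across the step: windows centred within ~0.5 s of the jump
  # contain both levels; SD there is ~5 uM > 3 uM
  flagged <- which(mask[1, ])
  expect_true(all(flagged >= 11 & flagged <= 21))
  expect_true(any(mask[1, 14:17]))
  # invariant to constant offsets
  mask2 <- detectArtifacts(
    channelTimeSeries(matrix(x + 100, 1), 10, "concentration"),
    window = 1, threshold = 3)
  expect_identical(mask2[1, ], mask[1, ])
  # constant series and infinite threshold give empty masks
  const <- channelTimeSeries(matrix(1, 1, 30), 10, "concentration")
  expect_false(any(detectArtifacts(const, 1, 3)))
  expect_false(any(detectArtifacts(s, 1, Inf)))
  expect_error(detectArtifacts(s, window = 10), "longer")
})

test_that("amplitude-excursion detector catches slow large deviations", {
  x <- rep(0, 400)
  x[200:240] <- 5 * exp(-(0:40) / 10)   # slow decaying excursion
  s <- channelTimeSeries(matrix(x, 1), 10, "concentration")
  expect_false(any(detectArtifacts(s, 1, 3)[1, 205:235]))  # too smooth
  amp <- detectAmplitudeArtifacts(s, threshold = 2)
  expect_true(any(amp[1, 200:220]))
  expect_false(any(amp[1, 1:150]))
})

test_that("spline correction removes spikes locally and only locally", {
  set.seed(9)
  fs <- 10
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  clean <- sin(2 * pi * 0.03 * t)          # slow physiological oscillation
  x <- clean
  seg <- 79:93                             # near the crest: locally flat
  x[seg] <- x[seg] + 8 * exp(-(0:14) / 10)  # sharp spike
  s <- channelTimeSeries(matrix(x, 1), fs, "concentration")
  mask <- matrix(FALSE, 1, length(x)); mask[1, seg] <- TRUE
  out <- splineCorrect(s, mask)
  v <- seriesValues(out)[1, ]
  # untouched outside the flagged segment
  expect_identical(v[-seg], x[-seg])
  # within the segment, back near the clean series
  rmsErr <- sqrt(mean((v[seg] - clean[seg])^2))
  expect_lt(rmsErr, 0.1 * sqrt(mean(clean[seg]^2)))
  # empty mask is the identity
  out0 <- splineCorrect(s, matrix(FALSE, 1, length(x)))
  expect_identical(seriesValues(out0), seriesValues(s))
  allbad <- matrix(TRUE, 1, length(x))
  expect_error(splineCorrect(s, allbad), "exclude")
})

test_that("mask dilation pads flags in both directions", {
  m <- matrix(FALSE, 1, 100)
  m[1, 50] <- TRUE
  d <- dilateMask(m, fs = 10, before = 0.3, after = 0.5)
  expect_true(all(d[1, 47:55]))
  expect_false(any(d[1, c(1:46, 56:100)]))
})

test_that("epoch averaging baselines, averages, and drops artifact epochs", {
  fs <- 10
  design <- buildBlockDesign(3, duration = 9, min_rest = 13, session = 200,
                             sampling_rate = fs, seed = 4)
  # snap onsets to the sample grid so every epoch is sample-identical
  design$events$onset <- round(design$events$onset * fs) / fs
  n <- 200 * fs
  u <- stimulusFunctions(design, fs, n)
  # deterministic response: identical for every epoch -> average == epoch
  h <- exp(-(0:80) / 20)
  resp <- convolve(u["V", ], rev(h), type = "open")[seq_len(n)]
  s <- channelTimeSeries(matrix(resp + 2, 1), fs, "concentration")
  avg <- suppressWarnings(epochAverage(s, design))
  on1 <- design$events$onset[design$events$condition == "V"][1]
  idx <- round(on1 * fs) + 1 + seq(round(-2 * fs), round(22 * fs) - 1)
  ep1 <- resp[idx] + 2
  ep1 <- ep1 - mean(ep1[1:20])
  seg <- avg$values[1, seq_len(avg$segmentLength)]
  expect_equal(as.numeric(seg), ep1, tolerance = 1e-9)
  expect_identical(length(avg$conditions), 2L)
  # artifact exclusion drops the overlapped epoch
  mask <- matrix(FALSE, 1, n)
  mask[1, idx[100]] <- TRUE
  avg2 <- suppressWarnings(suppressMessages(
    epochAverage(s, design, exclude = mask)))
  expect_identical(unname(avg2$nEpochs["V"]), unname(avg$nEpochs["V"]) - 1L)
})

test_that("averaging independent noise epochs shrinks variance ~ 1/n", {
  fs <- 10
  design <- buildBlockDesign(12, session = 690, sampling_rate = fs, seed = 2)
  set.seed(77)
  reps <- replicate(30, {
    noise <- channelTimeSeries(matrix(rnorm(6900), 1), fs, "concentration")
    avg <- suppressWarnings(epochAverage(noise, design))
    var(avg$values[1, ])
  })
  # 12 epochs (baseline shift adds a little variance back)
  expect_lt(abs(mean(reps) - 1 / 12) / (1 / 12), 0.3)
})

test_that("time-series CSV round trip preserves data and metadata", {
  set.seed(10)
  s <- channelTimeSeries(matrix(rnorm(40), 4, 10), 10, "optical_density",
                         c("770", "770", "850", "850"))
  tf <- tempfile(fileext = ".csv")
  writeSeriesCSV(s, tf)
  back <- readSeriesCSV(tf)
  expect_equal(seriesValues(back), seriesValues(s), tolerance = 1e-12)
  expect_identical(back@kind, "optical_density")
  expect_identical(back@axisInfo, s@axisInfo)
  expect_identical(samplingRate(back), 10)
})
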