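## fNIRS preprocessing: optical density, modified Beer-Lambert conversion,
## Butterworth filtering, moving-SD motion-artifact detection with spline
## correction, and trial averaging for DCM.

#' Construct a ChannelTimeSeries
#'
#' @param values channels x samples numeric matrix.
#' @param samplingRate sampling rate in Hz.
#' @param kind "intensity", "optical_density" or "concentration".
#' @param axisInfo per-row annotation (wavelength or chromophore labels).
#' @param units unit string; defaults chosen per kind.
#' @return a [ChannelTimeSeries-class].
#' @export
channelTimeSeries <- function(values, samplingRate,
                              kind = c("intensity", "optical_density",
                                       "concentration"),
                              axisInfo = character(), units = NULL) {
  kind <- match.arg(kind)
  if (is.null(units))
    units <- switch(kind, intensity = "au", optical_density = "OD",
                    concentration = "uM")
  new("ChannelTimeSeries", values = as.matrix(values),
      samplingRate = samplingRate, kind = kind,
      axisInfo = as.character(axisInfo), units = units)
}

#' Convert raw intensities to optical density
#'
#' OD = -ln(I / I0) per channel, with I0 the mean over a baseline window.
#'
#' @param series an intensity [ChannelTimeSeries-class]; strictly positive.
#' @param baseline_window integer sample range for I0 (default: all samples).
#' @return an optical-density series; baseline intensities are attached as
#'   attribute `I0`.
#' @export
intensityToOD <- function(series, baseline_window = NULL) {
  stopifnot(series@kind == "intensity")
  v <- series@values
  if (any(v <= 0)) {
    bad <- which(v <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive intensity at channel %d, sample %d",
                 bad[1], bad[2]))
  }
  if (is.null(baseline_window)) baseline_window <- seq_len(ncol(v))
  I0 <- rowMeans(v[, baseline_window, drop = FALSE])
  out <- channelTimeSeries(-log(v / I0), series@samplingRate,
                           "optical_density", series@axisInfo)
  attr(out, "I0") <- I0
  out
}

#' Invert [intensityToOD()]
#' @param series an optical-density series.
#' @param I0 per-channel baseline intensities.
#' @return an intensity series.
#' @export
odToIntensity <- function(series, I0) {
  stopifnot(series@kind == "optical_density")
  channelTimeSeries(I0 * exp(-series@values), series@samplingRate,
                    "intensity", series@axisInfo)
}

#' Extinction coefficients for HbO and HbR at 770 and 850 nm
#'
#' Specific absorption coefficients (natural-log base, micromolar^-1 mm^-1)
#' from a standard compilation of hemoglobin spectra; shipped as replaceable
#' defaults.  Rows are wavelengths, columns chromophores.
#'
#' @return 2 x 2 matrix with dimnames (wavelengths x c("HbO", "HbR")).
#' @export
defaultExtinctionCoefficients <- function() {
  matrix(c(1.50e-4, 3.02e-4,
           2.44e-4, 1.59e-4),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("770", "850"), c("HbO", "HbR")))
}

#' Modified Beer-Lambert conversion to chromophore concentration changes
#'
#' Solves, per channel and sample, dOD(lambda) =
#' (eps_HbO(lambda) dHbO + eps_HbR(lambda) dHbR) * d * DPF for
#' (dHbO, dHbR) in micromolar, using the two measured wavelengths.
#'
#' @param od optical-density [ChannelTimeSeries-class] whose `axisInfo`
#'   labels each row with one of exactly two wavelengths; rows are matched
#'   across wavelengths by order within each wavelength group.
#' @param extinction 2 x 2 matrix, rows = wavelengths in axisInfo order of
#'   first appearance, columns = (HbO, HbR), micromolar^-1 mm^-1.
#' @param distance source-detector distance in mm.
#' @param dpf differential pathlength factor (dimensionless); the study
#'   value 5.13 is the default.
#' @return a concentration series with 2 rows per channel, axisInfo "HbO"
#'   and "HbR" (all HbO rows first).
#' @export
mbll <- function(od, extinction = defaultExtinctionCoefficients(),
                 distance = 20, dpf = 5.13) {
  stopifnot(od@kind == "optical_density")
  if (distance <= 0) stop("distance must be positive")
  if (base::kappa(extinction, exact = TRUE) > 1e6)
    stop("extinction matrix is near-singular: wavelength pair uninformative")
  wl <- unique(od@axisInfo)
  if (length(wl) != 2) stop("mbll requires exactly two wavelengths in axisInfo")
  i1 <- which(od@axisInfo == wl[1])
  i2 <- which(od@axisInfo == wl[2])
  if (length(i1) != length(i2)) stop("unequal channel counts per wavelength")
  Einv <- solve(extinction * distance * dpf)
  hbo <- Einv[1, 1] * od@values[i1, , drop = FALSE] +
         Einv[1, 2] * od@values[i2, , drop = FALSE]
  hbr <- Einv[2, 1] * od@values[i1, , drop = FALSE] +
         Einv[2, 2] * od@values[i2, , drop = FALSE]
  channelTimeSeries(rbind(hbo, hbr), od@samplingRate, "concentration",
                    c(rep("HbO", nrow(hbo)), rep("HbR", nrow(hbr))))
}

#' Forward modified Beer-Lambert: concentrations to optical density
#'
#' @param conc concentration series (HbO rows then HbR rows).
#' @param extinction,distance,dpf as in [mbll()].
#' @param wavelengths labels for the output rows.
#' @return an optical-density series (wavelength-1 rows then wavelength-2).
#' @export
mbllForward <- function(conc, extinction = defaultExtinctionCoefficients(),
                        distance = 20, dpf = 5.13,
                        wavelengths = rownames(extinction)) {
  stopifnot(conc@kind == "concentration")
  hbo <- conc@values[conc@axisInfo == "HbO", , drop = FALSE]
  hbr <- conc@values[conc@axisInfo == "HbR", , drop = FALSE]
  E <- extinction * distance * dpf
  od1 <- E[1, 1] * hbo + E[1, 2] * hbr
  od2 <- E[2, 1] * hbo + E[2, 2] * hbr
  channelTimeSeries(rbind(od1, od2), conc@samplingRate, "optical_density",
                    c(rep(wavelengths[1], nrow(od1)),
                      rep(wavelengths[2], nrow(od2))))
}

# Butterworth low/high-pass as second-order sections (biquads).  Direct
# transfer-function band-stop designs are numerically unstable at the very
# low normalised cutoffs used here (poles round outside the unit circle),
# so each stage is built from bilinear-transformed pole pairs and the
# band-stop is realised as the parallel sum of a low-pass below the band
# and a high-pass above it.
butterSections <- function(order, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  wc <- 2 * fs * tan(pi * fc / fs)   # prewarped analog cutoff
  k <- seq_len(order)
  pa <- wc * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  if (type == "high") pa <- wc^2 / pa   # s -> wc^2/s keeps |poles| scaled
  zp <- (1 + pa / (2 * fs)) / (1 - pa / (2 * fs))
  sections <- list()
  used <- rep(FALSE, order)
  for (i in k) {
    if (used[i]) next
    if (abs(Im(zp[i])) < 1e-12) {
      a <- c(1, -Re(zp[i]))
      b <- if (type == "low") c(1, 1) else c(1, -1)
      used[i] <- TRUE
    } else {
      j <- which(!used & abs(zp - Conj(zp[i])) < 1e-9)[1]
      a <- c(1, -2 * Re(zp[i]), Mod(zp[i])^2)
      b <- if (type == "low") c(1, 2, 1) else c(1, -2, 1)
      used[c(i, j)] <- TRUE
    }
    # unit gain at DC (low-pass) or Nyquist (high-pass)
    g <- if (type == "low") sum(a) / sum(b) else
      sum(a * c(1, -1, 1)[seq_along(a)]) / sum(b * c(1, -1, 1)[seq_along(b)])
    sections[[length(sections) + 1]] <- list(b = b * g, a = a)
  }
  sections
}

applyZeroPhaseSections <- function(sections, x) {
  for (s in sections)
    x <- signal::filtfilt(signal::Arma(b = s$b, a = s$a), x)
  x
}

# each stage is either list(kind="high", sections=...) or
# list(kind="stop", lp=..., hp=...) applied as a parallel sum
designFilters <- function(fs, highpass_hz, stopbands, order) {
  stages <- list()
  if (!is.null(highpass_hz) && highpass_hz > 0)
    stages <- c(stages, list(list(
      kind = "high",
      sections = butterSections(order, highpass_hz, fs, "high"))))
  for (b in stopbands)
    stages <- c(stages, list(list(
      kind = "stop",
      lp = butterSections(order, b[1], fs, "low"),
      hp = butterSections(order, b[2], fs, "high"))))
  stages
}

applyFilterStages <- function(stages, x) {
  for (st in stages) {
    x <- if (st$kind == "high") applyZeroPhaseSections(st$sections, x)
    else applyZeroPhaseSections(st$lp, x) + applyZeroPhaseSections(st$hp, x)
  }
  x
}

#' Temporal filtering: Butterworth high-pass plus band-stops, zero-phase
#'
#' Applies a high-pass then each band-stop stage forward and backward
#' (zero-phase two-pass), which doubles the effective order and removes
#' phase distortion that would otherwise bias estimated delays.  Stages are
#' implemented as cascaded Butterworth biquads for numerical stability,
#' with each band-stop realised as a parallel low-pass + high-pass pair.
#' Defaults follow the infant pipeline: 5th-order high-pass at 0.008 Hz and
#' band-stops over 0.06-0.16 Hz (Mayer waves) and 0.8-1.8 Hz (cardiac).
#'
#' @param series a [ChannelTimeSeries-class].
#' @param highpass_hz high-pass cutoff in Hz (NULL to skip).
#' @param stopbands list of c(low, high) band edges in Hz.
#' @param order Butterworth design order per pass.
#' @return the filtered series.
#' @export
temporalFilter <- function(series, highpass_hz = 0.008,
                           stopbands = list(c(0.06, 0.16), c(0.8, 1.8)),
                           order = 5) {
  fs <- series@samplingRate
  nyq <- fs / 2
  edges <- unlist(stopbands)
  if (length(edges) && max(edges) >= nyq)
    stop("stopband edge at or above the Nyquist frequency")
  if (length(edges) && fs <= 2 * max(edges))
    stop("sampling rate must exceed twice the highest stopband edge")
  stages <- designFilters(fs, highpass_hz, stopbands, order)
  v <- series@values
  # remove the channel mean before high-pass filtering: the DC component
  # is in the stopband anyway and would otherwise excite long edge
  # transients (the high-pass time constant exceeds typical sessions)
  if (!is.null(highpass_hz) && highpass_hz > 0) v <- v - rowMeans(v)
  for (ch in seq_len(nrow(v))) v[ch, ] <- applyFilterStages(stages, v[ch, ])
  out <- series
  out@values <- v
  out
}

sectionGain <- function(sections, w) {
  g <- rep(1 + 0i, length(w))
  for (s in sections) {
    z <- exp(1i * w)
    num <- outer(z, -(seq_along(s$b) - 1), `^`) %*% s$b
    den <- outer(z, -(seq_along(s$a) - 1), `^`) %*% s$a
    g <- g * drop(num / den)
  }
  g
}

#' Amplitude response of the default filter cascade at given frequencies
#'
#' Two-pass (zero-phase) magnitude: the product over stages of squared
#' single-pass magnitudes (band-stop stages: squared magnitude of the
#' parallel low-pass + high-pass sum).
#'
#' @param freqs_hz frequencies to evaluate (Hz).
#' @param fs sampling rate (Hz).
#' @inheritParams temporalFilter
#' @return numeric amplitude gains.
#' @export
filterResponse <- function(freqs_hz, fs = 10, highpass_hz = 0.008,
                           stopbands = list(c(0.06, 0.16), c(0.8, 1.8)),
                           order = 5) {
  stages <- designFilters(fs, highpass_hz, stopbands, order)
  w <- 2 * pi * freqs_hz / fs
  gain <- rep(1, length(w))
  for (st in stages) {
    g <- if (st$kind == "high") Mod(sectionGain(st$sections, w))^2
    else Mod(sectionGain(st$lp, w))^2 + Mod(sectionGain(st$hp, w))^2
    gain <- gain * g
  }
  gain
}

#' Detect motion artifacts by moving standard deviation
#'
#' Flags samples where the centred moving standard deviation (truncated
#' windows at the edges) exceeds a threshold; the study criterion is 3
#' micromolar over a 1 s sliding window, applied to the HbO series.
#'
#' @param series a concentration [ChannelTimeSeries-class] (or any series in
#'   the units of `threshold`).
#' @param window window length in seconds (>= 2 samples).
#' @param threshold flagging threshold in the series' units.
#' @return an `ArtifactMask`: logical channels x samples matrix with
#'   attributes `window` and `threshold`.
#' @export
detectArtifacts <- function(series, window = 1, threshold = 3) {
  fs <- series@samplingRate
  nw <- round(window * fs)
  if (nw < 2) stop("window must span at least 2 samples")
  v <- series@values
  ns <- ncol(v)
  if (nw > ns) stop("window longer than the series")
  half <- nw %/% 2
  lo <- pmax(1L, seq_len(ns) - half)
  hi <- pmin(ns, seq_len(ns) + half)
  cnt <- hi - lo + 1
  mask <- matrix(FALSE, nrow(v), ns)
  for (ch in seq_len(nrow(v))) {
    cs <- cumsum(c(0, v[ch, ]))
    cs2 <- cumsum(c(0, v[ch, ]^2))
    s <- cs[hi + 1] - cs[lo]
    s2 <- cs2[hi + 1] - cs2[lo]
    varv <- pmax(0, (s2 - s^2 / cnt) / (cnt - 1))
    mask[ch, ] <- sqrt(varv) > threshold
  }
  structure(mask, window = window, threshold = threshold)
}

#' Correct flagged artifact segments by spline subtraction
#'
#' For each contiguous flagged segment per channel, fits a cubic smoothing
#' spline to the segment, subtracts the fit, and re-levels the segment to
#' the mean of the immediately preceding clean samples (following samples if
#' the segment starts the recording).  Unflagged samples are untouched.
#'
#' @param series a [ChannelTimeSeries-class].
#' @param mask logical matrix from [detectArtifacts()] of matching shape.
#' @param level_window seconds of adjacent clean signal used for re-leveling.
#' @return the corrected series.
#' @export
splineCorrect <- function(series, mask, level_window = 1) {
  stopifnot(all(dim(mask) == dim(series@values)))
  fs <- series@samplingRate
  nlev <- max(1L, round(level_window * fs))
  v <- series@values
  for (ch in seq_len(nrow(v))) {
    m <- mask[ch, ]
    if (!any(m)) next
    if (all(m))
      stop(sprintf("channel %d is entirely flagged; exclude it instead", ch))
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (seg in which(r$values)) {
      idx <- starts[seg]:ends[seg]
      y <- v[ch, idx]
      fit <- if (length(idx) >= 4) {
        sp <- smooth.spline(seq_along(idx), y)
        predict(sp, seq_along(idx))$y
      } else rep(mean(y), length(idx))
      pre <- seq(max(1, starts[seg] - nlev), starts[seg] - 1)
      pre <- pre[pre >= 1 & !mask[ch, pre]]
      level <- if (length(pre)) mean(v[ch, pre]) else {
        post <- seq(ends[seg] + 1, min(ncol(v), ends[seg] + nlev))
        post <- post[post <= ncol(v) & !mask[ch, post]]
        if (length(post)) mean(v[ch, post]) else 0
      }
      v[ch, idx] <- y - fit + level
    }
  }
  out <- series
  out@values <- v
  out
}

#' Trial-averaged series and input functions
#'
#' Extracts per-condition epochs over a peristimulus window, baseline-shifts
#' each epoch to its mean over the pre-onset interval, averages within
#' condition, and concatenates condition averages (in the design's condition
#' order) together with identically averaged stimulus functions.
#'
#' @param series a [ChannelTimeSeries-class].
#' @param design a `BlockDesign` from [buildBlockDesign()].
#' @param window c(pre, post) peristimulus window in seconds relative to
#'   block onset; default c(-2, 22) covering a 9 s block plus rest.
#' @param input_window optional wider window for the averaged stimulus
#'   functions (default: same as `window`).  A generative model can
#'   integrate through this input history so that carryover from preceding
#'   blocks is represented when predicting the epoch window.
#' @param exclude optional artifact mask ([detectArtifacts()] output or any
#'   logical matrix/vector over samples): epochs whose window overlaps a
#'   flagged sample on any channel are dropped (logged), the usual practice
#'   for residual motion artifacts that survive correction.
#' @return a list of class `AveragedSeries`: `values` (signals x samples,
#'   condition segments concatenated), `inputs` (conditions x samples
#'   averaged stimulus functions over `input_window`), `conditions`,
#'   `segmentLength`, `inputSegmentLength`, `inputOffset` (samples of
#'   `inputs` preceding the epoch window), `preSamples`, `samplingRate`,
#'   `window`, `nEpochs` per condition.
#' @export
epochAverage <- function(series, design, window = c(-2, 22),
                         input_window = window, exclude = NULL) {
  fs <- series@samplingRate
  v <- series@values
  ns <- ncol(v)
  badSample <- if (is.null(exclude)) rep(FALSE, ns) else {
    if (is.matrix(exclude)) apply(exclude, 2, any) else as.logical(exclude)
  }
  rel <- seq(round(window[1] * fs), round(window[2] * fs) - 1)
  relIn <- seq(round(input_window[1] * fs), round(input_window[2] * fs) - 1)
  if (input_window[1] > window[1] || input_window[2] < window[2])
    stop("input_window must contain window")
  pre <- sum(rel < 0)
  conds <- design$conditions
  u <- stimulusFunctions(design, fs, ns)
  onsets <- design$events$onset
  if (any(diff(sort(onsets)) * fs < length(rel)))
    warning("epoch windows overlap adjacent blocks")
  segs <- list(); useg <- list(); nEp <- integer(0)
  for (cn in conds) {
    ev <- design$events[design$events$condition == cn, ]
    acc <- 0; uacc <- 0; used <- 0
    for (on in ev$onset) {
      idx <- round(on * fs) + 1 + rel
      if (min(idx) < 1 || max(idx) > ns) {
        message(sprintf("epoch at %.1f s outside the recording; dropped", on))
        next
      }
      if (any(badSample[idx])) {
        message(sprintf("epoch at %.1f s overlaps a flagged artifact; dropped",
                        on))
        next
      }
      idxIn <- round(on * fs) + 1 + relIn
      uEp <- u[, pmax(pmin(idxIn, ns), 1), drop = FALSE]
      uEp[, idxIn < 1 | idxIn > ns] <- 0
      ep <- v[, idx, drop = FALSE]
      ep <- ep - rowMeans(ep[, seq_len(pre), drop = FALSE])
      acc <- acc + ep
      uacc <- uacc + uEp
      used <- used + 1
    }
    if (used == 0) stop(sprintf("no usable epochs for condition %s", cn))
    segs[[cn]] <- acc / used
    useg[[cn]] <- uacc / used
    nEp[cn] <- used
  }
  structure(list(values = do.call(cbind, segs),
                 inputs = do.call(cbind, useg),
                 conditions = conds, segmentLength = length(rel),
                 inputSegmentLength = length(relIn),
                 inputOffset = sum(relIn < rel[1]),
                 preSamples = pre, samplingRate = fs, window = window,
                 input_window = input_window, nEpochs = nEp),
            class = "AveragedSeries")
}

#' Write a time series as long-format CSV
#'
#' Columns: time (s), channel (row index), label (axisInfo), value.
#'
#' @param series a [ChannelTimeSeries-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSeriesCSV <- function(series, path) {
  ns <- ncol(series@values)
  nc <- nrow(series@values)
  lab <- if (length(series@axisInfo)) series@axisInfo else rep("", nc)
  df <- data.frame(
    time = rep((seq_len(ns) - 1) / series@samplingRate, each = nc),
    channel = rep(seq_len(nc), ns),
    label = rep(lab, ns),
    value = as.numeric(series@values)
  )
  df$kind <- series@kind
  df$sampling_rate <- series@samplingRate
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format CSV written by [writeSeriesCSV()]
#' @param path input path.
#' @return a [ChannelTimeSeries-class].
#' @export
readSeriesCSV <- function(path) {
  df <- read.csv(path)
  nc <- max(df$channel)
  ns <- nrow(df) / nc
  v <- matrix(df$value, nc, ns)
  lab <- df$label[seq_len(nc)]
  channelTimeSeries(v, as.numeric(df$sampling_rate[1]), df$kind[1],
                    as.character(lab))
}

#' Dilate an artifact mask in time
#'
#' Extends every flagged sample by a margin before and after, the usual
#' guard against residual artifact energy (e.g. the decaying tail of a
#' motion spike) escaping the detected segment.
#'
#' @param mask logical channels x samples matrix.
#' @param fs sampling rate (Hz).
#' @param before,after margins in seconds.
#' @return dilated logical matrix of the same shape.
#' @export
dilateMask <- function(mask, fs, before = 1, after = 4) {
  nb <- round(before * fs); na <- round(after * fs)
  out <- mask
  ns <- ncol(mask)
  for (ch in seq_len(nrow(mask))) {
    w <- which(mask[ch, ])
    if (!length(w)) next
    idx <- unique(pmax(1, pmin(ns, rep(w, each = nb + na + 1) +
                                 seq(-nb, na))))
    out[ch, idx] <- TRUE
  }
  out
}

#' Detect artifacts by amplitude excursion
#'
#' Flags samples whose deviation from a running median exceeds a threshold.
#' Complements the moving-SD detector: slow but large excursions (e.g. the
#' decaying tail of a motion spike) produce little local variance yet are
#' physiologically implausible in amplitude -- evoked hemoglobin changes at
#' the channel level are well below the default 2 micromolar.
#'
#' @param series a concentration [ChannelTimeSeries-class].
#' @param threshold amplitude threshold in the series' units.
#' @param baseline_s running-median window (s) defining the local baseline.
#' @return logical channels x samples mask.
#' @export
detectAmplitudeArtifacts <- function(series, threshold = 2, baseline_s = 10) {
  v <- series@values
  k <- round(baseline_s * series@samplingRate)
  if (k %% 2 == 0) k <- k + 1
  k <- min(k, ncol(v) - (1 - ncol(v) %% 2))
  mask <- matrix(FALSE, nrow(v), ncol(v))
  for (ch in seq_len(nrow(v))) {
    base <- stats::runmed(v[ch, ], k)
    mask[ch, ] <- abs(v[ch, ] - base) > threshold
  }
  mask
}
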