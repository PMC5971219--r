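## Fitting a DCM to trial-averaged data: the bridge between the generative
## model and the variational-Laplace engine.

#' Zero-phase filter operator as a matrix for fixed-length segments
#'
#' Filtering is linear, so the zero-phase two-pass Butterworth cascade on a
#' length-`n` segment can be precomputed as an n x n matrix (one filtfilt
#' per identity column).  Used to apply the preprocessing filters to model
#' predictions so data and prediction pass through the same operator.
#'
#' @param n segment length in samples.
#' @param fs sampling rate (Hz).
#' @param highpass_hz,stopbands,order as in [temporalFilter()].
#' @return n x n matrix F with (F x) the filtered segment.
#' @export
segmentFilterMatrix <- function(n, fs, highpass_hz = NULL,
                                stopbands = list(c(0.06, 0.16)), order = 5) {
  stages <- designFilters(fs, highpass_hz, stopbands, order)
  apply(diag(n), 2, function(x) applyFilterStages(stages, x))
}

#' Fit a DCM to trial-averaged data by variational Laplace
#'
#' Builds the generative predictor for an [epochAverage()] result --
#' integrating the DCM from rest over each condition segment with the
#' averaged stimulus functions, applying the observation model, the
#' optional preprocessing filter operator, and the same pre-onset baseline
#' shift as the data -- and inverts it with [variationalLaplace()].
#'
#' @param avg an `AveragedSeries` from [epochAverage()]; for fNIRS its rows
#'   are channels stacked by wavelength, for BOLD one row per region.
#' @param spec the [DCMSpec-class] model to fit (structure defines the free
#'   parameters).
#' @param modality "fnirs" or "bold".
#' @param obsModel `FNIRSObservationModel` (required for fNIRS).
#' @param hemo baseline `HemodynamicParameters`.
#' @param priors a `PriorSpec`; defaults to [dcmPriors()].
#' @param dt integration step (s).
#' @param filterMatrix optional segment filter operator from
#'   [segmentFilterMatrix()], applied to predictions.
#' @param ... passed to [variationalLaplace()] (e.g. `maxIter`,
#'   `fixedHyper`).
#' @return a [PosteriorFit-class]; `@prediction` holds the fitted signals
#'   x samples prediction.
#' @export
dcmFitAveraged <- function(avg, spec, modality = c("fnirs", "bold"),
                           obsModel = NULL,
                           hemo = hemodynamicParameters(length(spec@regions)),
                           priors = dcmPriors(spec, modality), dt = 0.1,
                           filterMatrix = NULL, ...) {
  modality <- match.arg(modality)
  if (modality == "fnirs" && is.null(obsModel))
    stop("an FNIRSObservationModel is required for fNIRS fits")
  tFm <- if (!is.null(filterMatrix)) t(filterMatrix)
  fs <- avg$samplingRate
  Tn <- avg$segmentLength
  Ti <- if (is.null(avg$inputSegmentLength)) Tn else avg$inputSegmentLength
  off <- if (is.null(avg$inputOffset)) 0L else avg$inputOffset
  nSeg <- length(avg$conditions)
  pre <- avg$preSamples
  duration <- (Ti - 1) / fs
  segIdx <- lapply(seq_len(nSeg), function(s) (s - 1) * Ti + seq_len(Ti))
  crop <- off + seq_len(Tn)

  predictFun <- function(theta) {
    up <- unpackParameters(theta, priors, spec, hemo)
    segs <- vector("list", nSeg)
    for (s in seq_len(nSeg)) {
      u <- avg$inputs[, segIdx[[s]], drop = FALSE]
      sim <- tryCatch(
        integrateDcm(up$spec, up$hemo, obsModel = NULL, u = u, u_rate = fs,
                     duration = duration, dt = dt, out_rate = fs),
        error = function(e) NULL)
      if (is.null(sim)) return(rep(1e6, length(avg$values)))
      yseg <- if (modality == "fnirs") {
        om <- obsModel
        om$k <- up$k
        observeFnirs(sim$dHc[, crop, drop = FALSE],
                     sim$dQc[, crop, drop = FALSE], om)
      } else observeBold(sim$v[, crop, drop = FALSE],
                         sim$q[, crop, drop = FALSE], E0 = up$hemo$E0[1])
      if (!is.null(tFm)) yseg <- yseg %*% tFm
      yseg <- yseg - rowMeans(yseg[, seq_len(pre), drop = FALSE])
      segs[[s]] <- yseg
    }
    as.numeric(do.call(cbind, segs))
  }

  nSig <- nrow(avg$values)
  groups <- if (modality == "fnirs") {
    perWl <- nSig / 2
    rep(rep(1:2, each = perWl), ncol(avg$values))
  } else rep(1L, length(avg$values))

  fit <- variationalLaplace(predictFun, priors, as.numeric(avg$values),
                            noiseGroups = groups, ...)
  fit@prediction <- matrix(predictFun(fullParameterVector(fit, priors)),
                           nrow = nSig)
  fit
}

# posterior mean embedded back into the full parameter vector
fullParameterVector <- function(fit, priors) {
  th <- priors$pE
  th[names(fit@mean)] <- fit@mean
  th
}

#' Trial-averaging operator as a sparse matrix
#'
#' Builds the linear operator that maps a full-session signal (one row per
#' signal, samples in columns) to concatenated per-condition epoch
#' averages with pre-onset baseline subtraction -- the exact operation of
#' [epochAverage()] -- so the same operator can be applied to model
#' predictions.
#'
#' @param design a `BlockDesign`.
#' @param fs sampling rate (Hz).
#' @param n_samples session length in samples.
#' @param window peristimulus window (s).
#' @param exclude optional artifact mask (as in [epochAverage()]): epochs
#'   overlapping flagged samples are dropped.
#' @return sparse (segments x samples) Matrix with attributes `conditions`,
#'   `segmentLength`, `preSamples`, `nEpochs`.
#' @export
epochAverageOperator <- function(design, fs, n_samples, window = c(-2, 22),
                                 exclude = NULL) {
  rel <- seq(round(window[1] * fs), round(window[2] * fs) - 1)
  Tn <- length(rel)
  pre <- sum(rel < 0)
  badSample <- if (is.null(exclude)) rep(FALSE, n_samples) else {
    if (is.matrix(exclude)) apply(exclude, 2, any) else as.logical(exclude)
  }
  conds <- design$conditions
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  nEp <- integer(0)
  for (ci in seq_along(conds)) {
    onsets <- design$events$onset[design$events$condition == conds[ci]]
    used <- list()
    for (on in onsets) {
      idx <- round(on * fs) + 1 + rel
      if (min(idx) < 1 || max(idx) > n_samples) next
      if (any(badSample[idx])) next
      used[[length(used) + 1]] <- idx
    }
    n <- length(used)
    if (n == 0) stop(sprintf("no usable epochs for condition %s", conds[ci]))
    nEp[conds[ci]] <- n
    rows0 <- (ci - 1) * Tn
    for (idx in used) {
      # direct average part
      ii <- c(ii, rows0 + seq_len(Tn)); jj <- c(jj, idx)
      xx <- c(xx, rep(1 / n, Tn))
      # per-epoch baseline subtraction part
      ii <- c(ii, rep(rows0 + seq_len(Tn), each = pre))
      jj <- c(jj, rep(idx[seq_len(pre)], times = Tn))
      xx <- c(xx, rep(-1 / (n * pre), pre * Tn))
    }
  }
  op <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                             dims = c(Tn * length(conds), n_samples))
  attr(op, "conditions") <- conds
  attr(op, "segmentLength") <- Tn
  attr(op, "preSamples") <- pre
  attr(op, "nEpochs") <- nEp
  op
}

#' Orthonormal DCT basis with confound bands removed
#'
#' Discrete-cosine basis over a segment of `n` samples with columns whose
#' frequencies fall inside the given bands (and optionally the constant)
#' removed.  Projecting data and model predictions onto the retained
#' columns removes nuisance bands (Mayer waves, cardiac pulsation) as a
#' confound subspace with exact data/model consistency and honest degrees
#' of freedom -- the projection analogue of the preprocessing band-stops.
#'
#' @param n segment length (samples).
#' @param fs sampling rate (Hz).
#' @param bands list of c(low, high) frequency bands (Hz) to remove.
#' @param dropConstant drop the constant component (default TRUE; segment
#'   means are already handled by baseline subtraction).
#' @return n x d matrix with orthonormal columns (d <= n).
#' @export
dctProjectionBasis <- function(n, fs,
                               bands = list(c(0.06, 0.16), c(0.8, 1.8)),
                               dropConstant = TRUE) {
  t <- seq_len(n) - 1
  freqs <- (seq_len(n) - 1) * fs / (2 * n)
  keep <- rep(TRUE, n)
  if (dropConstant) keep[1] <- FALSE
  for (b in bands) keep[freqs >= b[1] & freqs <= b[2]] <- FALSE
  ks <- which(keep) - 1
  Q <- vapply(ks, function(k) {
    col <- cos(pi * k * (2 * t + 1) / (2 * n))
    col / sqrt(sum(col^2))
  }, numeric(n))
  Q
}

#' Fit a DCM to a session recording via the trial-average operator
#'
#' The estimation route used by the recovery harness: the generative model
#' predicts the full session from the design's stimulus functions, and both
#' data and prediction pass through the identical linear pipeline -- trial
#' averaging with baseline subtraction ([epochAverageOperator()]) followed
#' by projection onto a DCT basis with the physiological-confound bands
#' removed ([dctProjectionBasis()]).  Because the two sides share the exact
#' operator, trial-averaged fitting incurs no epoching approximation.
#'
#' @param values signals x samples matrix (fNIRS: channels stacked by
#'   wavelength; BOLD: one row per region).
#' @param design the session `BlockDesign`.
#' @param spec the [DCMSpec-class] to fit.
#' @param modality "fnirs" or "bold".
#' @param obsModel `FNIRSObservationModel` (fNIRS only).
#' @param hemo baseline `HemodynamicParameters`.
#' @param fs sampling rate (Hz).
#' @param exclude optional artifact mask forwarded to the operator.
#' @param window peristimulus window (s).
#' @param bands confound bands removed by segment-domain DCT projection;
#'   NULL disables it.
#' @param whiten if TRUE (default), whiten the averaged domain by the
#'   Cholesky inverse of E E' (E the averaging operator): under white
#'   measurement noise the per-epoch baseline subtraction correlates the
#'   averaged samples, and whitening restores the iid noise assumed by the
#'   likelihood.
#' @param confounds optional session-domain confound regressors (samples x
#'   q matrix, e.g. [physiologicalConfounds()]): both data and prediction
#'   are projected onto their orthogonal complement before averaging.
#' @param confoundMask optional logical channels x samples artifact mask:
#'   confound coefficients are then estimated per channel from unflagged
#'   samples only, so large motion artifacts cannot corrupt them (the
#'   subtraction is still applied everywhere, and the operator remains
#'   linear and identical for data and prediction).
#' @param priors a `PriorSpec`.
#' @param dt integration step (s).
#' @param ... passed to [variationalLaplace()].
#' @return a [PosteriorFit-class]; `@prediction` holds the averaged-domain
#'   prediction (segments concatenated, confounds projected out).
#' @name dcmFitSession
NULL

#' Precompute the averaging/confound/whitening pipeline for [dcmFitSession()]
#'
#' The linear operator pieces depend only on the design, masks and
#' confounds -- not on the model -- so when several models are fitted to
#' the same session (as in model comparison) the pipeline can be built
#' once and shared.
#'
#' @inheritParams dcmFitSession
#' @return an opaque `FitPipeline` list.
#' @export
fitPipeline <- function(values, design, fs = design$sampling_rate,
                        exclude = NULL, window = c(-2, 22),
                        bands = list(c(0.06, 0.16), c(0.8, 1.8)),
                        confounds = NULL, confoundMask = NULL,
                        whiten = TRUE) {
  values <- as.matrix(values)
  nSamples <- ncol(values)
  E <- epochAverageOperator(design, fs, nSamples, window, exclude)
  Tn <- attr(E, "segmentLength")
  nSeg <- length(attr(E, "conditions"))
  # only the session samples the averaging operator actually reads matter
  # downstream; restricting to them (identically for data and prediction)
  # trims the per-evaluation cost
  sup <- which(Matrix::colSums(abs(E)) > 0)
  Esub <- E[, sup, drop = FALSE]
  tE <- Matrix::t(Esub)
  Q <- if (length(bands)) dctProjectionBasis(Tn, fs, bands) else NULL
  D <- if (!is.null(confounds)) as.matrix(confounds)[sup, , drop = FALSE]
  # per-channel masked least-squares estimator of confound coefficients:
  # coef_ch = (x_ch D - x_ch[miss] D[miss,]) G_ch with G_ch the masked
  # Gram inverse, so one shared GEMM covers all channels and only the few
  # masked samples need per-channel corrections
  if (!is.null(D)) {
    missIdx <- lapply(seq_len(nrow(values)), function(ch)
      if (is.null(confoundMask)) integer(0) else
        which(confoundMask[ch, sup]))
    Gch <- lapply(seq_len(nrow(values)), function(ch) {
      keep <- setdiff(seq_along(sup), missIdx[[ch]])
      solve(crossprod(D[keep, , drop = FALSE]))
    })
  }
  segIdx <- lapply(seq_len(nSeg), function(s) (s - 1) * Tn + seq_len(Tn))
  ED <- if (!is.null(D)) as.matrix(Esub %*% D)  # averaged confound columns
  tED <- if (!is.null(D)) t(ED)
  tW <- if (whiten) {
    # E E' is the averaged-domain noise covariance (up to sigma^2) under
    # iid session noise.  The baseline subtraction makes it rank
    # deficient (pre-onset rows of E sum to zero), so whiten onto the
    # non-null eigenspace, dropping the zero-information directions.
    S <- as.matrix(Matrix::tcrossprod(E))
    ei <- eigen(S, symmetric = TRUE)
    keep <- ei$values > max(ei$values) * 1e-10
    ei$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(ei$values[keep]))
  }
  toFitted <- function(mat, restricted = FALSE) {
    if (!restricted) mat <- mat[, sup, drop = FALSE]
    avg <- as.matrix(mat %*% tE)
    if (!is.null(D)) {
      # (mat - D coef) E' = mat E' - coef' (E D)'
      XD <- mat %*% D
      coefs <- t(vapply(seq_len(nrow(mat)), function(ch) {
        xd <- XD[ch, ]
        mi <- missIdx[[ch]]
        if (length(mi))
          xd <- xd - drop(mat[ch, mi] %*% D[mi, , drop = FALSE])
        drop(xd %*% Gch[[ch]])
      }, numeric(ncol(D))))
      avg <- avg - coefs %*% tED
    }
    if (whiten) avg <- avg %*% tW
    if (is.null(Q)) return(avg)
    do.call(cbind, lapply(segIdx, function(ix)
      avg[, ix, drop = FALSE] %*% Q))
  }
  yMat <- toFitted(values)
  u <- stimulusFunctions(design, fs, nSamples)
  structure(list(toFitted = toFitted, yMat = yMat, u = u, fs = fs,
                 sup = sup, nSamples = nSamples, nSig = nrow(values)),
            class = "FitPipeline")
}

#' @rdname dcmFitSession
#' @param pipeline optional precomputed [fitPipeline()] (built from the
#'   same values/design/mask arguments); reused across models when
#'   comparing a model space.
#' @export
dcmFitSession <- function(values, design, spec,
                          modality = c("fnirs", "bold"), obsModel = NULL,
                          hemo = hemodynamicParameters(length(spec@regions)),
                          fs = design$sampling_rate, exclude = NULL,
                          window = c(-2, 22),
                          bands = list(c(0.06, 0.16), c(0.8, 1.8)),
                          confounds = NULL, confoundMask = NULL,
                          whiten = TRUE, pipeline = NULL,
                          priors = dcmPriors(spec, modality), dt = 0.1,
                          ...) {
  modality <- match.arg(modality)
  if (modality == "fnirs" && is.null(obsModel))
    stop("an FNIRSObservationModel is required for fNIRS fits")
  if (is.null(pipeline))
    pipeline <- fitPipeline(values, design, fs, exclude, window, bands,
                            confounds, confoundMask, whiten)
  yMat <- pipeline$yMat
  u <- pipeline$u
  sup <- pipeline$sup
  toFitted <- pipeline$toFitted
  nSteps <- round((pipeline$nSamples - 1) / fs / dt)
  outEvery <- round(1 / (fs * dt))
  nReg <- length(spec@regions)
  failVec <- rep(1e6, length(yMat))

  predictFun <- function(theta) {
    up <- unpackParameters(theta, priors, spec, hemo)
    hm <- up$hemo
    res <- dcm_integrate_cpp(up$spec@A, unlist(up$spec@B, use.names = FALSE),
                             up$spec@C, hm$kappa_s, hm$gamma, hm$tau,
                             hm$alpha, hm$E0, u, 1 / fs, dt, nSteps,
                             outEvery, outMode = 1L)
    if (!res$ok) return(failVec)
    st <- res$states          # v and q only (outMode = 1)
    v <- st[seq_len(nReg), sup, drop = FALSE]
    q <- st[nReg + seq_len(nReg), sup, drop = FALSE]
    yhat <- if (modality == "fnirs") {
      dQc <- hm$HbR0 * (q - 1)
      dHc <- hm$HbT0 * (v - 1) - dQc
      do.call(rbind, lapply(seq_along(obsModel$S0), function(i) {
        mix <- obsModel$extinction[i, 1] * obsModel$WH[i] * dHc +
          obsModel$extinction[i, 2] * obsModel$WQ[i] * dQc
        (up$k * obsModel$S0[[i]]) %*% mix
      }))
    } else observeBold(v, q, E0 = hm$E0[1])
    as.numeric(toFitted(yhat, restricted = TRUE))
  }

  nSig <- pipeline$nSig
  groups <- if (modality == "fnirs")
    rep(rep(1:2, each = nSig / 2), ncol(yMat)) else rep(1L, length(yMat))

  fit <- variationalLaplace(predictFun, priors, as.numeric(yMat),
                            noiseGroups = groups, ...)
  fit@prediction <- matrix(predictFun(fullParameterVector(fit, priors)),
                           nrow = nSig)
  fit
}

#' Sine/cosine confound regressors at physiological frequencies
#'
#' A minimal session-domain basis capturing narrowband physiological
#' oscillations (Mayer waves, cardiac pulsation) as nuisance components:
#' one sine/cosine pair per frequency.  Removing their span from both data
#' and model prediction plays the role of the preprocessing band-stop
#' filters inside the estimation, with exact data/model consistency.
#'
#' @param n_samples session length (samples).
#' @param fs sampling rate (Hz).
#' @param freqs_hz frequencies (Hz) to span.
#' @return n_samples x (2 * length(freqs_hz)) matrix.
#' @export
physiologicalConfounds <- function(n_samples, fs, freqs_hz = c(0.1, 1.2)) {
  t <- (seq_len(n_samples) - 1) / fs
  do.call(cbind, lapply(freqs_hz, function(f)
    cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))))
}
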