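## Block design construction, canonical HRF basis, GLM fitting and region
## eigenvariate extraction.

# run expr with a private RNG state seeded by `seed`
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build a two-condition block design
#'
#' Generates a seeded block design with shuffled condition order: V and NV
#' blocks of fixed duration separated by at least `min_rest` of rest, with
#' seeded jitter spreading the slack over the session.  Defaults follow the
#' infant session: 12 + 12 blocks of 9 s, rest >= 13 s, 690 s at 10 Hz.
#'
#' @param n_per_condition blocks per condition.
#' @param duration block duration (s).
#' @param min_rest minimum inter-block rest (s).
#' @param session session length (s).
#' @param sampling_rate sampling rate (Hz), carried as metadata.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param conditions condition labels, first label = first factor level.
#' @param margin time reserved before the first and after the last block (s).
#' @return a `BlockDesign` list: `events` (condition, onset, duration),
#'   `session_length`, `sampling_rate`, `conditions`.
#' @export
buildBlockDesign <- function(n_per_condition = 12, duration = 9,
                             min_rest = 13, session = 690,
                             sampling_rate = 10, seed,
                             conditions = c("V", "NV"), margin = 2) {
  if (missing(seed)) stop("a seed is required")
  nTot <- n_per_condition * length(conditions)
  spacing <- duration + min_rest
  needed <- 2 * margin + (nTot - 1) * spacing + duration + min_rest
  if (needed > session)
    stop(sprintf("design infeasible: %d blocks need at least %.1f s", nTot, needed))
  slack <- session - needed
  withSeed(seed, {
    order <- sample(rep(conditions, n_per_condition))
    extra <- runif(nTot - 1)
    extra <- extra / sum(extra) * runif(1, 0.5, 1) * slack
    onsets <- margin + c(0, cumsum(spacing + extra))
  })
  ev <- data.frame(condition = order, onset = onsets, duration = duration)
  structure(list(events = ev, session_length = session,
                 sampling_rate = sampling_rate, conditions = conditions),
            class = "BlockDesign")
}

#' Sampled stimulus (input) functions of a design
#'
#' Boxcar functions, one row per condition: 1 while the condition's block is
#' on, 0 otherwise.
#'
#' @param design a `BlockDesign`.
#' @param fs sampling rate (Hz); defaults to the design's.
#' @param n_samples series length; defaults to the full session.
#' @return conditions x samples matrix.
#' @export
stimulusFunctions <- function(design, fs = design$sampling_rate,
                              n_samples = round(design$session_length * fs)) {
  u <- matrix(0, length(design$conditions), n_samples,
              dimnames = list(design$conditions, NULL))
  for (i in seq_len(nrow(design$events))) {
    ev <- design$events[i, ]
    idx <- seq(floor(ev$onset * fs) + 1,
               min(n_samples, floor((ev$onset + ev$duration) * fs)))
    u[ev$condition, idx] <- 1
  }
  u
}

#' Canonical HRF basis: double-gamma plus temporal and dispersion derivatives
#'
#' The canonical response is a difference of gamma densities (response peak
#' at ~6 s, undershoot at ~16 s, undershoot ratio 1/6), sampled over 32 s.
#' The temporal derivative is the finite difference against a 1 s onset
#' shift; the dispersion derivative is the finite difference with respect to
#' the peak dispersion parameter.
#'
#' @param sampling_rate sampling rate (Hz).
#' @return a samples x 3 matrix (canonical, temporal, dispersion) with a
#'   `time` attribute.
#' @export
canonicalHrfBasis <- function(sampling_rate) {
  if (sampling_rate <= 0) stop("sampling rate must be positive")
  t <- seq(0, 32, by = 1 / sampling_rate)
  gam <- function(tt, disp = 1)
    stats::dgamma(tt, shape = 6 / disp, rate = 1 / disp) -
      stats::dgamma(tt, shape = 16 / disp, rate = 1 / disp) / 6
  h <- gam(t)
  hShift <- gam(pmax(t - 1, 0))
  dDisp <- 0.01
  basis <- cbind(canonical = h,
                 temporal = (h - hShift),
                 dispersion = (h - gam(t, 1 + dDisp)) / dDisp)
  attr(basis, "time") <- t
  basis
}

#' Build an HRF-convolved design matrix
#'
#' Events are encoded as unit impulses at their onset samples (or optionally
#' as boxcars over the block duration) and convolved with each basis
#' function; all regressors except the constant are mean-centred.
#'
#' @param design a `BlockDesign`.
#' @param basis basis matrix from [canonicalHrfBasis()] (columns = basis
#'   functions), sampled at the design's rate.
#' @param boxcar if TRUE encode blocks as boxcars instead of onset deltas.
#' @return a `DesignMatrix`: samples x regressors matrix with named columns
#'   (condition x basis, plus "constant").
#' @export
buildDesignMatrix <- function(design, basis = canonicalHrfBasis(design$sampling_rate),
                              boxcar = FALSE) {
  fs <- design$sampling_rate
  n <- round(design$session_length * fs)
  cols <- list()
  for (cn in design$conditions) {
    ev <- design$events[design$events$condition == cn, ]
    if (nrow(ev) == 0) next   # conditions without events add no columns
    stick <- numeric(n)
    for (i in seq_len(nrow(ev))) {
      if (boxcar) {
        idx <- seq(floor(ev$onset[i] * fs) + 1,
                   min(n, floor((ev$onset[i] + ev$duration[i]) * fs)))
        stick[idx] <- 1
      } else stick[floor(ev$onset[i] * fs) + 1] <- 1
    }
    for (b in seq_len(ncol(basis))) {
      cv <- convolve(stick, rev(basis[, b]), type = "open")[seq_len(n)]
      cols[[paste(cn, colnames(basis)[b], sep = "_")]] <- cv - mean(cv)
    }
  }
  X <- cbind(do.call(cbind, cols), constant = 1)
  if (length(cols))
    colnames(X) <- c(names(cols), "constant")
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dep <- colnames(X)[qrx$pivot[-seq_len(qrx$rank)]]
    stop(sprintf("design matrix rank deficient; collinear columns: %s",
                 paste(dep, collapse = ", ")))
  }
  X
}

#' Ordinary least squares GLM with contrast t-statistics
#'
#' @param y numeric vector (samples) or samples x series matrix.
#' @param X full-rank design matrix (samples x regressors).
#' @param contrasts optional matrix of contrast column vectors (regressors x
#'   contrasts); t = c'beta / sqrt(sigma2 c'(X'X)^-1 c).
#' @return list with `beta`, `residuals`, `sigma2`, `df`, and (if requested)
#'   `t` and `p` per contrast.
#' @export
fitGlm <- function(y, X, contrasts = NULL) {
  y <- as.matrix(y)
  if (nrow(y) != nrow(X)) stop("sample counts of y and X differ")
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) stop("design matrix is rank deficient")
  beta <- qr.coef(qrx, y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  out <- list(beta = beta, residuals = res, sigma2 = sigma2, df = df)
  if (!is.null(contrasts)) {
    contrasts <- as.matrix(contrasts)
    XtXinv <- chol2inv(qr.R(qrx))
    tmat <- matrix(NA_real_, ncol(contrasts), ncol(y))
    for (k in seq_len(ncol(contrasts))) {
      cvec <- contrasts[, k]
      se <- sqrt(sigma2 * drop(t(cvec) %*% XtXinv %*% cvec))
      tmat[k, ] <- drop(t(cvec) %*% beta) / se
    }
    out$t <- tmat
    out$p <- 2 * pt(-abs(tmat), df)
  }
  out
}

#' Principal eigenvariate of region signals
#'
#' First left singular vector of the mean-centred signal matrix (samples x
#' signals), scaled by its singular value / sqrt(n) and signed so the
#' loading sum is positive.  If `positions` and `centre` are given, signals
#' are first restricted to those within `radius` of the centre.
#'
#' @param signals signals x samples matrix (rows are channels/voxels).
#' @param positions optional signals x 3 position matrix (mm).
#' @param centre optional numeric(3) sphere centre (mm).
#' @param radius sphere radius (mm); default 4.
#' @return numeric time series (length = samples) with attribute
#'   `varianceExplained`.
#' @export
extractEigenvariate <- function(signals, positions = NULL, centre = NULL,
                                radius = 4) {
  signals <- as.matrix(signals)
  if (!is.null(positions) && !is.null(centre)) {
    d2 <- rowSums((positions - matrix(centre, nrow(positions), 3, byrow = TRUE))^2)
    keep <- which(d2 <= radius^2)
    if (!length(keep))
      stop(sprintf("no signals within %g mm of centre (%g, %g, %g)",
                   radius, centre[1], centre[2], centre[3]))
    signals <- signals[keep, , drop = FALSE]
  }
  Y <- t(signals)                       # samples x k
  Y <- sweep(Y, 2, colMeans(Y))
  sv <- svd(Y)
  u <- sv$u[, 1] * sv$d[1] / sqrt(nrow(Y))
  if (sum(sv$v[, 1]) < 0) u <- -u
  attr(u, "varianceExplained") <- sv$d[1]^2 / sum(sv$d^2)
  u
}

#' Write design events as CSV
#' @param design a `BlockDesign`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDesignCSV <- function(design, path) {
  df <- design$events
  df$session_length <- design$session_length
  df$sampling_rate <- design$sampling_rate
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read design events written by [writeDesignCSV()]
#' @param path input path.
#' @return a `BlockDesign`.
#' @export
readDesignCSV <- function(path) {
  df <- read.csv(path)
  ev <- df[, c("condition", "onset", "duration")]
  ev$onset <- as.numeric(ev$onset)
  ev$duration <- as.numeric(ev$duration)
  structure(list(events = ev,
                 session_length = as.numeric(df$session_length[1]),
                 sampling_rate = as.numeric(df$sampling_rate[1]),
                 conditions = unique(df$condition)),
            class = "BlockDesign")
}
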