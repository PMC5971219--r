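#' @import methods
#' @importFrom stats sd var median mad quantile rnorm runif rpois coef
#'   pf pt convolve smooth.spline predict approx optimize setNames
#' @importFrom utils head tail read.table write.table read.csv write.csv
#' @useDynLib fnirsDCM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Labelled tetrahedral head mesh
#'
#' A volumetric tetrahedral mesh standing in for a layered infant head
#' segmentation.  Tissue labels per element: 1 = scalp/skull/extra-cerebral,
#' 2 = CSF, 3 = brain.  The scalp face lies at z = 0 and depth increases
#' with +z; coordinates are in mm.
#'
#' @slot nodes numeric matrix, nodes x 3, coordinates in mm.
#' @slot elements integer matrix, elements x 4, node indices (1-based).
#' @slot elementLabel integer vector, tissue class per element.
#' @slot boundaryFaces integer matrix, faces x 3, triangles on the surface.
#' @export
setClass("HeadMesh",
  representation(
    nodes = "matrix",
    elements = "matrix",
    elementLabel = "integer",
    boundaryFaces = "matrix"
  )
)

setValidity("HeadMesh", function(object) {
  msg <- character()
  n <- nrow(object@nodes)
  if (ncol(object@nodes) != 3L) msg <- c(msg, "nodes must be an n x 3 matrix")
  if (ncol(object@elements) != 4L) msg <- c(msg, "elements must be an m x 4 matrix")
  if (length(object@elementLabel) != nrow(object@elements))
    msg <- c(msg, "one tissue label per element required")
  if (nrow(object@elements) > 0L) {
    idx <- range(object@elements)
    if (idx[1] < 1L || idx[2] > n) msg <- c(msg, "element node index out of range")
    if (!all(object@elementLabel %in% 1:3))
      msg <- c(msg, "element labels must be in {1, 2, 3}")
    vols <- tetVolumes(object@nodes, object@elements)
    if (any(vols <= 0)) msg <- c(msg, "all tetrahedra must be positively oriented")
  }
  if (length(msg)) msg else TRUE
})

#' Optode array
#'
#' Source and detector positions plus the list of source-detector pairs
#' (channels) measured at a nominal separation.
#'
#' @slot sources data.frame with columns id, x, y, z (mm).
#' @slot detectors data.frame with columns id, x, y, z (mm).
#' @slot channels data.frame with columns source, detector (ids).
#' @slot nominalSeparation numeric, channel separation in mm.
#' @export
setClass("OptodeArray",
  representation(
    sources = "data.frame",
    detectors = "data.frame",
    channels = "data.frame",
    nominalSeparation = "numeric"
  )
)

setValidity("OptodeArray", function(object) {
  msg <- character()
  need <- c("id", "x", "y", "z")
  if (!all(need %in% names(object@sources))) msg <- c(msg, "sources need id,x,y,z")
  if (!all(need %in% names(object@detectors))) msg <- c(msg, "detectors need id,x,y,z")
  if (!all(c("source", "detector") %in% names(object@channels)))
    msg <- c(msg, "channels need source,detector columns")
  if (!length(msg)) {
    if (!all(object@channels$source %in% object@sources$id))
      msg <- c(msg, "channel refers to unknown source id")
    if (!all(object@channels$detector %in% object@detectors$id))
      msg <- c(msg, "channel refers to unknown detector id")
  }
  if (length(msg)) msg else TRUE
})

#' Multi-channel sampled time series
#'
#' Channels x samples matrix with sampling-rate and content metadata.
#' `kind` distinguishes raw intensity, optical density (dimensionless) and
#' chromophore concentration changes (micromolar).
#'
#' @slot values numeric matrix, channels x samples.
#' @slot samplingRate sampling rate in Hz.
#' @slot kind one of "intensity", "optical_density", "concentration".
#' @slot axisInfo character per row: wavelength ("770nm") or chromophore
#'   ("HbO", "HbR") annotation.
#' @slot units measurement units ("au", "OD", "uM").
#' @export
setClass("ChannelTimeSeries",
  representation(
    values = "matrix",
    samplingRate = "numeric",
    kind = "character",
    axisInfo = "character",
    units = "character"
  )
)

setValidity("ChannelTimeSeries", function(object) {
  msg <- character()
  if (!object@kind %in% c("intensity", "optical_density", "concentration"))
    msg <- c(msg, "kind must be intensity, optical_density or concentration")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (anyNA(object@values)) msg <- c(msg, "values must not contain NA")
  if (length(object@axisInfo) && length(object@axisInfo) != nrow(object@values))
    msg <- c(msg, "axisInfo must annotate every channel row")
  if (length(msg)) msg else TRUE
})

#' Channel sensitivity matrix (photon measurement density functions)
#'
#' Per-wavelength sensitivity of each channel's log-measurement to local
#' absorption changes, as channels x nodes matrices, with an optional
#' channels x regions condensation.
#'
#' @slot S0 named list (by wavelength) of channels x nodes matrices.
#' @slot regionSensitivity named list (by wavelength) of channels x regions
#'   matrices, possibly empty.
#' @slot channelNames character, one name per channel row.
#' @export
setClass("SensitivityMatrix",
  representation(
    S0 = "list",
    regionSensitivity = "list",
    channelNames = "character"
  )
)

setValidity("SensitivityMatrix", function(object) {
  msg <- character()
  for (w in names(object@S0)) {
    m <- object@S0[[w]]
    if (!is.matrix(m) || any(!is.finite(m)))
      msg <- c(msg, sprintf("S0[%s] must be a finite matrix", w))
    else if (nrow(m) != length(object@channelNames))
      msg <- c(msg, sprintf("S0[%s] row count must equal channel count", w))
  }
  if (length(msg)) msg else TRUE
})

#' Dynamic causal model specification
#'
#' One bilinear deterministic DCM: intrinsic coupling A (Hz), per-input
#' modulatory matrices B (Hz), and driving-input weights C (Hz).  Structural
#' zeros are exactly zero; A carries self-connections on its diagonal.
#'
#' @slot regions ordered region names.
#' @slot A n x n intrinsic coupling matrix.
#' @slot B named list of n x n modulatory matrices, one per input.
#' @slot C n x m driving-input matrix.
#' @slot inputs ordered input (condition) names.
#' @slot name model label.
#' @export
setClass("DCMSpec",
  representation(
    regions = "character",
    A = "matrix",
    B = "list",
    C = "matrix",
    inputs = "character",
    name = "character"
  )
)

setValidity("DCMSpec", function(object) {
  msg <- character()
  n <- length(object@regions)
  m <- length(object@inputs)
  if (!all(dim(object@A) == c(n, n))) msg <- c(msg, "A must be n x n")
  if (!all(dim(object@C) == c(n, m))) msg <- c(msg, "C must be n x m")
  if (length(object@B) != m) msg <- c(msg, "one B matrix per input required")
  for (b in object@B) if (!all(dim(b) == c(n, n))) msg <- c(msg, "each B must be n x n")
  if (length(msg)) msg else TRUE
})

#' Posterior fit from variational Laplace
#'
#' Posterior moments over DCM parameters together with the variational free
#' energy F (nats), its accuracy/complexity decomposition, the per-iteration
#' F trace, estimated noise hyperparameters and the fitted prediction.
#'
#' @slot mean named posterior mean vector.
#' @slot cov posterior covariance matrix.
#' @slot hyper named numeric, posterior log-precision per noise group.
#' @slot F variational free energy (nats).
#' @slot accuracy expected log-likelihood component of F.
#' @slot complexity KL(posterior || prior), so F = accuracy - complexity.
#' @slot trace numeric, F after each accepted iteration.
#' @slot prediction fitted prediction at the posterior mean.
#' @slot priors the PriorSpec-like list used for the fit.
#' @export
setClass("PosteriorFit",
  representation(
    mean = "numeric",
    cov = "matrix",
    hyper = "numeric",
    F = "numeric",
    accuracy = "numeric",
    complexity = "numeric",
    trace = "numeric",
    prediction = "matrix",
    priors = "list"
  )
)

setValidity("PosteriorFit", function(object) {
  msg <- character()
  if (!is.finite(object@F)) msg <- c(msg, "free energy must be finite")
  p <- length(object@mean)
  if (!all(dim(object@cov) == c(p, p))) msg <- c(msg, "covariance dimension mismatch")
  else {
    sym <- max(abs(object@cov - t(object@cov)))
    if (sym > 1e-8 * max(1, max(abs(object@cov))))
      msg <- c(msg, "covariance must be symmetric")
    ev <- min(eigen((object@cov + t(object@cov)) / 2, symmetric = TRUE,
                    only.values = TRUE)$values)
    if (ev < -1e-8 * max(1, max(abs(object@cov))))
      msg <- c(msg, "covariance must be positive semidefinite")
  }
  if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "HeadMesh", function(object) {
  cat(sprintf("HeadMesh: %d nodes, %d tetrahedra, %d boundary faces\n",
              nrow(object@nodes), nrow(object@elements), nrow(object@boundaryFaces)))
  tab <- table(factor(object@elementLabel, levels = 1:3,
                      labels = c("scalp/skull", "CSF", "brain")))
  cat("  elements by tissue:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "OptodeArray", function(object) {
  cat(sprintf("OptodeArray: %d sources, %d detectors, %d channels (separation %g mm)\n",
              nrow(object@sources), nrow(object@detectors), nrow(object@channels),
              object@nominalSeparation))
})

setMethod("show", "ChannelTimeSeries", function(object) {
  cat(sprintf("ChannelTimeSeries [%s, %s]: %d channels x %d samples @ %g Hz\n",
              object@kind, object@units, nrow(object@values), ncol(object@values),
              object@samplingRate))
})

setMethod("show", "SensitivityMatrix", function(object) {
  cat(sprintf("SensitivityMatrix: %d channels, wavelengths: %s\n",
              length(object@channelNames), paste(names(object@S0), collapse = ", ")))
})

setMethod("show", "DCMSpec", function(object) {
  cat(sprintf("DCMSpec '%s': regions %s; inputs %s\n", object@name,
              paste(object@regions, collapse = ", "),
              paste(object@inputs, collapse = ", ")))
  nb <- vapply(object@B, function(b) sum(b != 0), integer(1))
  cat(sprintf("  A: %d nonzero; B nonzeros per input: %s; C: %d nonzero\n",
              sum(object@A != 0), paste(nb, collapse = ", "), sum(object@C != 0)))
})

setMethod("show", "PosteriorFit", function(object) {
  cat(sprintf("PosteriorFit: %d parameters, F = %.3f nats (%d iterations)\n",
              length(object@mean), object@F, length(object@trace)))
})

## ---- basic accessors ----------------------------------------------------

#' Number of mesh nodes
#' @param x a HeadMesh
#' @return integer
#' @export
nNodes <- function(x) nrow(x@nodes)

#' Number of mesh elements
#' @param x a HeadMesh
#' @return integer
#' @export
nElements <- function(x) nrow(x@elements)

#' Number of channels of an array or time series
#' @param x an OptodeArray or ChannelTimeSeries
#' @return integer
#' @export
nChannels <- function(x) {
  if (is(x, "OptodeArray")) nrow(x@channels) else nrow(x@values)
}

#' Sampling rate accessor
#' @param x a ChannelTimeSeries
#' @return sampling rate in Hz
#' @export
samplingRate <- function(x) x@samplingRate

#' Time-series values accessor
#' @param x a ChannelTimeSeries
#' @return channels x samples matrix
#' @export
seriesValues <- function(x) x@values

#' Free energy accessor
#' @param fit a PosteriorFit
#' @return variational free energy in nats
#' @export
freeEnergy <- function(fit) fit@F

#' Posterior mean accessor
#' @param fit a PosteriorFit
#' @return named numeric vector
#' @export
posteriorMean <- function(fit) fit@mean

#' Posterior covariance accessor
#' @param fit a PosteriorFit
#' @return covariance matrix
#' @export
posteriorCov <- function(fit) fit@cov
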