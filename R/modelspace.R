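## The 13-model space over (IFG, STS, TPJ), fixed-effects Bayesian model
## selection and averaging, and the cross-method agreement statistics
## (Pearson, robust regression, bootstrap regression).

#' The four modulable inter-regional connections, in canonical order
#' @return data.frame with from/to region names.
#' @export
modulableConnections <- function() {
  data.frame(from = c("STS", "TPJ", "STS", "IFG"),
             to = c("TPJ", "STS", "IFG", "STS"))
}

#' Build the 13-model space
#'
#' All models share the same skeleton: auditory input for both conditions
#' (V, NV) drives STS; intrinsic connections are bidirectional STS-TPJ and
#' STS-IFG plus self-connections.  The models differ only in which
#' connection (if any) is modulated: model 1 has no modulation; models 2-5
#' put the V modulation on STS->TPJ, TPJ->STS, STS->IFG, IFG->STS in that
#' order; models 6-9 put the NV modulation on the same ordered connections
#' (so model 8 carries NV on STS->IFG); models 10-13 put both V and NV on
#' the same ordered connection.  The enumeration is the package's
#' reconstruction consistent with the published structural constraints and
#' parameter census (91 intrinsic, 26 input, 8 + 8 modulatory parameters).
#'
#' @param A_values optional named values for simulation templates; by
#'   default intrinsic couplings carry nominal values (off-diagonal 0.25,
#'   self -0.5) and B/C structural entries are 0 with free structure.
#' @return a `ModelSpace`: list of 13 [DCMSpec-class] objects named
#'   model_1 ... model_13.
#' @export
buildModelSpace <- function(A_values = NULL) {
  rg <- c("IFG", "STS", "TPJ")
  inputs <- c("V", "NV")
  conn <- modulableConnections()
  n <- length(rg)
  A <- matrix(0, n, n, dimnames = list(rg, rg))
  diag(A) <- -0.5
  for (r in seq_len(nrow(conn)))
    A[conn$to[r], conn$from[r]] <- if (is.null(A_values)) 0.25 else
      A_values[paste0(conn$from[r], "->", conn$to[r])]
  C <- matrix(0, n, 2, dimnames = list(rg, inputs))
  Cstruct <- C > 0
  Cstruct["STS", ] <- TRUE
  Astruct <- A != 0 | diag(n) > 0

  makeModel <- function(idx, vConn, nvConn) {
    B <- list(V = matrix(0, n, n, dimnames = list(rg, rg)),
              NV = matrix(0, n, n, dimnames = list(rg, rg)))
    Bstruct <- lapply(B, function(b) b != 0)
    if (!is.na(vConn))
      Bstruct$V[conn$to[vConn], conn$from[vConn]] <- TRUE
    if (!is.na(nvConn))
      Bstruct$NV[conn$to[nvConn], conn$from[nvConn]] <- TRUE
    dcmSpec(rg, A, B, C, inputs, sprintf("model_%d", idx),
            structure = list(A = Astruct, B = Bstruct, C = Cstruct))
  }

  space <- c(
    list(makeModel(1, NA, NA)),
    lapply(1:4, function(k) makeModel(1 + k, k, NA)),
    lapply(1:4, function(k) makeModel(5 + k, NA, k)),
    lapply(1:4, function(k) makeModel(9 + k, k, k))
  )
  names(space) <- sprintf("model_%d", 1:13)
  structure(space, class = "ModelSpace",
            provenance = paste("reconstructed enumeration: shared STS-driven",
                               "skeleton; single-connection V, NV and V+NV",
                               "modulations in canonical connection order"))
}

#' Parameter census of a model space
#'
#' Counts free parameters across all models: intrinsic (A, including
#' self-connections), driving inputs (C), and modulatory effects per
#' condition.
#'
#' @param space a `ModelSpace`.
#' @return named numeric: n_models, A, C, B_V, B_NV.
#' @export
modelSpaceCensus <- function(space) {
  a <- sum(vapply(space, function(m) sum(dcmStructure(m)$A), numeric(1)))
  cc <- sum(vapply(space, function(m) sum(dcmStructure(m)$C), numeric(1)))
  bv <- sum(vapply(space, function(m) sum(dcmStructure(m)$B$V), numeric(1)))
  bnv <- sum(vapply(space, function(m) sum(dcmStructure(m)$B$NV), numeric(1)))
  c(n_models = length(space), A = a, C = cc, B_V = bv, B_NV = bnv)
}

#' Fixed-effects Bayesian model selection
#'
#' Posterior model probabilities proportional to exp(F_m) under a uniform
#' model prior; ties for the best model break to the lowest index.
#'
#' @param fits list of [PosteriorFit-class] objects (one per model), or a
#'   numeric vector of free energies.
#' @param modelNames optional model labels.
#' @return a `BMSResult` list: `table` (model, F, dF, prob), `best`.
#' @export
bms <- function(fits, modelNames = NULL) {
  Fv <- if (is.numeric(fits)) fits else {
    if (any(vapply(fits, is.null, logical(1)))) {
      miss <- which(vapply(fits, is.null, logical(1)))
      stop(sprintf("missing fit for model(s) %s", paste(miss, collapse = ", ")))
    }
    vapply(fits, freeEnergy, numeric(1))
  }
  if (is.null(modelNames))
    modelNames <- if (!is.null(names(Fv))) names(Fv) else
      sprintf("model_%d", seq_along(Fv))
  dF <- Fv - max(Fv)
  prob <- exp(dF) / sum(exp(dF))
  best <- unname(which(dF == 0)[1])
  structure(list(table = data.frame(model = modelNames, F = Fv, dF = dF,
                                    prob = prob, row.names = NULL),
                 best = best, bestName = modelNames[best]),
            class = "BMSResult")
}

#' Bayesian model averaging over a fitted model space
#'
#' Mixture moments across models weighted by their posterior probabilities;
#' a parameter absent from a model contributes a point mass at zero with
#' that model's weight.
#'
#' @param fits list of [PosteriorFit-class] objects.
#' @param bmsResult the matching `BMSResult`.
#' @return a `BMAResult` data.frame: parameter, mean, variance.
#' @export
bma <- function(fits, bmsResult) {
  w <- bmsResult$table$prob
  params <- unique(unlist(lapply(fits, function(f) names(f@mean))))
  mean1 <- m2 <- setNames(numeric(length(params)), params)
  for (m in seq_along(fits)) {
    mu <- fits[[m]]@mean
    va <- diag(fits[[m]]@cov)
    idx <- match(names(mu), params)
    mean1[idx] <- mean1[idx] + w[m] * mu
    m2[idx] <- m2[idx] + w[m] * (va + mu^2)
    # absent parameters: point mass at zero adds nothing to either moment
  }
  out <- data.frame(parameter = params, mean = unname(mean1),
                    variance = pmax(unname(m2 - mean1^2), 0))
  class(out) <- c("BMAResult", "data.frame")
  out
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y numeric vectors, n >= 3, non-degenerate.
#' @return list with `r` and `p` (t transform).
#' @export
pearson <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Robust linear regression (IRLS, bisquare weights)
#'
#' Iteratively reweighted least squares with Tukey's bisquare psi (tuning
#' constant 4.685, MAD-based scale), as used for comparing connectivity
#' estimates across methods.  The F statistic and R^2 are computed on the
#' final weighted fit with df = (1, n - 2).
#'
#' @param x,y numeric vectors, n >= 3.
#' @param maxit IRLS iteration cap.
#' @return list: slope, intercept, Fstat, p, R2, weights, converged.
#' @export
robustRegression <- function(x, y, maxit = 50) {
  if (length(x) < 3) stop("need at least 3 observations")
  fit <- withCallingHandlers(
    MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = 4.685, maxit = maxit),
    warning = function(w) {
      if (grepl("failed to converge", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  wts <- fit$w
  yhat <- fitted(fit)
  ybar <- sum(wts * y) / sum(wts)
  sst <- sum(wts * (y - ybar)^2)
  ssr <- sum(wts * (y - yhat)^2)
  R2 <- 1 - ssr / sst
  n <- length(x)
  Fstat <- (sst - ssr) / (ssr / (n - 2))
  if (!fit$converged)
    warning("IRLS did not converge within the iteration cap; returning last iterate")
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       Fstat = Fstat, p = pf(Fstat, 1, n - 2, lower.tail = FALSE),
       R2 = R2, weights = wts, converged = fit$converged)
}

#' Bootstrap confidence interval for the robust-regression slope
#'
#' Seeded case resampling; degenerate resamples (zero x variance) are
#' redrawn and counted.  Point estimates come from the full-sample robust
#' fit; the CI is the percentile interval over bootstrap slopes.
#'
#' @param x,y numeric vectors, n >= 5.
#' @param n_boot number of bootstrap resamples.
#' @param seed RNG seed.
#' @param level confidence level.
#' @return list: slope, ci (length 2), R2, Fstat, p, n_redrawn.
#' @export
bootstrapRegression <- function(x, y, n_boot = 1000, seed, level = 0.95) {
  if (length(x) < 5) stop("need at least 5 observations")
  if (missing(seed)) stop("a seed is required")
  full <- robustRegression(x, y)
  n <- length(x)
  slopes <- numeric(n_boot)
  redrawn <- 0
  withSeed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (var(x[idx]) > 0) break
        redrawn <- redrawn + 1
      }
      slopes[b] <- suppressWarnings(robustRegression(x[idx], y[idx])$slope)
    }
  })
  alpha <- (1 - level) / 2
  list(slope = full$slope,
       ci = unname(quantile(slopes, c(alpha, 1 - alpha))),
       R2 = full$R2, Fstat = full$Fstat, p = full$p,
       n_redrawn = redrawn)
}

#' Write a model-comparison report as CSV
#' @param bmsResult a `BMSResult`.
#' @param bmaResult optional `BMAResult`.
#' @param prefix output path prefix.
#' @return written paths, invisibly.
#' @export
writeComparisonCSV <- function(bmsResult, bmaResult = NULL, prefix) {
  paths <- sprintf("%s_bms.csv", prefix)
  write.csv(bmsResult$table, paths, row.names = FALSE)
  if (!is.null(bmaResult)) {
    p2 <- sprintf("%s_bma.csv", prefix)
    write.csv(as.data.frame(bmaResult), p2, row.names = FALSE)
    paths <- c(paths, p2)
  }
  invisible(paths)
}
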