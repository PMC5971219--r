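## The forward model: bilinear neuronal dynamics, balloon hemodynamics,
## chromophore mapping, and the augmented fNIRS optics observation
## y(lambda) = epsH WH S dHc + epsQ WQ S dQc with S = k * S0, plus a BOLD
## observation analogue for twin-modality simulation.

#' Construct a DCM specification
#'
#' @param regions ordered region names.
#' @param A n x n intrinsic coupling (Hz); diagonal = self-connections.
#' @param B named list of n x n modulatory matrices, one per input.
#' @param C n x m driving-input weights (Hz).
#' @param inputs ordered input names.
#' @param name model label.
#' @param structure optional list of logical masks (`A`, `B`, `C`) marking
#'   free parameters; defaults to the nonzero pattern (A diagonal always
#'   free).
#' @return a [DCMSpec-class].
#' @export
dcmSpec <- function(regions, A, B, C, inputs, name = "model",
                    structure = NULL) {
  n <- length(regions)
  m <- length(inputs)
  dimnames(A) <- list(regions, regions)
  dimnames(C) <- list(regions, inputs)
  B <- lapply(B, function(b) { dimnames(b) <- list(regions, regions); b })
  names(B) <- inputs
  if (is.null(structure)) {
    structure <- list(
      A = (A != 0) | diag(n) > 0,
      B = lapply(B, function(b) b != 0),
      C = C != 0
    )
  }
  # Class= named in full: a `C = ` argument would otherwise partially
  # match new()'s Class formal
  obj <- new(Class = "DCMSpec", regions = regions, A = A, B = B, C = C,
             inputs = inputs, name = name)
  attr(obj, "structure") <- structure
  obj
}

#' Free-parameter structure of a DCM
#' @param spec a [DCMSpec-class].
#' @return list of logical masks A, B (per input), C.
#' @export
dcmStructure <- function(spec) {
  s <- attr(spec, "structure")
  if (is.null(s)) {
    n <- length(spec@regions)
    s <- list(A = (spec@A != 0) | diag(n) > 0,
              B = lapply(spec@B, function(b) b != 0),
              C = spec@C != 0)
  }
  s
}

#' Hemodynamic (balloon-model) parameters
#'
#' Region-wise balloon-model constants with standard literature defaults:
#' signal decay kappa_s, autoregulation gamma (s^-1), venous transit time
#' tau (s), vessel stiffness alpha, resting oxygen extraction E0, and
#' baseline total/deoxy hemoglobin concentrations (micromolar) for the
#' chromophore mapping.  Only products of the baselines with the optical
#' sensitivity are identifiable; the observation scaling k absorbs the rest.
#'
#' @param n_regions number of regions.
#' @param kappa_s,gamma,tau,alpha,E0,HbT0,HbR0 scalars or length-n vectors.
#' @return a `HemodynamicParameters` list of per-region vectors.
#' @export
hemodynamicParameters <- function(n_regions = 3, kappa_s = 0.64, gamma = 0.32,
                                  tau = 2, alpha = 0.32, E0 = 0.32,
                                  HbT0 = 100, HbR0 = 40) {
  rep_n <- function(x) rep_len(x, n_regions)
  p <- list(kappa_s = rep_n(kappa_s), gamma = rep_n(gamma), tau = rep_n(tau),
            alpha = rep_n(alpha), E0 = rep_n(E0), HbT0 = rep_n(HbT0),
            HbR0 = rep_n(HbR0))
  if (any(unlist(p[c("kappa_s", "gamma", "tau", "E0")]) <= 0))
    stop("hemodynamic rate parameters must be positive")
  if (any(p$alpha <= 0 | p$alpha >= 1)) stop("alpha must lie in (0, 1)")
  structure(p, class = "HemodynamicParameters")
}

#' fNIRS observation model
#'
#' The augmented optics equation: per wavelength, optical-density changes
#' are epsH WH S dHc + epsQ WQ S dQc with S = k * S0, where S0 is the
#' channels x regions optical sensitivity and k a free scaling accommodating
#' source strength and detection efficiency.
#'
#' @param S0 named list (by wavelength) of channels x regions sensitivities.
#' @param extinction 2 x 2 matrix, rows = wavelengths (same order as S0),
#'   columns = (HbO, HbR).
#' @param WH,WQ pial-vein correction factors per wavelength (default 1: no
#'   correction).
#' @param k positive sensitivity scaling.
#' @return an `FNIRSObservationModel` list.
#' @export
fnirsObservationModel <- function(S0,
                                  extinction = defaultExtinctionCoefficients(),
                                  WH = c(1, 1), WQ = c(1, 1), k = 1) {
  if (k <= 0) stop("the sensitivity scaling k must be positive")
  if (length(S0) != 2) stop("S0 must cover the two wavelengths")
  if (any(extinction <= 0)) stop("extinction coefficients must be positive")
  structure(list(S0 = S0, extinction = extinction, WH = WH, WQ = WQ, k = k),
            class = "FNIRSObservationModel")
}

#' Bilinear neuronal state derivative
#'
#' dz/dt = (A + sum_j u_j B_j) z + C u.
#'
#' @param z region states.
#' @param u input values (length = number of inputs).
#' @param spec a [DCMSpec-class].
#' @return dz/dt.
#' @export
neuralDerivative <- function(z, u, spec) {
  n <- length(spec@regions)
  if (length(z) != n || length(u) != length(spec@inputs))
    stop("state or input dimension mismatch")
  Aeff <- spec@A
  for (j in seq_along(u)) Aeff <- Aeff + u[j] * spec@B[[j]]
  drop(Aeff %*% z + spec@C %*% u)
}

#' Balloon-model state derivatives
#'
#' ds/dt = z - kappa_s s - gamma (f - 1); df/dt = s;
#' tau dv/dt = f - v^(1/alpha);
#' tau dq/dt = f (1 - (1 - E0)^(1/f)) / E0 - v^(1/alpha) q / v.
#'
#' @param state list or numeric with s, f, v, q per region (f, v, q > 0).
#' @param z neuronal states.
#' @param params a `HemodynamicParameters` list.
#' @return list of derivatives ds, df, dv, dq.
#' @export
hemodynamicDerivative <- function(state, z, params) {
  s <- state$s; f <- state$f; v <- state$v; q <- state$q
  if (any(f <= 0) || any(v <= 0) || any(q <= 0))
    stop("f, v and q must stay positive")
  vexp <- v^(1 / params$alpha)
  ext <- (1 - (1 - params$E0)^(1 / f)) / params$E0
  list(ds = z - params$kappa_s * s - params$gamma * (f - 1),
       df = s,
       dv = (f - vexp) / params$tau,
       dq = (f * ext - vexp * q / v) / params$tau)
}

#' Chromophore concentration changes from balloon states
#'
#' dHbT = HbT0 (v - 1); dQc = HbR0 (q - 1); dHc = dHbT - dQc (micromolar).
#'
#' @param v venous volume (normalised).
#' @param q deoxyhemoglobin content (normalised).
#' @param params a `HemodynamicParameters` list.
#' @return list with `dHc` (oxy) and `dQc` (deoxy) changes; inputs may be
#'   region x time matrices.
#' @export
chromophoreChanges <- function(v, q, params) {
  if (any(v <= 0) || any(q <= 0)) stop("v and q must be positive")
  dHbT <- params$HbT0 * (v - 1)
  dQc <- params$HbR0 * (q - 1)
  list(dHc = dHbT - dQc, dQc = dQc)
}

#' Observe fNIRS optical-density changes
#'
#' Applies the augmented optics equation, stacking wavelengths:
#' y(lambda_i) = epsH(lambda_i) WH(lambda_i) k S0(lambda_i) dHc +
#' epsQ(lambda_i) WQ(lambda_i) k S0(lambda_i) dQc.
#'
#' @param dHc,dQc region x time chromophore changes (micromolar).
#' @param model an `FNIRSObservationModel`.
#' @return (channels * 2) x time matrix, wavelength-1 rows first.
#' @export
observeFnirs <- function(dHc, dQc, model) {
  if (model$k <= 0) stop("the sensitivity scaling k must be positive")
  dHc <- as.matrix(dHc); dQc <- as.matrix(dQc)
  out <- lapply(seq_along(model$S0), function(i) {
    # y = S (epsH WH dHc + epsQ WQ dQc), folded into one product
    mix <- model$extinction[i, 1] * model$WH[i] * dHc +
      model$extinction[i, 2] * model$WQ[i] * dQc
    (model$k * model$S0[[i]]) %*% mix
  })
  do.call(rbind, out)
}

#' BOLD observation equation
#'
#' y = V0 (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v)), the classic static BOLD
#' observation used for the fMRI twin of a simulated dataset.
#'
#' @param v,q balloon states (region x time allowed).
#' @param V0 resting venous volume fraction.
#' @param k1,k2,k3 observation constants; defaults 7 E0, 2, 2 E0 - 0.2.
#' @param E0 resting extraction used for the default constants.
#' @return BOLD signal, same shape as `v`.
#' @export
observeBold <- function(v, q, V0 = 0.04, E0 = 0.32,
                        k1 = 7 * E0, k2 = 2, k3 = 2 * E0 - 0.2) {
  if (any(v <= 0) || any(q <= 0)) stop("v and q must be positive")
  V0 * (k1 * (1 - q) + k2 * (1 - q / v) + k3 * (1 - v))
}

#' Integrate the full DCM generative model
#'
#' Fixed-step 4th-order Runge-Kutta integration of the stacked neuronal and
#' balloon states, with inputs held on their own grid and linearly
#' interpolated at stage times.  Observations are produced at the output
#' sampling rate.
#'
#' @param spec a [DCMSpec-class].
#' @param hemo a `HemodynamicParameters` list.
#' @param obsModel optional `FNIRSObservationModel`; if given, `$y` holds
#'   the stacked optical-density prediction.
#' @param u inputs x samples matrix on the `u_rate` grid.
#' @param u_rate sampling rate of `u` (Hz).
#' @param duration integration length (s).
#' @param dt integration step (s), <= 0.1.
#' @param out_rate output sampling rate (Hz); must divide 1/dt.
#' @param bold if TRUE also return the per-region BOLD observation.
#' @return list with `time`, `z`, `s`, `f`, `v`, `q` (region x time),
#'   `dHc`, `dQc`, and optionally `y` and `bold`.
#' @export
integrateDcm <- function(spec, hemo, obsModel = NULL, u, u_rate,
                         duration, dt = 0.05, out_rate = 10, bold = FALSE) {
  if (dt > 0.1) stop("dt must be <= 0.1 s")
  n <- length(spec@regions)
  m <- length(spec@inputs)
  outEvery <- round(1 / (out_rate * dt))
  if (abs(outEvery - 1 / (out_rate * dt)) > 1e-9)
    stop("1/(out_rate * dt) must be an integer")
  nSteps <- round(duration / dt)
  Bflat <- unlist(spec@B, use.names = FALSE)
  if (!length(Bflat)) Bflat <- numeric(n * n * m)
  res <- dcm_integrate_cpp(spec@A, Bflat, spec@C,
                           hemo$kappa_s, hemo$gamma, hemo$tau, hemo$alpha,
                           hemo$E0, u, 1 / u_rate, dt, nSteps, outEvery)
  if (!res$ok)
    stop(sprintf("DCM integration failed: %s (model '%s')", res$message,
                 spec@name))
  st <- res$states
  z <- st[seq_len(n), , drop = FALSE]
  v <- st[3 * n + seq_len(n), , drop = FALSE]
  q <- st[4 * n + seq_len(n), , drop = FALSE]
  rownames(z) <- rownames(v) <- rownames(q) <- spec@regions
  ch <- chromophoreChanges(v, q, hemo)
  out <- list(time = res$time, z = z,
              s = st[n + seq_len(n), , drop = FALSE],
              f = st[2 * n + seq_len(n), , drop = FALSE],
              v = v, q = q, dHc = ch$dHc, dQc = ch$dQc)
  if (!is.null(obsModel)) out$y <- observeFnirs(ch$dHc, ch$dQc, obsModel)
  if (bold) out$bold <- observeBold(v, q, E0 = hemo$E0[1])
  out
}

#' Serialize a DCM specification to JSON
#' @param spec a [DCMSpec-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDcmJSON <- function(spec, path) {
  s <- dcmStructure(spec)
  flat <- function(m) as.numeric(m)   # column-major
  jsonlite::write_json(list(
    name = spec@name, regions = spec@regions, inputs = spec@inputs,
    A = flat(spec@A), B = lapply(spec@B, flat), C = flat(spec@C),
    structure = list(A = flat(s$A), B = lapply(s$B, flat), C = flat(s$C))
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a DCM specification written by [writeDcmJSON()]
#' @param path input path.
#' @return a [DCMSpec-class].
#' @export
readDcmJSON <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- length(j$regions)
  m <- length(j$inputs)
  toM <- function(x, nr, nc) matrix(as.numeric(unlist(x)), nr, nc)
  st <- list(A = toM(j$structure$A, n, n) > 0,
             B = lapply(seq_len(m), function(k)
               toM(j$structure$B[[k]], n, n) > 0),
             C = toM(j$structure$C, n, m) > 0)
  names(st$B) <- j$inputs
  dimnames(st$A) <- list(j$regions, j$regions)
  dimnames(st$C) <- list(j$regions, j$inputs)
  st$B <- lapply(st$B, function(b) {
    dimnames(b) <- list(j$regions, j$regions); b
  })
  dcmSpec(j$regions, toM(j$A, n, n),
          lapply(seq_len(m), function(k) toM(j$B[[k]], n, n)),
          toM(j$C, n, m), j$inputs, j$name, structure = st)
}
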