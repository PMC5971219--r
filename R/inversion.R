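## Variational-Laplace inversion: Gaussian fixed-form variational Bayes with
## Gauss-Newton ascent on the free energy, finite-difference Jacobians and
## Levenberg-style damping, plus the DCM parameter packing conventions.

#' Default priors and parameter map for a DCM
#'
#' Builds the flat parameter ordering (A row-major off-diagonals, A
#' diagonal, B per input, C, hemodynamic log-scalings, observation scaling)
#' with established shrinkage priors: off-diagonal couplings N(0, n/64);
#' self-connections as log-scalings of -0.5 s^-1 with N(0, 1/256);
#' modulations and inputs N(0, 1); transit/stiffness log-scalings
#' N(0, 1/256); and for fNIRS an informed log-normal prior on the
#' sensitivity scaling, log k ~ N(0, 1/16).
#'
#' @param spec a [DCMSpec-class]; free parameters come from its structure.
#' @param modality "fnirs" (adds log k) or "bold".
#' @return a `PriorSpec` list: `pE` (prior mean), `pV` (prior variance),
#'   and `map` (per-parameter type and indices).
#' @export
dcmPriors <- function(spec, modality = c("fnirs", "bold")) {
  modality <- match.arg(modality)
  st <- dcmStructure(spec)
  rg <- spec@regions
  n <- length(rg)
  nm <- character(); pE <- numeric(); pV <- numeric(); map <- list()
  add <- function(name, mean, var, entry) {
    nm <<- c(nm, name); pE <<- c(pE, mean); pV <<- c(pV, var)
    map[[name]] <<- entry
  }
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && st$A[i, j])
      add(sprintf("A_%s->%s", rg[j], rg[i]), 0, n / 64,
          list(type = "A", i = i, j = j))
  for (i in seq_len(n))
    add(sprintf("Aself_%s", rg[i]), 0, 1 / 256,
        list(type = "Aself", i = i, j = i))
  for (u in seq_along(spec@inputs))
    for (i in seq_len(n)) for (j in seq_len(n))
      if (st$B[[u]][i, j])
        add(sprintf("B_%s_%s->%s", spec@inputs[u], rg[j], rg[i]), 0, 1,
            list(type = "B", i = i, j = j, input = u))
  for (u in seq_along(spec@inputs))
    for (i in seq_len(n))
      if (st$C[i, u])
        add(sprintf("C_%s->%s", spec@inputs[u], rg[i]), 0, 1,
            list(type = "C", i = i, input = u))
  for (i in seq_len(n)) {
    add(sprintf("tau_%s", rg[i]), 0, 1 / 256, list(type = "tau", i = i))
    add(sprintf("alpha_%s", rg[i]), 0, 1 / 256, list(type = "alpha", i = i))
  }
  if (modality == "fnirs")
    add("logk", 0, 1 / 16, list(type = "logk"))
  names(pE) <- names(pV) <- nm
  structure(list(pE = pE, pV = pV, map = map, modality = modality),
            class = "PriorSpec")
}

#' Pack DCM values into the flat parameter vector
#'
#' Inverse of [unpackParameters()]: reads the model's (and hemodynamic /
#' observation) values into the deterministic ordering defined by the prior
#' map.  Self-connections and hemodynamic parameters are stored as
#' log-scalings of their reference values.
#'
#' @param spec a [DCMSpec-class] carrying parameter values.
#' @param priors a `PriorSpec` from [dcmPriors()].
#' @param hemo a `HemodynamicParameters` list (reference values assumed
#'   tau = 2, alpha = 0.32 scalings).
#' @param k observation scaling (fNIRS).
#' @return named numeric parameter vector.
#' @export
packParameters <- function(spec, priors, hemo = hemodynamicParameters(length(spec@regions)),
                           k = 1) {
  theta <- numeric(length(priors$pE))
  names(theta) <- names(priors$pE)
  for (nmi in names(priors$map)) {
    e <- priors$map[[nmi]]
    theta[nmi] <- switch(e$type,
      A = spec@A[e$i, e$j],
      Aself = log(-spec@A[e$i, e$i] / 0.5),
      B = spec@B[[e$input]][e$i, e$j],
      C = spec@C[e$i, e$input],
      tau = log(hemo$tau[e$i] / 2),
      alpha = log(hemo$alpha[e$i] / 0.32),
      logk = log(k))
  }
  theta
}

#' Unpack a flat parameter vector into model components
#'
#' @param theta named parameter vector (ordering of [dcmPriors()]).
#' @param priors the matching `PriorSpec`.
#' @param spec template [DCMSpec-class] (structure source).
#' @param hemo template `HemodynamicParameters`.
#' @return list with `spec`, `hemo`, and `k`.
#' @export
unpackParameters <- function(theta, priors, spec,
                             hemo = hemodynamicParameters(length(spec@regions))) {
  A <- spec@A; B <- spec@B; C <- spec@C
  k <- 1
  for (nmi in names(priors$map)) {
    e <- priors$map[[nmi]]
    val <- theta[[nmi]]
    if (e$type == "A") A[e$i, e$j] <- val
    else if (e$type == "Aself") A[e$i, e$i] <- -0.5 * exp(val)
    else if (e$type == "B") B[[e$input]][e$i, e$j] <- val
    else if (e$type == "C") C[e$i, e$input] <- val
    else if (e$type == "tau") hemo$tau[e$i] <- 2 * exp(val)
    else if (e$type == "alpha") hemo$alpha[e$i] <- 0.32 * exp(val)
    else if (e$type == "logk") k <- exp(val)
  }
  # slot assignment on a copy avoids re-running the validity machinery on
  # every generative-model evaluation
  out <- spec
  out@A <- A; out@B <- B; out@C <- C
  list(spec = out, hemo = hemo, k = k)
}

# log-determinant of an SPD matrix via Cholesky
logdet <- function(M) 2 * sum(log(diag(chol(M))))

# symmetric inverse with damped pseudo-inverse fallback
spdInverse <- function(H) {
  H <- (H + t(H)) / 2
  ch <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(ch)) {
    warning("singular curvature; using damped pseudo-inverse")
    ch <- chol(H + diag(max(abs(diag(H)), 1) * 1e-8, nrow(H)))
  }
  chol2inv(ch)
}

#' Variational Laplace inversion of a nonlinear observation model
#'
#' Fixed-form Gaussian variational Bayes: iterated Gauss-Newton ascent on
#' the free energy F = accuracy - complexity under Gaussian priors and
#' Gaussian observation noise with group-wise log-precision
#' hyperparameters.  Jacobians are central finite differences; steps use
#' Levenberg-style damping and an iteration is accepted only if F
#' increases, otherwise the parameters revert and damping grows.
#' Convergence when the accepted improvement falls below `tolF` (0.01
#' nats) or after `maxIter` (64) iterations.
#'
#' @param predict function theta -> predicted data vector.
#' @param priors list with `pE` (prior means) and `pV` (prior variances);
#'   entries with zero variance are fixed at their prior mean.
#' @param y observed data vector (finite).
#' @param noiseGroups integer group index per data point (default: one
#'   group).
#' @param hyperMean,hyperVar Normal hyperprior on each group's
#'   log-precision.
#' @param fixedHyper optional fixed log-precisions (named per group);
#'   disables hyperparameter estimation.
#' @param maxIter iteration cap.
#' @param tolF convergence threshold on the accepted F improvement (nats).
#' @param fdStep relative finite-difference step.
#' @return a [PosteriorFit-class].
#' @export
variationalLaplace <- function(predict, priors, y, noiseGroups = NULL,
                               hyperMean = 4, hyperVar = 1,
                               fixedHyper = NULL, maxIter = 64, tolF = 0.01,
                               fdStep = 1e-4) {
  y <- as.numeric(y)
  if (!all(is.finite(y))) stop("data must be finite")
  if (is.null(noiseGroups)) noiseGroups <- rep(1L, length(y))
  groups <- sort(unique(noiseGroups))
  Ng <- vapply(groups, function(g) sum(noiseGroups == g), numeric(1))
  estHyper <- is.null(fixedHyper)
  lambda <- if (estHyper) rep(hyperMean, length(groups)) else
    rep_len(as.numeric(fixedHyper), length(groups))

  free <- which(priors$pV > 0)
  m0 <- priors$pE[free]
  V0 <- priors$pV[free]
  p <- length(free)
  fullTheta <- function(th) {
    out <- priors$pE
    out[free] <- th
    out
  }
  g0 <- predict(fullTheta(m0))
  if (!all(is.finite(g0)))
    stop("generative model not evaluable at the prior mean")
  N <- length(y)
  if (length(g0) != N) stop("prediction and data lengths differ")

  piVec <- function(lam) exp(lam)[match(noiseGroups, groups)]

  Fcalc <- function(e, J, lam, th, Cq, Clam) {
    Pd <- piVec(lam)
    trJ <- rowSums((J %*% Cq) * J)
    acc <- -0.5 * sum(Pd * e^2) + 0.5 * sum(Ng * lam) -
      0.5 * N * log(2 * pi) - 0.5 * sum(Pd * trJ)
    dth <- th - m0
    klTheta <- 0.5 * (sum(dth^2 / V0) + sum(diag(Cq) / V0) - p +
                        sum(log(V0)) - logdet(Cq))
    klLam <- if (estHyper)
      0.5 * sum(Clam / hyperVar + (lam - hyperMean)^2 / hyperVar - 1 +
                  log(hyperVar / Clam))
    else 0
    list(F = acc - klTheta - klLam, accuracy = acc,
         complexity = klTheta + klLam)
  }

  theta <- m0
  thetaBest <- theta
  nu <- 0   # Levenberg damping; 0 = pure Gauss-Newton
  Fbest <- -Inf
  trace <- numeric(0)
  best <- NULL
  sinceAccept <- 0
  P0 <- 1 / V0

  for (iter in seq_len(maxIter)) {
    g <- predict(fullTheta(theta))
    e <- y - g
    # central finite-difference Jacobian at the expansion point
    J <- matrix(0, N, p)
    for (i in seq_len(p)) {
      h <- fdStep * max(1, abs(theta[i]))
      tp <- theta; tp[i] <- tp[i] + h
      tm <- theta; tm[i] <- tm[i] - h
      J[, i] <- (predict(fullTheta(tp)) - predict(fullTheta(tm))) / (2 * h)
    }
    Clam <- rep(hyperVar, length(groups))
    lam0 <- lambda
    for (hIter in if (estHyper) 1:8 else integer(0)) {
      Pd <- piVec(lambda)
      H <- crossprod(J * sqrt(Pd)) + diag(P0, p)
      Cq <- spdInverse(H)
      trJ <- rowSums((J %*% Cq) * J)
      for (gi in seq_along(groups)) {
        sel <- noiseGroups == groups[gi]
        Rg <- sum(e[sel]^2 + trJ[sel])
        gr <- 0.5 * Ng[gi] - 0.5 * exp(lambda[gi]) * Rg -
          (lambda[gi] - hyperMean) / hyperVar
        he <- -0.5 * exp(lambda[gi]) * Rg - 1 / hyperVar
        step <- gr / he
        lambda[gi] <- lambda[gi] - sign(step) * min(abs(step), 4)
        # precision annealing: let the estimated log-precision rise by at
        # most 2 nats per outer iteration so early Gauss-Newton steps see
        # a tempered landscape (the fixed point is unchanged)
        lambda[gi] <- min(lambda[gi], lam0[gi] + 2)
        Clam[gi] <- -1 / he
      }
    }
    Pd <- piVec(lambda)
    H <- crossprod(J * sqrt(Pd)) + diag(P0, p)
    Cq <- spdInverse(H)
    Fi <- Fcalc(e, J, lambda, theta, Cq, Clam)

    if (is.finite(Fi$F) && Fi$F > Fbest) {
      dF <- Fi$F - Fbest
      Fbest <- Fi$F
      thetaBest <- theta
      best <- list(F = Fi, Cq = Cq, lambda = lambda, g = g,
                   H = H, J = J, e = e, Clam = Clam)
      trace <- c(trace, Fbest)
      nu <- nu / 8
      if (nu < 1e-4) nu <- 0
      sinceAccept <- 0
      if (length(trace) > 1 && dF < tolF) break
    } else {
      # exact F did not improve at the proposed point: revert the
      # expansion to the best accepted point and damp harder
      theta <- thetaBest
      nu <- min(max(nu * 8, 1), 1e8)
      sinceAccept <- sinceAccept + 1
      if (sinceAccept >= 3 || is.null(best)) break
      J <- best$J; e <- best$e; lambda <- best$lambda
      H <- best$H; Cq <- best$Cq; Fi <- best$F; Clam <- best$Clam
    }

    # inner Levenberg search with the Jacobian frozen: each candidate costs
    # one model evaluation; while the (approximate) F improves, keep
    # stepping so a single Jacobian supports several Gauss-Newton moves.
    # The exact F is re-checked at the start of the next iteration.
    found <- FALSE
    eInner <- e
    Finner <- Fi$F
    for (inner in 1:6) {
      grad <- crossprod(J, piVec(lambda) * eInner) - (theta - m0) / V0
      stepped <- FALSE
      for (tries in 1:8) {
        Hd <- H + nu * diag(diag(H), p)
        delta <- drop(spdInverse(Hd) %*% grad)
        thc <- theta + delta
        gc <- predict(fullTheta(thc))
        Fc <- Fcalc(y - gc, J, lambda, thc, Cq, Clam)$F
        if (is.finite(Fc) && Fc > Finner) {
          theta <- thc
          eInner <- y - gc
          Finner <- Fc
          stepped <- TRUE
          found <- TRUE
          nu <- nu / 2
          if (nu < 1e-4) nu <- 0
          break
        }
        nu <- min(max(nu * 8, 1), 1e8)
      }
      if (!stepped) break
    }
    if (!found) break   # no ascent step found at any damping
  }

  if (is.null(best)) stop("free energy never became finite")
  if (!is.finite(Fbest)) stop("non-finite free energy at convergence")
  mu <- fullTheta(thetaBest)[free]
  names(mu) <- names(priors$pE)[free]
  hy <- best$lambda
  names(hy) <- paste0("group", groups)
  new("PosteriorFit",
      mean = mu,
      cov = (best$Cq + t(best$Cq)) / 2,
      hyper = hy,
      F = Fbest,
      accuracy = best$F$accuracy,
      complexity = best$F$complexity,
      trace = trace,
      prediction = matrix(best$g, nrow = 1),
      priors = list(pE = priors$pE, pV = priors$pV, free = free))
}

#' Accuracy / complexity decomposition of a fit
#'
#' F = accuracy - complexity, with complexity the KL divergence from the
#' posterior to the prior (including the hyperparameter term when noise was
#' estimated).
#'
#' @param fit a [PosteriorFit-class].
#' @return named numeric c(accuracy, complexity).
#' @export
freeEnergyComponents <- function(fit) {
  c(accuracy = fit@accuracy, complexity = fit@complexity)
}

#' Serialize a posterior fit to JSON
#' @param fit a [PosteriorFit-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFitJSON <- function(fit, path) {
  jsonlite::write_json(list(
    parameters = names(fit@mean), mean = unname(fit@mean),
    cov = fit@cov, hyper = as.list(fit@hyper), F = fit@F,
    accuracy = fit@accuracy, complexity = fit@complexity,
    trace = fit@trace
  ), path, auto_unbox = TRUE, digits = NA, matrix = "columnmajor")
  invisible(path)
}
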