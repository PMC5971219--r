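## Continuous-wave photon transport on the labelled mesh.
##
## The diffusion approximation (div(kappa grad) + mua) phi = 0 with the Robin
## boundary condition phi + 2 A kappa n.grad(phi) = q is discretised with
## linear tetrahedral finite elements.  Channel sensitivity functions (photon
## measurement density functions) follow from products of the forward field
## of a source and the adjoint field of its detector, normalised by the
## unperturbed measurement (Rytov form), so entries approximate
## d(-ln I)/d(mua) locally.

#' Baseline tissue optical coefficients
#'
#' A replaceable literature-default table of absorption and reduced
#' scattering coefficients per tissue layer and wavelength, for an infant
#' head at 770 and 850 nm.  These are plausible neonatal values from
#' standard compilations, shipped as configurable defaults.  The diffusion
#' coefficient kappa = 1/(3(mua + mus)) is always derived, never stored.
#'
#' @param A_boundary refractive-index-mismatch boundary term (dimensionless,
#'   >= 1); default 2.82 for a tissue-air interface with n ~ 1.4.
#' @return an object of class `OpticalCoefficients`: a list with the
#'   coefficient `table` (tissue, wavelength, mua, mus in mm^-1) and
#'   `A_boundary`.
#' @export
defaultOpticalCoefficients <- function(A_boundary = 2.82) {
  tab <- data.frame(
    tissue = rep(1:3, each = 2),
    wavelength = rep(c(770, 850), 3),
    mua = c(0.017, 0.019, 0.004, 0.004, 0.018, 0.021),
    mus = c(0.74, 0.64, 0.30, 0.30, 0.55, 0.50)
  )
  opticalCoefficients(tab, A_boundary)
}

#' Construct a validated optical-coefficient set
#'
#' @param table data.frame with columns tissue, wavelength, mua, mus
#'   (absorption and reduced scattering, mm^-1).
#' @param A_boundary boundary mismatch term, >= 1.
#' @return an `OpticalCoefficients` list.
#' @export
opticalCoefficients <- function(table, A_boundary = 2.82) {
  stopifnot(all(c("tissue", "wavelength", "mua", "mus") %in% names(table)))
  if (any(table$mua <= 0) || any(table$mus <= 0))
    stop("mua and mus must be positive")
  if (A_boundary < 1) stop("A_boundary must be >= 1")
  structure(list(table = table, A_boundary = A_boundary),
            class = "OpticalCoefficients")
}

# coefficient lookup for one wavelength; errors name the missing label
coeffsForWavelength <- function(coeffs, labels, wavelength) {
  tab <- coeffs$table[coeffs$table$wavelength == wavelength, ]
  if (nrow(tab) == 0)
    stop(sprintf("no optical coefficients for wavelength %s", wavelength))
  idx <- match(labels, tab$tissue)
  if (anyNA(idx)) {
    miss <- unique(labels[is.na(idx)])
    stop(sprintf("missing optical coefficients for tissue label(s) %s",
                 paste(miss, collapse = ", ")))
  }
  mua <- tab$mua[idx]
  mus <- tab$mus[idx]
  list(mua = mua, mus = mus, kappa = 1 / (3 * (mua + mus)))
}

# triangle areas, vectorised
triAreas <- function(nodes, faces) {
  a <- nodes[faces[, 1], , drop = FALSE]
  b <- nodes[faces[, 2], , drop = FALSE] - a
  c_ <- nodes[faces[, 3], , drop = FALSE] - a
  cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sqrt(rowSums(cr^2)) / 2
}

#' Assemble the finite-element diffusion system
#'
#' Galerkin discretisation on linear tetrahedra: volume terms
#' kappa grad(psi_i).grad(psi_j) + mua psi_i psi_j, plus the Robin boundary
#' mass 1/(2 A) psi_i psi_j over the surface.  The result is symmetric
#' positive definite.
#'
#' @param mesh a [HeadMesh-class].
#' @param coeffs an `OpticalCoefficients` object covering every tissue label
#'   present in the mesh.
#' @param wavelength wavelength (nm) selecting the coefficient row.
#' @return an `FEMSystem` list: sparse matrix `K`, the `mesh`, per-element
#'   optics, the wavelength, and a factorisation cache.
#' @export
assembleSystem <- function(mesh, coeffs, wavelength) {
  el <- mesh@elements
  nd <- mesh@nodes
  nn <- nrow(nd)
  ne <- nrow(el)
  opt <- coeffsForWavelength(coeffs, mesh@elementLabel, wavelength)
  vol <- tetVolumes(nd, el)

  # shape-function gradients: for D = [p2-p1; p3-p1; p4-p1] (rows), the
  # gradients of barycentric coords 2..4 are the rows of t(solve(D)); done
  # in closed form via the adjugate for all elements at once.
  p1 <- nd[el[, 1], , drop = FALSE]
  e1 <- nd[el[, 2], , drop = FALSE] - p1
  e2 <- nd[el[, 3], , drop = FALSE] - p1
  e3 <- nd[el[, 4], , drop = FALSE] - p1
  det6 <- 6 * vol  # det of [e1;e2;e3] rows = 6V (positively oriented)
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  g2 <- cross(e2, e3) / det6
  g3 <- cross(e3, e1) / det6
  g4 <- cross(e1, e2) / det6
  g1 <- -(g2 + g3 + g4)
  grads <- list(g1, g2, g3, g4)

  nTrip <- ne * 16L
  ii <- integer(nTrip); jj <- integer(nTrip); xx <- numeric(nTrip)
  k <- 0L
  for (a in 1:4) for (b in 1:4) {
    stiff <- opt$kappa * vol * rowSums(grads[[a]] * grads[[b]])
    mass <- opt$mua * vol * (if (a == b) 1 / 10 else 1 / 20)
    idx <- k + seq_len(ne)
    ii[idx] <- el[, a]; jj[idx] <- el[, b]; xx[idx] <- stiff + mass
    k <- k + ne
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nn, nn))

  faces <- mesh@boundaryFaces
  if (nrow(faces)) {
    ar <- triAreas(nd, faces)
    w <- 1 / (2 * coeffs$A_boundary)
    bi <- integer(0); bj <- integer(0); bx <- numeric(0)
    for (a in 1:3) for (b in 1:3) {
      bi <- c(bi, faces[, a]); bj <- c(bj, faces[, b])
      bx <- c(bx, w * ar * (if (a == b) 1 / 6 else 1 / 12))
    }
    K <- K + Matrix::sparseMatrix(i = bi, j = bj, x = bx, dims = c(nn, nn))
  }

  structure(list(K = K, mesh = mesh, optics = opt, coeffs = coeffs,
                 wavelength = wavelength, cache = new.env(parent = emptyenv())),
            class = "FEMSystem")
}

# barycentric coordinates of p in every element; returns the first element
# containing p (all coords >= -tol) or NA
findContainingElement <- function(mesh, p, tol = 1e-8) {
  el <- mesh@elements; nd <- mesh@nodes
  p1 <- nd[el[, 1], , drop = FALSE]
  e1 <- nd[el[, 2], , drop = FALSE] - p1
  e2 <- nd[el[, 3], , drop = FALSE] - p1
  e3 <- nd[el[, 4], , drop = FALSE] - p1
  rp <- matrix(p, nrow(el), 3, byrow = TRUE) - p1
  det6 <- 6 * tetVolumes(nd, el)
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  l2 <- rowSums(rp * cross(e2, e3)) / det6
  l3 <- rowSums(rp * cross(e3, e1)) / det6
  l4 <- rowSums(rp * cross(e1, e2)) / det6
  l1 <- 1 - l2 - l3 - l4
  ok <- which(l1 >= -tol & l2 >= -tol & l3 >= -tol & l4 >= -tol)
  if (!length(ok)) return(NULL)
  e <- ok[1]
  list(element = e, bary = c(l1[e], l2[e], l3[e], l4[e]))
}

# load vector for an isotropic point source buried one reduced scattering
# length below the boundary entry point
sourceLoadVector <- function(system, entry, power = 1) {
  mesh <- system$mesh
  surf <- projectToScalp(entry, mesh)
  if (sqrt(sum((entry - surf)^2)) > 10)
    stop("source position lies outside the mesh (more than 10 mm from the boundary)")
  ctr <- colMeans(mesh@nodes)
  dir <- ctr - surf
  # inward direction: toward the mesh centroid, projected on the face normal
  # is adequate for slab geometry; fall back to +z for degenerate cases
  if (sqrt(sum(dir^2)) < 1e-12) dir <- c(0, 0, 1)
  dir <- dir / sqrt(sum(dir^2))
  musFirst <- system$coeffs$table$mus[
    system$coeffs$table$tissue == 1 &
      system$coeffs$table$wavelength == system$wavelength]
  depth <- 1 / musFirst
  p <- surf + depth * dir
  hit <- findContainingElement(mesh, p)
  if (is.null(hit)) {
    hit <- findContainingElement(mesh, entry)
    if (is.null(hit)) stop("source position lies outside the mesh")
  }
  b <- numeric(nNodes(mesh))
  b[mesh@elements[hit$element, ]] <- power * hit$bary
  b
}

#' Solve the diffusion system for a point source
#'
#' Places an isotropic point source one reduced scattering length of the
#' outermost tissue below the boundary entry point (barycentric load on the
#' containing element) and solves the sparse SPD system via a cached
#' Cholesky factorisation.
#'
#' @param system an `FEMSystem` from [assembleSystem()].
#' @param source_position numeric(3), entry point on (or near) the boundary.
#' @param source_power source strength; nodal fluence scales linearly.
#' @return a `FluenceField` list: `values` (nodal fluence), `source`
#'   descriptor, and the load vector.
#' @export
solveFluence <- function(system, source_position, source_power = 1) {
  b <- sourceLoadVector(system, source_position, source_power)
  if (is.null(system$cache$chol))
    system$cache$chol <- Matrix::Cholesky(Matrix::forceSymmetric(system$K))
  phi <- as.numeric(Matrix::solve(system$cache$chol, b))
  res <- sqrt(sum((as.numeric(system$K %*% phi) - b)^2)) / max(sqrt(sum(b^2)), 1e-300)
  if (!all(is.finite(phi)) || res > 1e-8)
    stop(sprintf("fluence solve failed to converge (relative residual %.3g)", res))
  structure(list(values = phi, source = list(position = source_position,
                                             power = source_power),
                 load = b, mesh = system$mesh),
            class = "FluenceField")
}

#' Analytic semi-infinite medium fluence (extrapolated-boundary oracle)
#'
#' Closed-form CW fluence for a homogeneous semi-infinite medium: a real
#' isotropic source at depth z0 = 1/mus and a negative image source mirrored
#' about the extrapolated boundary at z = -zb, zb = 2 A kappa:
#' phi = (1/(4 pi kappa)) (exp(-mueff r1)/r1 - exp(-mueff r2)/r2) with
#' mueff = sqrt(mua/kappa).  Used as an independent oracle for the FEM
#' solver on a homogeneous slab.
#'
#' @param rho lateral distance from the source axis (mm); vectorised.
#' @param z depth below the physical boundary (mm); vectorised.
#' @param mua absorption coefficient (mm^-1).
#' @param mus reduced scattering coefficient (mm^-1).
#' @param A_boundary boundary mismatch term.
#' @return fluence values (per unit source power).
#' @export
analyticSemiInfiniteFluence <- function(rho, z, mua, mus, A_boundary = 2.82) {
  if (mua <= 0 || mus <= 0) stop("optical coefficients must be positive")
  kappa <- 1 / (3 * (mua + mus))
  mueff <- sqrt(mua / kappa)
  z0 <- 1 / mus
  zb <- 2 * A_boundary * kappa
  r1 <- sqrt(rho^2 + (z - z0)^2)
  r2 <- sqrt(rho^2 + (z + z0 + 2 * zb)^2)
  if (any(r1 == 0)) stop("evaluation at the source point (r1 = 0)")
  (exp(-mueff * r1) / r1 - exp(-mueff * r2) / r2) / (4 * pi * kappa)
}

# element-mass action (M_e phi)_i = V/20 (sum_j phi_j + phi_i), all elements
elementMassAction <- function(mesh, phi) {
  el <- mesh@elements
  vol <- tetVolumes(mesh@nodes, el)
  ph <- matrix(phi[el], nrow(el), 4)
  (rowSums(ph) + ph) * (vol / 20)
}

#' Channel sensitivity from forward and adjoint fluence fields
#'
#' The photon measurement density function: the absorption derivative of the
#' log-measurement.  For element e the exact Galerkin derivative is
#' phi_fwd' M_e phi_adj / I (M_e the element mass matrix, I the unperturbed
#' measurement); node entries distribute element contributions symmetrically
#' so that the row is invariant under source-detector exchange and sums to
#' the total.
#'
#' @param forward `FluenceField` of the physical source.
#' @param adjoint `FluenceField` of the detector (adjoint source).
#' @param measurement_amplitude unperturbed measurement I (> 0).
#' @param granularity "node" (default) or "element".
#' @return numeric sensitivity row over nodes (or elements).
#' @export
computeSensitivity <- function(forward, adjoint, measurement_amplitude,
                               granularity = c("node", "element")) {
  granularity <- match.arg(granularity)
  if (measurement_amplitude <= 0) stop("measurement_amplitude must be positive")
  mesh <- forward$mesh
  el <- mesh@elements
  phiF <- matrix(forward$values[el], nrow(el), 4)
  phiA <- matrix(adjoint$values[el], nrow(el), 4)
  mF <- elementMassAction(mesh, forward$values)
  mA <- elementMassAction(mesh, adjoint$values)
  shares <- (phiF * mA + phiA * mF) / (2 * measurement_amplitude)
  if (granularity == "element") return(rowSums(shares))
  as.numeric(rowsum(as.numeric(shares), as.integer(el), reorder = TRUE)[
    as.character(seq_len(nNodes(mesh))), 1])
}

#' Channel sensitivity matrix for an optode array
#'
#' One forward solve per source and one adjoint solve per detector and
#' wavelength; channel rows reuse the fields, so the solve count is
#' (#sources + #detectors) per wavelength rather than 2 x #channels.
#'
#' @param mesh a [HeadMesh-class].
#' @param array an [OptodeArray-class] whose optodes project onto the mesh
#'   boundary.
#' @param coeffs an `OpticalCoefficients` object.
#' @param wavelengths numeric wavelengths (nm) to compute.
#' @return a [SensitivityMatrix-class]; attribute `n_solves` records the
#'   number of linear solves per wavelength.
#' @export
channelSensitivityMatrix <- function(mesh, array, coeffs,
                                     wavelengths = c(770, 850)) {
  chn <- channelNames(array)
  S0 <- list()
  nsolv <- 0L
  for (w in wavelengths) {
    sys <- assembleSystem(mesh, coeffs, w)
    fwd <- lapply(seq_len(nrow(array@sources)), function(i)
      solveFluence(sys, as.numeric(array@sources[i, c("x", "y", "z")])))
    names(fwd) <- array@sources$id
    adj <- lapply(seq_len(nrow(array@detectors)), function(i)
      solveFluence(sys, as.numeric(array@detectors[i, c("x", "y", "z")])))
    names(adj) <- array@detectors$id
    nsolv <- nsolv + length(fwd) + length(adj)
    rows <- matrix(0, length(chn), nNodes(mesh))
    for (c in seq_along(chn)) {
      f <- fwd[[array@channels$source[c]]]
      a <- adj[[array@channels$detector[c]]]
      I <- sum(a$load * f$values)  # detector functional applied to forward field
      rows[c, ] <- computeSensitivity(f, a, I)
    }
    rownames(rows) <- chn
    S0[[as.character(w)]] <- rows
  }
  out <- new("SensitivityMatrix", S0 = S0, regionSensitivity = list(),
             channelNames = chn)
  attr(out, "n_solves") <- nsolv
  out
}

#' Nodes of a spherical region restricted to one tissue
#'
#' @param mesh a [HeadMesh-class].
#' @param centre numeric(3), sphere centre (mm).
#' @param radius sphere radius (mm); default 4.
#' @param tissue tissue label the nodes must belong to (via any adjacent
#'   element); default 3 (brain).
#' @return integer node indices.
#' @export
regionNodes <- function(mesh, centre, radius = 4, tissue = 3) {
  d2 <- rowSums((mesh@nodes - matrix(centre, nNodes(mesh), 3, byrow = TRUE))^2)
  inBall <- which(d2 <= radius^2)
  tissueNodes <- unique(as.integer(mesh@elements[mesh@elementLabel == tissue, ]))
  intersect(inBall, tissueNodes)
}

#' Condense node sensitivities onto named regions
#'
#' Sums the channel x node sensitivity entries over each region's node set,
#' per channel and wavelength, giving channel x region sensitivities for the
#' observation model.
#'
#' @param S a [SensitivityMatrix-class].
#' @param regions named list of integer node-index vectors.
#' @return the input with `regionSensitivity` filled (a named list per
#'   wavelength of channel x region matrices).
#' @export
regionSensitivity <- function(S, regions) {
  if (!length(regions) || is.null(names(regions)))
    stop("regions must be a non-empty named list of node sets")
  for (r in names(regions)) {
    if (!length(regions[[r]])) stop(sprintf("region '%s' is empty", r))
  }
  out <- lapply(S@S0, function(m) {
    cond <- sapply(regions, function(idx) rowSums(m[, idx, drop = FALSE]))
    cond <- matrix(cond, nrow = nrow(m),
                   dimnames = list(rownames(m), names(regions)))
    cond
  })
  S@regionSensitivity <- out
  S
}

#' Write sensitivity matrices as CSV tables
#'
#' One file per wavelength (`<prefix>_<wavelength>.csv`) with channels as
#' rows; a node index header row is implied by column order.
#'
#' @param S a [SensitivityMatrix-class].
#' @param prefix output path prefix.
#' @return written file paths, invisibly.
#' @export
writeSensitivityCSV <- function(S, prefix) {
  paths <- character(0)
  for (w in names(S@S0)) {
    p <- sprintf("%s_%s.csv", prefix, w)
    write.csv(data.frame(channel = S@channelNames, S@S0[[w]],
                         check.names = FALSE), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
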