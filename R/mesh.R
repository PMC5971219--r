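## Synthetic layered head geometry and the optode-array fixture.
##
## The mesh is a structured slab: a box split into cells, each cell into six
## tetrahedra sharing the cell's main diagonal (Kuhn triangulation), which
## makes neighbouring cells conforming.  The scalp face is z = 0 and depth
## increases with +z, so tissue layers are horizontal slabs.

# Signed volumes of tetrahedra, vectorised; positive for correct orientation.
tetVolumes <- function(nodes, elements) {
  a <- nodes[elements[, 1], , drop = FALSE]
  b <- nodes[elements[, 2], , drop = FALSE] - a
  c_ <- nodes[elements[, 3], , drop = FALSE] - a
  d <- nodes[elements[, 4], , drop = FALSE] - a
  cr <- cbind(
    c_[, 2] * d[, 3] - c_[, 3] * d[, 2],
    c_[, 3] * d[, 1] - c_[, 1] * d[, 3],
    c_[, 1] * d[, 2] - c_[, 2] * d[, 1]
  )
  rowSums(b * cr) / 6
}

# Faces on the domain boundary: element faces that occur exactly once.
extractBoundaryFaces <- function(elements) {
  faceIdx <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  faces <- do.call(rbind, lapply(1:4, function(k) elements[, faceIdx[k, ], drop = FALSE]))
  sorted <- t(apply(faces, 1, sort))
  key <- paste(sorted[, 1], sorted[, 2], sorted[, 3])
  once <- names(which(table(key) == 1L))
  faces[key %in% once, , drop = FALSE]
}

#' Build a layered slab head mesh
#'
#' Constructs a structured tetrahedral mesh of a rectangular slab and labels
#' elements by centroid depth into three tissue layers: scalp/skull and
#' extra-cerebral tissue (label 1, outermost), CSF (label 2) and brain
#' (label 3).  The scalp face is the plane z = 0; depth increases with +z.
#' Each grid cell is split into six tetrahedra with consistent diagonals so
#' the mesh is conforming.
#'
#' @param extent_xyz numeric(3), box dimensions in mm (x, y, depth).
#' @param layer_thicknesses numeric(3), layer depths in mm for tissues
#'   1, 2, 3; must sum to `extent_xyz[3]`.
#' @param target_edge_length numeric, requested grid spacing in mm; the
#'   actual spacing divides each extent evenly.
#' @param grid optional list with components `x`, `y`, `z`: explicit sorted
#'   node coordinate vectors per axis (spanning 0 to the extent), allowing
#'   non-uniform (graded) spacing, e.g. refinement under an optode.
#'   Overrides `target_edge_length`.
#' @return a [HeadMesh-class] object.
#' @examples
#' mesh <- buildLayeredSlabMesh(c(40, 40, 30), c(5, 2, 23), 10)
#' mesh
#' @export
buildLayeredSlabMesh <- function(extent_xyz, layer_thicknesses,
                                 target_edge_length, grid = NULL) {
  if (length(extent_xyz) != 3 || any(extent_xyz <= 0))
    stop("extent_xyz must be three positive lengths (mm)")
  if (length(layer_thicknesses) != 3 || any(layer_thicknesses <= 0))
    stop("layer_thicknesses must be three positive lengths (mm)")
  if (abs(sum(layer_thicknesses) - extent_xyz[3]) > 1e-9)
    stop("layer_thicknesses must sum to the z extent")
  if (is.null(grid)) {
    if (length(target_edge_length) != 1 || target_edge_length <= 0)
      stop("target_edge_length must be positive")
    ncell <- pmax(1L, as.integer(round(extent_xyz / target_edge_length)))
    xs <- seq(0, extent_xyz[1], length.out = ncell[1] + 1L)
    ys <- seq(0, extent_xyz[2], length.out = ncell[2] + 1L)
    zs <- seq(0, extent_xyz[3], length.out = ncell[3] + 1L)
  } else {
    xs <- sort(unique(grid$x)); ys <- sort(unique(grid$y))
    zs <- sort(unique(grid$z))
    for (v in list(xs, ys, zs)) if (length(v) < 2)
      stop("each grid axis needs at least 2 coordinates")
    ncell <- c(length(xs), length(ys), length(zs)) - 1L
  }
  nx <- ncell[1] + 1L; ny <- ncell[2] + 1L; nz <- ncell[3] + 1L
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dimnames(nodes) <- NULL
  nid <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * as.integer(nx * ny)

  # cell corners (0/1 offsets); six tets along the main diagonal 000 -> 111
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  cells <- expand.grid(i = seq_len(ncell[1]), j = seq_len(ncell[2]), k = seq_len(ncell[3]))
  ei <- diag(3)
  elems <- vector("list", 6)
  for (p in 1:6) {
    o1 <- ei[perms[p, 1], ]
    o2 <- o1 + ei[perms[p, 2], ]
    verts <- rbind(c(0, 0, 0), o1, o2, c(1, 1, 1))
    ids <- sapply(1:4, function(v)
      nid(cells$i + verts[v, 1], cells$j + verts[v, 2], cells$k + verts[v, 3]))
    elems[[p]] <- matrix(as.integer(ids), ncol = 4)
  }
  elements <- do.call(rbind, elems)
  # fix orientation: swap last two nodes where the signed volume is negative
  v <- tetVolumes(nodes, elements)
  neg <- v < 0
  if (any(neg)) elements[neg, c(3, 4)] <- elements[neg, c(4, 3)]

  centZ <- (nodes[elements[, 1], 3] + nodes[elements[, 2], 3] +
            nodes[elements[, 3], 3] + nodes[elements[, 4], 3]) / 4
  breaks <- cumsum(layer_thicknesses)
  label <- ifelse(centZ < breaks[1], 1L, ifelse(centZ < breaks[2], 2L, 3L))

  new("HeadMesh",
      nodes = nodes,
      elements = elements,
      elementLabel = as.integer(label),
      boundaryFaces = extractBoundaryFaces(elements))
}

#' Optode-array fixture: 4 sources, 4 detectors, 9 channels at 2 cm
#'
#' Returns the package's probe fixture emulating an infant temporal-lobe
#' array: four sources and four detectors on the scalp plane (z = 0) whose
#' pairings at exactly 20 mm separation define nine measurement channels.
#' Channels are enumerated detector-major so the list is independent of
#' optode insertion order.
#'
#' @return an [OptodeArray-class] with 9 channels at 20 mm separation.
#' @examples
#' arr <- buildFixtureArray()
#' nChannels(arr)
#' @export
buildFixtureArray <- function() {
  sources <- data.frame(
    id = paste0("S", 1:4),
    x = c(0, 40, 20, 20), y = c(0, 0, 20, -20), z = 0
  )
  detectors <- data.frame(
    id = paste0("D", 1:4),
    x = c(20, 0, 40, -20), y = c(0, 20, 20, 0), z = 0
  )
  sep <- 20
  chan <- list()
  for (d in seq_len(nrow(detectors))) {
    for (s in seq_len(nrow(sources))) {
      dist <- sqrt(sum((unlist(sources[s, c("x", "y", "z")]) -
                        unlist(detectors[d, c("x", "y", "z")]))^2))
      if (abs(dist - sep) < 1e-9)
        chan[[length(chan) + 1L]] <- data.frame(source = sources$id[s],
                                                detector = detectors$id[d])
    }
  }
  new("OptodeArray",
      sources = sources, detectors = detectors,
      channels = do.call(rbind, chan), nominalSeparation = sep)
}

optodePosition <- function(array, id) {
  s <- array@sources[array@sources$id == id, c("x", "y", "z")]
  if (nrow(s) == 1) return(as.numeric(s))
  d <- array@detectors[array@detectors$id == id, c("x", "y", "z")]
  if (nrow(d) == 1) return(as.numeric(d))
  stop(sprintf("unknown optode id '%s'", id))
}

#' Channel names of an optode array
#' @param array an OptodeArray
#' @return character, e.g. "S1-D1"
#' @export
channelNames <- function(array) {
  paste0(array@channels$source, "-", array@channels$detector)
}

#' Midpoint of a channel's source and detector
#'
#' The channel's fiducial centre: the arithmetic midpoint between its source
#' and detector positions.
#'
#' @param array an [OptodeArray-class].
#' @param channel channel index (row) or a "S#-D#" channel name.
#' @return numeric(3), position in mm.
#' @export
channelMidpoint <- function(array, channel) {
  if (is.character(channel)) {
    idx <- match(channel, channelNames(array))
    if (is.na(idx)) stop(sprintf("unknown channel '%s'", channel))
  } else {
    idx <- channel
    if (idx < 1 || idx > nrow(array@channels))
      stop(sprintf("unknown channel index %s", channel))
  }
  s <- optodePosition(array, array@channels$source[idx])
  d <- optodePosition(array, array@channels$detector[idx])
  (s + d) / 2
}

# Closest points on a set of triangles to a query point (Ericson's method),
# vectorised over triangles.  Returns the closest point per triangle.
closestPointOnTriangles <- function(p, A, B, C) {
  ab <- B - A; ac <- C - A
  ap <- matrix(p, nrow(A), 3, byrow = TRUE) - A
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- matrix(p, nrow(A), 3, byrow = TRUE) - B
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- matrix(p, nrow(A), 3, byrow = TRUE) - C
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  out <- matrix(NA_real_, nrow(A), 3)
  # vertex regions
  reg <- d1 <= 0 & d2 <= 0
  out[reg, ] <- A[reg, , drop = FALSE]
  reg2 <- d3 >= 0 & d4 <= d3 & is.na(out[, 1])
  out[reg2, ] <- B[reg2, , drop = FALSE]
  reg3 <- d6 >= 0 & d5 <= d6 & is.na(out[, 1])
  out[reg3, ] <- C[reg3, , drop = FALSE]
  # edge AB
  regAB <- vc <= 0 & d1 >= 0 & d3 <= 0 & is.na(out[, 1])
  if (any(regAB)) {
    t <- d1[regAB] / (d1[regAB] - d3[regAB])
    out[regAB, ] <- A[regAB, , drop = FALSE] + t * ab[regAB, , drop = FALSE]
  }
  # edge AC
  regAC <- vb <= 0 & d2 >= 0 & d6 <= 0 & is.na(out[, 1])
  if (any(regAC)) {
    t <- d2[regAC] / (d2[regAC] - d6[regAC])
    out[regAC, ] <- A[regAC, , drop = FALSE] + t * ac[regAC, , drop = FALSE]
  }
  # edge BC
  regBC <- va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0 & is.na(out[, 1])
  if (any(regBC)) {
    t <- (d4[regBC] - d3[regBC]) / ((d4[regBC] - d3[regBC]) + (d5[regBC] - d6[regBC]))
    out[regBC, ] <- B[regBC, , drop = FALSE] +
      t * (C[regBC, , drop = FALSE] - B[regBC, , drop = FALSE])
  }
  # interior
  inner <- is.na(out[, 1])
  if (any(inner)) {
    denom <- va[inner] + vb[inner] + vc[inner]
    v <- vb[inner] / denom; w <- vc[inner] / denom
    out[inner, ] <- A[inner, , drop = FALSE] + v * ab[inner, , drop = FALSE] +
      w * ac[inner, , drop = FALSE]
  }
  out
}

#' Project a point onto the mesh boundary (scalp surface)
#'
#' Returns the closest point on the boundary surface to `point`, by exact
#' point-to-triangle projection minimised over all boundary faces.  Ties are
#' broken by the lowest face index, so the result is deterministic.
#'
#' @param point numeric(3), position in mm.
#' @param mesh a [HeadMesh-class] with boundary faces.
#' @return numeric(3), a point on some boundary face.
#' @export
projectToScalp <- function(point, mesh) {
  faces <- mesh@boundaryFaces
  if (nrow(faces) == 0) stop("mesh has no boundary faces")
  cand <- closestPointOnTriangles(point,
                                  mesh@nodes[faces[, 1], , drop = FALSE],
                                  mesh@nodes[faces[, 2], , drop = FALSE],
                                  mesh@nodes[faces[, 3], , drop = FALSE])
  d2 <- rowSums((cand - matrix(point, nrow(cand), 3, byrow = TRUE))^2)
  cand[which.min(d2), ]
}

## ---- ASCII mesh and table I/O ------------------------------------------

#' Write a head mesh in plain ASCII node/element format
#'
#' Format: a header line "<nNodes> <nElements>", one node per line
#' ("id x y z"), then one element per line ("id n1 n2 n3 n4 label").
#'
#' @param mesh a [HeadMesh-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeHeadMesh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nNodes(mesh), nElements(mesh)), con)
  nd <- cbind(seq_len(nNodes(mesh)), mesh@nodes)
  writeLines(sprintf("%d %.10g %.10g %.10g", nd[, 1], nd[, 2], nd[, 3], nd[, 4]), con)
  el <- cbind(seq_len(nElements(mesh)), mesh@elements, mesh@elementLabel)
  writeLines(sprintf("%d %d %d %d %d %d", el[, 1], el[, 2], el[, 3], el[, 4],
                     el[, 5], el[, 6]), con)
  invisible(path)
}

#' Read a head mesh written by [writeHeadMesh()]
#' @param path input file path.
#' @return a [HeadMesh-class].
#' @export
readHeadMesh <- function(path) {
  lines <- readLines(path)
  hd <- as.integer(strsplit(lines[1], "\\s+")[[1]])
  nn <- hd[1]; ne <- hd[2]
  nd <- read.table(text = lines[2:(1 + nn)])
  el <- read.table(text = lines[(2 + nn):(1 + nn + ne)])
  elements <- unname(as.matrix(el[, 2:5]))
  storage.mode(elements) <- "integer"
  new("HeadMesh",
      nodes = unname(as.matrix(nd[, 2:4])),
      elements = elements,
      elementLabel = as.integer(el[, 6]),
      boundaryFaces = extractBoundaryFaces(elements))
}

#' Export a head mesh to Gmsh 2.2 ASCII interchange format
#'
#' Writes nodes and 4-node tetrahedra (Gmsh element type 4) with the tissue
#' label as the physical tag, readable by standard mesh tooling.
#'
#' @param mesh a [HeadMesh-class].
#' @param path output `.msh` file path.
#' @return `path`, invisibly.
#' @export
writeMeshGmsh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nNodes(mesh))), con)
  writeLines(sprintf("%d %.10g %.10g %.10g", seq_len(nNodes(mesh)),
                     mesh@nodes[, 1], mesh@nodes[, 2], mesh@nodes[, 3]), con)
  writeLines(c("$EndNodes", "$Elements", as.character(nElements(mesh))), con)
  writeLines(sprintf("%d 4 2 %d %d %d %d %d %d", seq_len(nElements(mesh)),
                     mesh@elementLabel, mesh@elementLabel,
                     mesh@elements[, 1], mesh@elements[, 2],
                     mesh@elements[, 3], mesh@elements[, 4]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Write an optode array as CSV tables
#'
#' One CSV with columns kind (source/detector), id, x, y, z and an attached
#' channel table (source, detector) appended as rows with kind "channel".
#'
#' @param array an [OptodeArray-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeOptodeArray <- function(array, path) {
  opt <- rbind(
    data.frame(kind = "source", array@sources),
    data.frame(kind = "detector", array@detectors)
  )
  ch <- data.frame(kind = "channel", id = channelNames(array),
                   x = NA_real_, y = NA_real_, z = NA_real_)
  df <- rbind(opt, ch)
  df$separation <- array@nominalSeparation
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an optode array written by [writeOptodeArray()]
#' @param path input CSV path.
#' @return an [OptodeArray-class].
#' @export
readOptodeArray <- function(path) {
  df <- read.csv(path)
  src <- df[df$kind == "source", c("id", "x", "y", "z")]
  det <- df[df$kind == "detector", c("id", "x", "y", "z")]
  ch <- do.call(rbind, strsplit(df$id[df$kind == "channel"], "-"))
  new("OptodeArray", sources = src, detectors = det,
      channels = data.frame(source = ch[, 1], detector = ch[, 2]),
      nominalSeparation = df$separation[1])
}
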