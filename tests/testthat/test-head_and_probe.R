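test_that("slab mesh partitions the box and labels layers by depth", {
  mesh <- smallMesh(10)
  vols <- fnirsDCM:::tetVolumes(mesh@nodes, mesh@elements)
  expect_true(all(vols > 0))
  expect_equal(sum(vols), 40 * 40 * 30, tolerance = 1e-6)
  # all element centroids shallower than 5 mm are scalp/skull (label 1)
  ctr <- (mesh@nodes[mesh@elements[, 1], 3] + mesh@nodes[mesh@elements[, 2], 3] +
          mesh@nodes[mesh@elements[, 3], 3] + mesh@nodes[mesh@elements[, 4], 3]) / 4
  expect_true(all(mesh@elementLabel[ctr < 5] == 1L))
  expect_true(all(mesh@elementLabel[ctr > 7] == 3L))
  expect_true(all(mesh@elementLabel %in% 1:3))
})

test_that("node count grows as the edge length shrinks, per grid arithmetic", {
  # expected counts derived from the grid: (round(extent/edge)+1) per axis
  expectNodes <- function(edge)
    prod(round(c(40, 40, 30) / edge) + 1)
  m10 <- smallMesh(10)
  m5 <- smallMesh(5)
  expect_identical(nNodes(m10), as.integer(expectNodes(10)))
  expect_identical(nNodes(m5), as.integer(expectNodes(5)))
  expect_gt(nNodes(m5), nNodes(m10))
})

test_that("boundary faces form a closed surface", {
  mesh <- smallMesh(10)
  faces <- mesh@boundaryFaces
  edges <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(1, 3)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  expect_true(all(table(key) == 2L))
})

test_that("invalid mesh arguments are rejected with a named message", {
  expect_error(buildLayeredSlabMesh(c(-1, 40, 30), c(5, 2, 23), 10),
               "extent_xyz")
  expect_error(buildLayeredSlabMesh(c(40, 40, 30), c(5, 2, 20), 10),
               "sum to the z extent")
  expect_error(buildLayeredSlabMesh(c(40, 40, 30), c(5, 2, 23), 0),
               "target_edge_length")
})

test_that("fixture array has 9 channels of 4+4 optodes at exactly 2 cm", {
  arr <- buildFixtureArray()
  expect_identical(nrow(arr@sources), 4L)
  expect_identical(nrow(arr@detectors), 4L)
  expect_identical(nChannels(arr), 9L)
  seps <- vapply(seq_len(9), function(i) {
    s <- fnirsDCM:::optodePosition(arr, arr@channels$source[i])
    d <- fnirsDCM:::optodePosition(arr, arr@channels$detector[i])
    sqrt(sum((s - d)^2))
  }, numeric(1))
  expect_equal(seps, rep(20, 9), tolerance = 1e-12)
  # distant pairs are not channels
  expect_false(any(arr@channels$source == "S2" & arr@channels$detector == "D4"))
})

test_that("channel midpoints are arithmetic midpoints, equidistant from ends", {
  arr <- buildFixtureArray()
  expect_equal(channelMidpoint(arr, "S1-D1"), c(10, 0, 0))
  expect_equal(channelMidpoint(arr, "S3-D1"), c(20, 10, 0))
  for (i in seq_len(9)) {
    mp <- channelMidpoint(arr, i)
    s <- fnirsDCM:::optodePosition(arr, arr@channels$source[i])
    d <- fnirsDCM:::optodePosition(arr, arr@channels$detector[i])
    expect_equal(sqrt(sum((mp - s)^2)), sqrt(sum((mp - d)^2)), tolerance = 1e-12)
  }
  expect_error(channelMidpoint(arr, "S9-D9"), "S9-D9")
})

test_that("scalp projection is exact on flat faces and idempotent", {
  mesh <- smallMesh(10)
  onFace <- c(10, 10, 0)
  expect_equal(projectToScalp(onFace, mesh), onFace)
  above <- c(15, 25, -3)
  expect_equal(projectToScalp(above, mesh), c(15, 25, 0))
  # interior points project onto some boundary face (brute-force check)
  set.seed(11)
  for (rep in 1:10) {
    p <- c(runif(1, 0, 40), runif(1, 0, 40), runif(1, 0, 30))
    pr <- projectToScalp(p, mesh)
    dToFaces <- apply(mesh@boundaryFaces, 1, function(f) {
      cp <- fnirsDCM:::closestPointOnTriangles(
        pr, mesh@nodes[f[1], , drop = FALSE], mesh@nodes[f[2], , drop = FALSE],
        mesh@nodes[f[3], , drop = FALSE])
      sqrt(sum((cp - pr)^2))
    })
    expect_lt(min(dToFaces), 1e-9)
    # idempotence and boundedness by boundary nodes
    expect_equal(projectToScalp(pr, mesh), pr, tolerance = 1e-9)
    bn <- unique(as.integer(mesh@boundaryFaces))
    dNodes <- sqrt(rowSums(sweep(mesh@nodes[bn, , drop = FALSE], 2, p)^2))
    expect_lte(sqrt(sum((pr - p)^2)), min(dNodes) + 1e-9)
  }
})

test_that("channel list is invariant to optode insertion order", {
  arr <- buildFixtureArray()
  shuffled <- arr
  perm <- c(3, 1, 4, 2)
  shuffled@sources <- arr@sources[perm, ]
  shuffled@detectors <- arr@detectors[perm, ]
  # re-derive channels with the builder's enumeration rule
  chan <- list()
  for (d in seq_len(4)) for (s in seq_len(4)) {
    dist <- sqrt(sum((unlist(shuffled@sources[s, c("x", "y", "z")]) -
                      unlist(shuffled@detectors[d, c("x", "y", "z")]))^2))
    if (abs(dist - 20) < 1e-9)
      chan[[length(chan) + 1]] <- paste0(shuffled@sources$id[s], "-",
                                         shuffled@detectors$id[d])
  }
  expect_setequal(unlist(chan), channelNames(arr))
})

test_that("mesh and array round-trip through their plain-text formats", {
  mesh <- smallMesh(10)
  tf <- tempfile(fileext = ".txt")
  writeHeadMesh(mesh, tf)
  back <- readHeadMesh(tf)
  expect_equal(back@nodes, mesh@nodes)
  expect_identical(back@elements, mesh@elements)
  expect_identical(back@elementLabel, mesh@elementLabel)
  tg <- tempfile(fileext = ".msh")
  writeMeshGmsh(mesh, tg)
  expect_true(any(grepl("^\\$MeshFormat", readLines(tg))))

  arr <- buildFixtureArray()
  ta <- tempfile(fileext = ".csv")
  writeOptodeArray(arr, ta)
  arr2 <- readOptodeArray(ta)
  expect_equal(channelNames(arr2), channelNames(arr))
  expect_equal(arr2@nominalSeparation, 20)
})
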