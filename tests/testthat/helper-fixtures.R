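# Shared fixtures, built in code.

# small default slab used across geometry tests
smallMesh <- function(edge = 10)
  buildLayeredSlabMesh(c(40, 40, 30), c(5, 2, 23), edge)

# homogeneous optics for oracle comparisons
homogeneousOptics <- function(mua = 0.01, mus = 1.0, A = 2.82)
  opticalCoefficients(data.frame(tissue = 1:3, wavelength = 770,
                                 mua = mua, mus = mus), A_boundary = A)

# a tiny 3-region DCM with known values (model-8 structure)
tinyTruth <- function() defaultGroundTruth()

# cached probe/head fixture with region sensitivities (expensive-ish; reuse)
fixtureCache <- new.env(parent = emptyenv())
getFixture <- function() {
  if (is.null(fixtureCache$fx)) fixtureCache$fx <- fixtureObservationModel()
  fixtureCache$fx
}
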