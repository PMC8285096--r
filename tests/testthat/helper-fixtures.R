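# Shared fixtures, computed once per test run and cached, since the
# fine-grid sphere solve is the expensive part of the suite.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- maker()
  .fixtures[[name]]
}

spherePhantom <- function(res, noiseSD = 0, seed = 1L) {
  fixture(sprintf("sphere_%g_%g_%d", res, noiseSD, seed), function() {
    shellPhantom("concentric", rInner = 10, rOuter = 12,
                 spacing = rep(res, 3), noiseSD = noiseSD, seed = seed)
  })
}

# solved field on the ground-truth mask (segmentation tested separately)
sphereField <- function(res) {
  fixture(sprintf("field_%g", res), function() {
    solveLaplace(spherePhantom(res)$mask)
  })
}

sphereThickness <- function(res, step = NULL) {
  fixture(sprintf("thick_%g_%s", res, deparse(step)), function() {
    thicknessMap(sphereField(res), step = step)
  })
}

slabPhantom <- function(res = 0.5, gap = 3) {
  fixture(sprintf("slab_%g_%g", res, gap), function() {
    shellPhantom("slab", slabGap = gap, spacing = rep(res, 3))
  })
}

slabField <- function(res = 0.5, gap = 3) {
  fixture(sprintf("slabfield_%g_%g", res, gap), function() {
    solveLaplace(slabPhantom(res, gap)$mask)
  })
}

# radius of each wall voxel of a concentric phantom, mm
wallRadii <- function(mask) {
  lab <- wallLabels(mask)
  sp <- voxelSpacing(mask)
  d <- dim(lab)
  ctr <- (d - 1) / 2 * sp
  w <- which(lab == 2L, arr.ind = TRUE)
  list(idx = w,
       r = sqrt(((w[, 1] - 1) * sp[1] - ctr[1])^2 +
                ((w[, 2] - 1) * sp[2] - ctr[2])^2 +
                ((w[, 3] - 1) * sp[3] - ctr[3])^2))
}

# eight-feature matrix with a linearly separable label, for protocol tests
separableData <- function(n, seed = 42) {
  set.seed(seed)
  x <- matrix(rnorm(n * 8), n, 8)
  colnames(x) <- c("non_paroxysmal_af", "age", "hypertension", "diabetes",
                   "vascular_disease", "heart_failure", "lvef", "e_em")
  list(x = x, y = as.integer(x[, 2] + x[, 7] > 0))
}
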