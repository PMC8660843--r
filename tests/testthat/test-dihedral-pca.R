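test_that("circular embedding maps angles to (cos, sin) and is invertible", {
  ang <- matrix(c(0, pi, pi / 3, -2.5), 2, 2)
  feats <- new("DihedralFeatures", angles = ang,
               labels = data.frame(resno = 1:2, dihedral = c("phi", "psi")))
  emb <- circularEmbed(feats)
  expect_equal(emb[1, 1:2], c(cos.phi1 = 1, sin.phi1 = 0))
  expect_equal(emb[2, 1:2], c(cos.phi1 = -1, sin.phi1 = 0))
  dec <- circularDecode(emb)
  expect_equal(unname(dec), unname(ang), tolerance = 1e-12)
})

test_that("PCA degenerates correctly on constant and collinear data", {
  X <- matrix(rep(c(1, 2, 3, 4), each = 5), 5)
  m <- fitDihedralPCA(X)
  expect_equal(m@eigenvalues, rep(0, 4), tolerance = 1e-12)

  set.seed(6)
  t <- rnorm(30)
  dir <- c(1, -2, 0.5); dir <- dir / sqrt(sum(dir^2))
  L <- outer(t, dir) + matrix(5, 30, 3)
  mL <- fitDihedralPCA(L)
  expect_gt(mL@eigenvalues[1], 1e-6)
  expect_equal(mL@eigenvalues[2:3], c(0, 0), tolerance = 1e-10)
})

test_that("projection reproduces the eigenvalue-variance identity", {
  set.seed(7)
  X <- matrix(rnorm(200 * 6), 200)
  m <- fitDihedralPCA(X)
  sc <- projectFrames(m, X, nComponents = 6)
  v <- apply(sc, 2, function(x) mean((x - mean(x))^2))
  expect_equal(unname(v), m@eigenvalues, tolerance = 1e-6)
  # the model mean projects to the origin
  expect_equal(unname(projectFrames(m, m@center, 6)[1, ]), rep(0, 6),
               tolerance = 1e-10)
  # full reconstruction of the centred data
  Xc <- sweep(X, 2, m@center)
  expect_equal(sc %*% m@components, Xc, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("frames built along one component score only on that component", {
  set.seed(9)
  X <- matrix(rnorm(100 * 5), 100)
  X[, 1] <- X[, 1] * 4    # dominant direction
  m <- fitDihedralPCA(X)
  two <- rbind(m@center + 0.5 * m@components[1, ],
               m@center + 2.0 * m@components[1, ])
  sc <- projectFrames(m, two, nComponents = 5)
  expect_equal(unname(sc[, 1]), c(0.5, 2.0), tolerance = 1e-8)
  expect_lt(max(abs(sc[, 2:5])), 1e-8)
})

test_that("planted two-basin data concentrates variance on PC1", {
  g <- twoBasinFixture(nFrames = 150, seed = 11, concentration = 30)
  f <- computeDihedrals(g$ensemble, proteinDihedralSpec(g$ensemble))
  m <- fitDihedralPCA(circularEmbed(f))
  expect_gt(m@eigenvalues[1] / m@eigenvalues[2], 5)
})

test_that("component signs follow the largest-loading-positive convention", {
  set.seed(10)
  X <- matrix(rnorm(50 * 4), 50)
  m <- fitDihedralPCA(X)
  for (i in seq_len(nrow(m@components)))
    expect_gt(m@components[i, which.max(abs(m@components[i, ]))], 0)
})

test_that("free-energy surfaces follow the Boltzmann-inversion definition", {
  # two occupied bins with weight ratio 1:e give a gap of exactly 1 kT
  x <- c(rep(0.25, 100), rep(0.75, 368))
  y <- rep(0.5, length(x))
  fes <- freeEnergySurface(x, y, bins = c(2, 1), xlim = c(0, 1),
                           ylim = c(0, 1))
  expect_equal(fes@surface[2, 1], 0)
  expect_equal(fes@surface[1, 1], log(3.68), tolerance = 1e-12)

  # scaling all weights leaves F unchanged
  w <- runif(length(x)) + 0.5
  f1 <- freeEnergySurface(x, y, weights = w, bins = c(2, 1),
                          xlim = c(0, 1), ylim = c(0, 1))
  f2 <- freeEnergySurface(x, y, weights = 17 * w, bins = c(2, 1),
                          xlim = c(0, 1), ylim = c(0, 1))
  expect_equal(f1@surface, f2@surface, tolerance = 1e-12)

  # uniform sampling is flat within the counting-noise bound
  set.seed(12)
  n <- 40000; nb <- 5
  fu <- freeEnergySurface(runif(n), runif(n), bins = nb,
                          xlim = c(0, 1), ylim = c(0, 1))
  bound <- 3 / sqrt(n / nb^2)
  expect_lt(max(abs(fu@surface[is.finite(fu@surface)])), 2 * bound + 0.1)
  expect_error(freeEnergySurface(1:3, 1:3, weights = c(0, 0, 0)), "zero")
})

test_that("RMSF is zero for identical or rigidly rotated frames", {
  set.seed(13)
  base <- matrix(rnorm(30), 10)
  top <- makeTopology(10, resno = rep(1:5, each = 2))
  same <- ensembleFromFrames(list(base, base, base), top)
  expect_equal(residueFluctuations(same)$rmsf, rep(0, 5), tolerance = 1e-10)

  rot <- ensembleFromFrames(lapply(1:4, function(s) rigidMotion(base, s)), top)
  expect_lt(max(residueFluctuations(rot)$rmsf), 1e-8)
})

test_that("RMSF of an isotropically jittered residue is sigma * sqrt(3)", {
  set.seed(14)
  nres <- 15
  base <- matrix(rnorm(6 * nres, sd = 8), 2 * nres)
  sigma <- 0.5
  frames <- lapply(1:2000, function(f) {
    x <- base
    x[29:30, ] <- x[29:30, ] + matrix(rnorm(6, sd = sigma), 2)
    x
  })
  top <- makeTopology(2 * nres, resno = rep(seq_len(nres), each = 2))
  ens <- ensembleFromFrames(frames, top)
  r <- residueFluctuations(ens)
  expect_equal(r$rmsf[nres], sigma * sqrt(3), tolerance = 0.1)
  expect_lt(max(r$rmsf[seq_len(nres - 1)]), 0.15)
})

test_that("RMSF agrees with an independent superposition (bio3d)", {
  spec <- ensembleSpec(nFrames = 30, nResidues = 15, clusterWeights = 1,
                       seed = 15, noiseLevel = 0.03)
  g <- generateEnsemble(spec)
  ours <- residueFluctuations(g$ensemble)
  nfr <- nFrames(g$ensemble)
  xyz <- t(vapply(seq_len(nfr),
                  function(f) as.numeric(t(frameCoords(g$ensemble, f))),
                  numeric(3 * nAtoms(g$ensemble))))
  fitted <- bio3d::fit.xyz(xyz[1, ], xyz, 1:ncol(xyz), 1:ncol(xyz))
  perAtom <- bio3d::rmsf(fitted)
  resno <- topology(g$ensemble)$resno
  theirs <- sqrt(tapply(perAtom^2, resno, mean))
  expect_equal(unname(ours$rmsf), unname(as.numeric(theirs)),
               tolerance = 0.05)
})

test_that("dihedral computation rejects out-of-range atoms and flags NA", {
  g <- twoBasinFixture(nFrames = 2, seed = 16)
  spec <- proteinDihedralSpec(g$ensemble)
  bad <- spec; bad$l[1] <- 10000L
  expect_error(computeDihedrals(g$ensemble, bad), "outside")
})
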