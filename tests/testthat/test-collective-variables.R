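test_that("P1 reproduces canonical node torsions", {
  # single-atom nodes at the planar-anti quadruple -> 180 degrees
  xyz <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  top <- makeTopology(4, resno = 1:4, elety = rep("CA", 4))
  ens <- ensembleFromFrames(list(xyz), top)
  spec <- helixNodeSpec(atomSelection(resno = 1), atomSelection(resno = 2),
                        atomSelection(resno = 3), atomSelection(resno = 4))
  expect_equal(computeP1(ens, spec), 180)
})

test_that("P1 of multi-atom node centres reproduces the +/-90 quadruple", {
  # each node is 3 atoms whose centre of geometry sits on the target points
  target <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 0, 1))
  off <- rbind(c(0.3, 0, 0), c(-0.3, 0, 0), c(0, 0, 0))
  frames <- do.call(rbind, lapply(1:4, function(i)
    sweep(off, 2, target[i, ], "+")))
  top <- makeTopology(12, resno = rep(1:4, each = 3), elety = rep("CA", 12))
  ens <- ensembleFromFrames(list(frames), top)
  spec <- helixNodeSpec(atomSelection(resno = 1), atomSelection(resno = 2),
                        atomSelection(resno = 3), atomSelection(resno = 4))
  expect_equal(computeP1(ens, spec), 90, tolerance = 1e-10)
  # mirrored fourth node gives the negative torsion
  frames2 <- frames
  frames2[10:12, 3] <- -frames2[10:12, 3]
  ens2 <- ensembleFromFrames(list(frames2), top)
  expect_equal(computeP1(ens2, spec), -90, tolerance = 1e-10)
})

test_that("P1 is invariant under rigid-body motion of the frame", {
  g <- twoBasinFixture(nFrames = 3, seed = 31)
  ens <- g$ensemble
  spec <- helixNodeSpec(atomSelection(resno = 1:3, elety = "CA"),
                        atomSelection(resno = 6:8, elety = "CA"),
                        atomSelection(resno = 13:15, elety = "CA"),
                        atomSelection(resno = 18:20, elety = "CA"))
  p0 <- computeP1(ens, spec)
  moved <- ensembleFromFrames(
    lapply(seq_len(nFrames(ens)),
           function(f) rigidMotion(frameCoords(ens, f), seed = f)),
    topology(ens))
  expect_lt(max(abs(computeP1(moved, spec) - p0)), 1e-8)
})

test_that("overlapping node selections are rejected", {
  g <- twoBasinFixture(nFrames = 1, seed = 32)
  spec <- helixNodeSpec(atomSelection(resno = 1:3, elety = "CA"),
                        atomSelection(resno = 3:5, elety = "CA"),
                        atomSelection(resno = 13:15, elety = "CA"),
                        atomSelection(resno = 18:20, elety = "CA"))
  expect_error(computeP1(g$ensemble, spec), "disjoint")
})

test_that("conjugated-chain dihedrals are computed along the declared order", {
  # all-trans toy chain: every torsion exactly 180
  ens <- generateConjugatedChainSeries(3, 0, seed = 33, concentration = Inf)
  cd <- computeCarDihedrals(ens, paste0("C", 1:8))
  expect_equal(dim(cd$angles), c(3L, 5L))
  expect_true(all(abs(abs(cd$angles) - 180) < 1e-9))

  # explicit 35-degree first torsion, built by internal-coordinate placement
  xyz <- matrix(NA_real_, 5, 3)
  xyz[1, ] <- c(0, 0, 0); xyz[2, ] <- c(1.45, 0, 0)
  xyz[3, ] <- xyz[2, ] + 1.45 * c(-cos(2 * pi / 3 / 2), sin(2 * pi / 3 / 2), 0)
  xyz[4, ] <- quenchscape:::placeAtom(xyz[1, ], xyz[2, ], xyz[3, ],
                                      1.45, 2 * pi / 3, 35 * pi / 180)
  xyz[5, ] <- quenchscape:::placeAtom(xyz[2, ], xyz[3, ], xyz[4, ],
                                      1.45, 2 * pi / 3, pi)
  top <- makeTopology(5, resno = 1L, elety = paste0("C", 1:5))
  ens1 <- ensembleFromFrames(list(xyz), top)
  cd1 <- computeCarDihedrals(ens1, paste0("C", 1:5))
  expect_equal(unname(cd1$angles[1, "d1"]), 35, tolerance = 1e-6)

  # reversed atom order: torsion sequence reversed, values preserved
  cdRev <- computeCarDihedrals(ens1, paste0("C", 5:1))
  expect_equal(unname(cdRev$angles[1, ]), unname(rev(cd1$angles[1, ])),
               tolerance = 1e-9)
  expect_error(computeCarDihedrals(ens1, c("C1", "C2", "C3", "C9")),
               "not found")
})

test_that("conformer classification uses the 90-degree boundary", {
  expect_equal(classifyConformer(10), "s-cis")
  expect_equal(classifyConformer(178), "s-trans")
  expect_equal(classifyConformer(-90), "s-trans")
  expect_equal(classifyConformer(90), "s-trans")
  expect_equal(classifyConformer(89.9), "s-cis")
  expect_equal(classifyConformer(-350), "s-cis")   # wraps to +10
  expect_true(is.na(classifyConformer(NA_real_)))
})

test_that("planted conformer fractions are recovered by classification", {
  n <- 2000; f0 <- 0.3
  ens <- generateConjugatedChainSeries(n, f0, seed = 34)
  cd <- computeCarDihedrals(ens, paste0("C", 1:8))
  frac <- mean(cd$conformer[, 1] == "s-cis")
  se <- sqrt(f0 * (1 - f0) / n)
  expect_lt(abs(frac - f0), 3 * se)
  # classification matches the generator's own record exactly
  expect_identical(unname(cd$conformer[, 1]),
                   ensembleMetadata(ens)$conformer)
})

test_that("box-plot summaries follow the quartile and whisker rules", {
  s <- distributionSummary(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3); expect_equal(s$q1, 2); expect_equal(s$q3, 4)
  expect_equal(s$whiskerLow, 1); expect_equal(s$whiskerHigh, 5)
  expect_equal(s$nOutliers, 0L)

  sc <- distributionSummary(rep(7, 10))
  expect_equal(sc$q3 - sc$q1, 0)
  expect_equal(sc$whiskerLow, 7); expect_equal(sc$whiskerHigh, 7)

  # outliers land beyond the 1.5 IQR whisker
  so <- distributionSummary(c(1, 2, 3, 4, 5, 100))
  expect_equal(so$nOutliers, 1L)
  expect_equal(attr(so, "outliers")[[1]], 100)

  set.seed(35)
  sn <- distributionSummary(rnorm(1000))
  expect_lt(abs(sn$median), 0.1)
  expect_equal(sn$q3 - sn$q1, 1.349, tolerance = 0.1)

  # circular option: a distribution straddling +/-180 is not torn apart
  ang <- c(rnorm(500, 178, 3), rnorm(500, -178, 3))
  ang <- quenchscape:::wrapAngle(ang * pi / 180) * 180 / pi
  scirc <- distributionSummary(ang, circular = TRUE)
  expect_gt(abs(scirc$median), 170)
  expect_lt(scirc$q3 - scirc$q1, 10)

  expect_error(distributionSummary(numeric(0)), "no values")
  g <- distributionSummary(c(1:5, 101:105), rep(c("a", "b"), each = 5))
  expect_equal(g$median, c(3, 103))
})
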