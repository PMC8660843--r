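# naive double-loop oracle for the transition-charge Coulomb sum
naiveCoulomb <- function(cA, qA, cB, qB) {
  v <- 0
  for (i in seq_len(nrow(cA))) {
    for (j in seq_len(nrow(cB))) {
      v <- v + qA[i] * qB[j] / sqrt(sum((cA[i, ] - cB[j, ])^2))
    }
  }
  physicalConstants$coulombCm1 * v
}

randomPigment <- function(n, spread = 6) {
  list(coords = matrix(runif(3 * n, -spread, spread), n),
       charges = rnorm(n, sd = 0.1))
}

test_that("the vectorized Coulomb sum equals the double-loop oracle", {
  set.seed(40)
  for (rep in 1:25) {
    A <- randomPigment(50)
    B <- randomPigment(50)
    B$coords[, 1] <- B$coords[, 1] + 20   # keep the sets disjoint
    v <- coulombCoupling(A$coords, A$charges, B$coords, B$charges)
    v0 <- naiveCoulomb(A$coords, A$charges, B$coords, B$charges)
    expect_lt(abs(v - v0) / abs(v0), 1e-12)
  }
})

test_that("the conversion constant matches an independent CODATA assembly", {
  # direct route: e^2 / (4 pi eps0 * 1 Angstrom) expressed in cm^-1
  pc <- physicalConstants
  Kdirect <- pc$e^2 / (4 * pi * pc$eps0 * 1e-10) / (pc$h * pc$c * 100)
  expect_lt(abs(pc$coulombCm1 - Kdirect) / Kdirect, 1e-10)
  # frozen pre-build oracle value
  expect_lt(abs(pc$coulombCm1 - oracleK) / oracleK, 1e-10)
  v <- coulombCoupling(matrix(0, 1, 3), 0.1, matrix(c(4, 0, 0), 1, 3), -0.2)
  expect_lt(abs(v - oracleCouplingSpot) / abs(oracleCouplingSpot), 1e-10)
})

test_that("Coulomb coupling is linear, symmetric and guards r = 0", {
  set.seed(41)
  A <- randomPigment(10); B <- randomPigment(10)
  B$coords[, 3] <- B$coords[, 3] + 15
  v <- coulombCoupling(A$coords, A$charges, B$coords, B$charges)
  expect_equal(coulombCoupling(A$coords, 2 * A$charges, B$coords, B$charges),
               2 * v, tolerance = 1e-14)
  expect_identical(coulombCoupling(A$coords, rep(0, 10),
                                   B$coords, B$charges), 0)
  expect_equal(coulombCoupling(B$coords, B$charges, A$coords, A$charges), v,
               tolerance = 1e-14)
  expect_error(coulombCoupling(A$coords, A$charges, A$coords, A$charges),
               "coincident")
})

test_that("V and O are invariant under joint rigid motion of both pigments", {
  set.seed(42)
  A <- randomPigment(12); B <- randomPigment(12)
  B$coords[, 2] <- B$coords[, 2] + 10
  elA <- rep("C", 12); elB <- rep(c("C", "N", "O"), 4)
  v0 <- coulombCoupling(A$coords, A$charges, B$coords, B$charges)
  o0 <- overlapParameter(A$coords, B$coords, elementsA = elA, elementsB = elB)
  both <- rigidMotion(rbind(A$coords, B$coords), seed = 43)
  v1 <- coulombCoupling(both[1:12, ], A$charges, both[13:24, ], B$charges)
  o1 <- overlapParameter(both[1:12, ], both[13:24, ],
                         elementsA = elA, elementsB = elB)
  expect_lt(abs(v1 - v0) / abs(v0), 1e-10)
  expect_lt(abs(o1 - o0) / o0, 1e-10)
})

test_that("charge-neutral pigments follow the dipole 1/r^3 far-field law", {
  rs <- exp(seq(log(50), log(500), length.out = 10))
  vs <- vapply(rs, function(r) {
    p <- generatePigmentPair(r, rotation = 20)
    abs(coulombCoupling(p$A@coords, p$A@charges, p$B@coords, p$B@charges))
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(vs) ~ log(rs)))[[2]]
  expect_lt(abs(slope + 3), 0.05)
})

test_that("sphere overlap reproduces its analytic limits", {
  one <- function(d, R1 = 1.7, R2 = 1.7)
    overlapParameter(matrix(0, 1, 3), matrix(c(d, 0, 0), 1, 3),
                     radiiA = R1, radiiB = R2)
  R <- 1.7
  expect_equal(one(0), (4 / 3) * pi * R^3, tolerance = 1e-12)
  expect_equal(one(1.7), (pi / 12) * (4 * R + 1.7) * (2 * R - 1.7)^2,
               tolerance = 1e-12)
  expect_equal(one(1.7), oracleLens, tolerance = 1e-6)
  expect_identical(one(3.4), 0)
  expect_identical(one(5), 0)
  # full containment of a smaller sphere
  expect_equal(one(0.2, R1 = 2, R2 = 0.5), (4 / 3) * pi * 0.5^3,
               tolerance = 1e-12)
  # continuity at the containment boundary
  expect_equal(one(1.5 + 1e-9, R1 = 2, R2 = 0.5),
               (4 / 3) * pi * 0.5^3, tolerance = 1e-6)
})

test_that("overlap is non-increasing as pigments separate along any axis", {
  set.seed(44)
  A <- matrix(runif(30, -2, 2), 10)
  B <- matrix(runif(30, -2, 2), 10)
  el <- rep("C", 10)
  for (axis in 1:3) {
    prev <- Inf
    for (shift in seq(0, 12, by = 0.5)) {
      Bs <- B; Bs[, axis] <- Bs[, axis] + shift
      o <- overlapParameter(A, Bs, elementsA = el, elementsB = el)
      expect_lte(o, prev + 1e-12)
      prev <- o
    }
    expect_identical(prev, 0)
  }
})

test_that("the sphere-model scale factor rescales radii", {
  d <- 4
  o1 <- overlapParameter(matrix(0, 1, 3), matrix(c(d, 0, 0), 1, 3),
                         elementsA = "C", elementsB = "C",
                         model = sphereModel(scale = 1))
  o2 <- overlapParameter(matrix(0, 1, 3), matrix(c(d, 0, 0), 1, 3),
                         elementsA = "C", elementsB = "C",
                         model = sphereModel(scale = 1.3))
  expect_identical(o1, 0)          # 2 * 1.7 = 3.4 < 4: no contact
  expect_gt(o2, 0)                 # 2 * 2.21 = 4.42 > 4: lens forms
  expect_error(sphereModel(scale = 0), "positive")
})

test_that("per-frame pair couplings behave over a translating ensemble", {
  p <- generatePigmentPair(4, rotation = 0, chargeMagnitude = 0.1)
  nfr <- 8
  frames <- lapply(seq_len(nfr), function(f) {
    b <- p$B@coords
    b[, 3] <- b[, 3] + (f - 1) * 2.5
    rbind(p$A@coords, b)
  })
  top <- rbind(makeTopology(6, chain = "P", resno = 1,
                            elety = paste0("C", 1:6)),
               makeTopology(6, chain = "Q", resno = 1,
                            elety = paste0("C", 1:6)))
  ens <- ensembleFromFrames(frames, top)
  qa <- withr::local_tempfile(fileext = ".tsv")
  writeChargeTable(p$A, qa)
  spec <- list(list(id = "toy", selectionA = atomSelection(chain = "P"),
                    selectionB = atomSelection(chain = "Q"),
                    chargesA = readChargeTable(qa),
                    chargesB = readChargeTable(qa)))
  tab <- pairCouplingsOverEnsemble(ens, spec)
  expect_equal(nrow(tab), nfr)
  # |V| strictly decreasing as the pair separates; O reaches 0 first
  expect_true(all(diff(abs(tab$vCoulomb)) < 0))
  expect_true(all(diff(tab$overlap) <= 1e-12))
  expect_identical(tab$overlap[nfr], 0)
  expect_gt(abs(tab$vCoulomb[nfr]), 0)
  firstZeroO <- which(tab$overlap == 0)[1]
  expect_lt(firstZeroO, nfr)
  # swapped pair order gives identical V and O
  specSwap <- list(list(id = "toy", selectionA = atomSelection(chain = "Q"),
                        selectionB = atomSelection(chain = "P"),
                        chargesA = readChargeTable(qa),
                        chargesB = readChargeTable(qa)))
  tabSwap <- pairCouplingsOverEnsemble(ens, specSwap)
  expect_equal(tabSwap$vCoulomb, tab$vCoulomb, tolerance = 1e-12)
  expect_equal(tabSwap$overlap, tab$overlap, tolerance = 1e-12)
  # identical frames give constant columns
  same <- ensembleFromFrames(frames[c(2, 2, 2)], top)
  tabSame <- pairCouplingsOverEnsemble(same, spec)
  expect_equal(length(unique(tabSame$vCoulomb)), 1L)
  expect_equal(length(unique(tabSame$overlap)), 1L)
})
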