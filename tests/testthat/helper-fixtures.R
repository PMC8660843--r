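# shared fixtures, all built in code

# minimal topology for hand-crafted coordinate sets
makeTopology <- function(n, chain = "A", resno = seq_len(n),
                         elety = paste0("C", seq_len(n)), elesy = "C",
                         resid = "UNK") {
  data.frame(chain = chain, resid = resid, resno = resno,
             elety = elety, elesy = elesy, stringsAsFactors = FALSE)
}

# ensemble from a list of per-frame coordinate matrices
ensembleFromFrames <- function(frames, topology) {
  coords <- array(NA_real_, c(length(frames), nrow(frames[[1]]), 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  ConformationalEnsemble(coords, topology)
}

# random rigid-body motion applied to an n x 3 coordinate matrix
rigidMotion <- function(xyz, seed) {
  set.seed(seed)
  q <- matrix(rnorm(9), 3)
  R <- qr.Q(qr(q))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t(R %*% t(xyz)) + matrix(rnorm(3) * 10, nrow(xyz), 3, byrow = TRUE)
}

# planted two-basin ensemble used by several tests: phi of three residues
# separated by pi across two equally weighted clusters
twoBasinFixture <- function(nFrames = 150, seed = 11, concentration = 30) {
  spec <- ensembleSpec(
    nFrames = nFrames, nResidues = 20, clusterWeights = c(0.5, 0.5),
    plantedResidues = c(5, 6, 15),
    plantedMeans = rbind(rep(-1, 3), rep(-1 + pi, 3)),
    concentration = concentration, seed = seed, noiseLevel = 0.05)
  generateEnsemble(spec)
}

# adjusted Rand index oracle (mclust)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# frozen constant-assembly oracle values (CODATA 2018, computed with an
# independent script before the implementation was written)
oracleK <- 116140.97328874          # e^2/Angstrom in cm^-1
oracleCouplingSpot <- -580.704866443702   # q = +0.1 e, -0.2 e at r = 4 A
oracleMarcusSpot <- 4.249713447415e5      # V=10 cm-1, dG=+0.2 eV, lam=0.7 eV, 300 K
oracleMarcusPrefactor <- 3.077129362864e10  # same V, lam, T at dG = -lam
oracleLens <- 6.431102              # equal spheres R = 1.7 A at r = 1.7 A
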