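#' Hierarchical clustering of frames in principal-component space
#'
#' Agglomerative clustering (default: Ward linkage on Euclidean distances)
#' of the retained dPCA scores, cutting the dendrogram at a user-chosen
#' number of conformational states. Clusters are relabeled by descending
#' size, ties broken by first occurrence, so cluster 0 is always the most
#' populated state.
#'
#' @param scores numeric matrix frames x components (from
#'   \code{\link{projectFrames}}).
#' @param nClusters number of clusters (>= 1, <= frames).
#' @param linkage agglomeration method passed to \code{\link[stats]{hclust}}
#'   (default "ward.D2").
#' @return a \linkS4class{ClusterModel}.
#' @export
hierarchicalCluster <- function(scores, nClusters, linkage = "ward.D2") {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1)
  n <- nrow(scores)
  if (nClusters < 1L) stop("nClusters must be >= 1")
  if (nClusters > n) stop("nClusters cannot exceed the number of frames")
  if (nClusters == n) {
    raw <- seq_len(n)
  } else {
    hc <- stats::hclust(stats::dist(scores), method = linkage)
    raw <- stats::cutree(hc, k = nClusters)
  }
  tab <- table(raw)
  sizes <- as.integer(tab)
  ord <- order(-sizes, as.integer(names(tab)))
  remap <- integer(length(tab))
  remap[as.integer(names(tab))[ord]] <- seq_along(ord) - 1L
  labels <- remap[raw]
  new("ClusterModel", labels = as.integer(labels), linkage = linkage,
      metric = "euclidean", nClusters = as.integer(nClusters),
      counts = as.integer(table(factor(labels, levels = 0:(nClusters - 1)))))
}

#' @rdname hierarchicalCluster
#' @param x a ClusterModel
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname hierarchicalCluster
setMethod("clusterLabels", "ClusterModel", function(x) x@labels)

setMethod("show", "ClusterModel", function(object) {
  cat("ClusterModel:", object@nClusters, "clusters (", object@linkage,
      "linkage,", object@metric, "),",
      length(object@labels), "frames\n")
  cat("  sizes:", paste(object@counts, collapse = ", "), "\n")
  invisible(NULL)
})

#' Farthest-point sampling of representative frames per cluster
#'
#' Greedy max-min selection in score space, independently within each
#' cluster: the first representative is the cluster medoid (the frame with
#' the smallest total distance to its cluster mates); each subsequent pick
#' maximises the minimum distance to the frames already selected. All ties
#' are broken by the lowest frame index, so the selection is deterministic.
#'
#' @param scores numeric matrix frames x components.
#' @param labels 0-based cluster labels (or a \linkS4class{ClusterModel}).
#' @param kPerCluster representatives per cluster; must not exceed any
#'   cluster's size.
#' @return named list, one integer vector of frame indices per cluster
#'   (in greedy selection order).
#' @export
farthestPointSample <- function(scores, labels, kPerCluster) {
  if (is(labels, "ClusterModel")) labels <- clusterLabels(labels)
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1)
  out <- list()
  for (cl in sort(unique(labels))) {
    members <- which(labels == cl)
    if (!length(members)) stop("empty cluster ", cl)
    if (kPerCluster > length(members))
      stop("kPerCluster exceeds the size of cluster ", cl)
    S <- scores[members, , drop = FALSE]
    D <- as.matrix(stats::dist(S))
    medoid <- which.min(rowSums(D))          # ties: which.min takes lowest
    sel <- medoid
    while (length(sel) < kPerCluster) {
      minD <- apply(D[, sel, drop = FALSE], 1, min)
      minD[sel] <- -Inf
      sel <- c(sel, which.max(minD))
    }
    out[[as.character(cl)]] <- members[sel]
  }
  out
}

#' Rank residues by how strongly their dihedrals discriminate the clusters
#'
#' For each dihedral feature the angles are embedded as (cos, sin) and the
#' correlation ratio eta^2 = SSB / (SSB + SSW) of the embedded points across
#' clusters is computed (between-cluster over total sum of squares; an
#' F-like variance-ratio statistic bounded in [0, 1], finite even at zero
#' within-cluster variance). A residue's score is the maximum over its
#' features; the ranking is by descending score with ties broken by residue
#' number.
#'
#' @param features a \linkS4class{DihedralFeatures}.
#' @param labels 0-based cluster labels (or a ClusterModel); at least two
#'   clusters with at least two frames each.
#' @return list with \code{featureScores} (data.frame resno, dihedral,
#'   score) and \code{residueRanking} (data.frame resno, score, rank).
#' @export
residueImportance <- function(features, labels) {
  if (is(labels, "ClusterModel")) labels <- clusterLabels(labels)
  a <- features@angles
  if (nrow(a) != length(labels))
    stop("labels length must equal the number of frames")
  tab <- table(labels)
  if (length(tab) < 2L || any(tab < 2L))
    stop("need >= 2 clusters with >= 2 frames each")
  g <- factor(labels)
  score <- numeric(ncol(a))
  for (j in seq_len(ncol(a))) {
    E <- cbind(cos(a[, j]), sin(a[, j]))
    mu <- colMeans(E)
    sst <- sum(sweep(E, 2, mu)^2)
    if (sst < 1e-24) { score[j] <- 0; next }
    ssb <- 0
    for (lev in levels(g)) {
      Ek <- E[g == lev, , drop = FALSE]
      ssb <- ssb + nrow(Ek) * sum((colMeans(Ek) - mu)^2)
    }
    score[j] <- ssb / sst
  }
  fs <- data.frame(resno = features@labels$resno,
                   dihedral = features@labels$dihedral,
                   score = score, stringsAsFactors = FALSE)
  agg <- tapply(fs$score, fs$resno, max)
  rr <- data.frame(resno = as.integer(names(agg)),
                   score = as.numeric(agg))
  rr <- rr[order(-rr$score, rr$resno), , drop = FALSE]
  rr$rank <- seq_len(nrow(rr))
  rownames(rr) <- NULL
  list(featureScores = fs, residueRanking = rr)
}
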