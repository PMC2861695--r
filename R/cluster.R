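#' Minimal RMSD between two structures (optimal superposition)
#'
#' Root-mean-square deviation after optimal rigid superposition (Kabsch:
#' centroids removed, rotation from the SVD of the covariance matrix,
#' restricted to proper rotations).
#'
#' @param A,B n x 3 coordinate matrices with matched atom ordering
#' @return RMSD in Angstrom
#' @export
kabsch_rmsd <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("structures must have equal atom counts")
  n <- nrow(A)
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  H <- crossprod(Ac, Bc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  diff <- Bc - Ac %*% t(R)
  sqrt(sum(diff^2) / n)
}

#' Pairwise RMSD distance matrix
#'
#' @param structures list of n x 3 coordinate matrices
#' @param atoms optional row indices to restrict the RMSD to (e.g. CA
#'   beads)
#' @return a symmetric `dist`-like matrix (base matrix, zero diagonal)
#' @export
rmsd_matrix <- function(structures, atoms = NULL) {
  n <- length(structures)
  if (!is.null(atoms))
    structures <- lapply(structures, function(m) m[atoms, , drop = FALSE])
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- kabsch_rmsd(structures[[i]], structures[[j]])
    }
  }
  D
}

#' Subsample frames by minimum time separation
#'
#' Greedy earliest-first selection keeping frames at least
#' `min_separation` apart (50 ps = 1000 tu by default), mirroring the
#' "separated by at least 50 ps" clustering input rule. With a `replica`
#' column, the rule is applied per replica.
#'
#' @param frames tibble with a `time` column (tu)
#' @param min_separation minimum time between kept frames (tu)
#' @return the kept rows of `frames`
#' @export
subsample_frames <- function(frames, min_separation = 1000) {
  pick <- function(t) {
    keep <- logical(length(t))
    last <- -Inf
    for (i in order(t)) {
      if (t[i] - last >= min_separation) { keep[i] <- TRUE; last <- t[i] }
    }
    keep
  }
  if ("replica" %in% names(frames)) {
    keep <- unsplit(lapply(split(frames$time, frames$replica), pick),
                    frames$replica)
  } else keep <- pick(frames$time)
  frames[keep, , drop = FALSE]
}

#' Single-linkage clustering at an RMSD cutoff
#'
#' Single linkage (minimum-distance criterion) at a fixed cutoff is
#' equivalent to the connected components of the graph whose edges join
#' structures closer than the cutoff; implemented as a deterministic
#' union-find over the thresholded edges (strictly `<` cutoff).
#'
#' @param D symmetric distance matrix
#' @param cutoff RMSD cutoff (Angstrom, > 0); 2.0 A is the study default,
#'   2.5 A for the XN1Q47 no-polyP model
#' @return a `cluster_result`: `membership` (cluster id per structure,
#'   ids ordered by decreasing cluster size then lowest member index),
#'   `clusters` (list of member index sets), `centroids`,
#'   `largest_fraction`, `cutoff`
#' @export
single_linkage <- function(D, cutoff) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (cutoff <= 0) stop("cutoff must be positive")
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(max(n - 1, 0))) {
    for (j in (i + 1):n) {
      if (D[i, j] < cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  if (n == 1) comp <- 1L else comp <- vapply(seq_len(n), find, integer(1))
  # relabel: decreasing size, ties by lowest member index
  sizes <- table(comp)
  ord <- order(-as.numeric(sizes), as.integer(names(sizes)))
  relab <- stats::setNames(seq_along(ord), names(sizes)[ord])
  membership <- unname(relab[as.character(comp)])
  clusters <- lapply(seq_along(ord), function(k) which(membership == k))
  centroids <- vapply(clusters, centroid, integer(1), D = D)
  structure(list(membership = membership, clusters = clusters,
                 centroids = centroids,
                 largest_fraction = length(clusters[[1]]) / n,
                 n = n, cutoff = cutoff),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> %d structures, %d clusters at %.2f Å, largest %.1f%% (centroid %d)\n",
    x$n, length(x$clusters), x$cutoff, 100 * x$largest_fraction,
    x$centroids[1]))
  invisible(x)
}

#' Number of clusters as a function of the RMSD cutoff
#'
#' The cutoff curve used to choose a clustering cutoff: similar
#' structures join on the steep initial descent, dissimilar ones only in
#' the tail, so a suitable cutoff sits after the first and before the
#' second. The suggested cutoff is the midpoint of the widest merge-free
#' gap in the pairwise distances (the knee plateau).
#'
#' @param D symmetric distance matrix
#' @param cutoffs ascending cutoff grid
#' @return tibble (`cutoff`, `n_clusters`) with attribute
#'   `suggested_cutoff`
#' @export
cluster_curve <- function(D, cutoffs) {
  if (is.unsorted(cutoffs)) stop("cutoffs must be ascending")
  D <- as.matrix(D)
  rows <- lapply(cutoffs, function(ct) {
    tibble::tibble(cutoff = ct,
                   n_clusters = length(single_linkage(D, ct)$clusters))
  })
  out <- dplyr::bind_rows(rows)
  # widest gap between consecutive merge heights (single-linkage dendrogram)
  hts <- sort(unique(stats::hclust(stats::as.dist(D), method = "single")$height))
  if (length(hts) >= 2) {
    gaps <- diff(hts)
    g <- which.max(gaps)
    attr(out, "suggested_cutoff") <- (hts[g] + hts[g + 1]) / 2
  } else {
    attr(out, "suggested_cutoff") <- if (length(hts)) hts[1] else NA_real_
  }
  class(out) <- c("cluster_curve", class(out))
  out
}

#' Centroid of a cluster
#'
#' The member minimizing the sum of distances to all other members (the
#' centermost node); ties break to the lowest index.
#'
#' @param members member indices
#' @param D distance matrix
#' @return the centroid's index
#' @export
centroid <- function(members, D) {
  if (length(members) == 0) stop("empty cluster")
  if (length(members) == 1) return(as.integer(members[1]))
  sums <- rowSums(D[members, members, drop = FALSE])
  as.integer(members[which.min(sums)])    # which.min takes the first tie
}

#' Fraction of structures in the largest cluster
#'
#' The significance measure of the overall representative: the size of
#' the largest cluster over the number of structures clustered; its
#' centroid is the representative conformation.
#'
#' @param result a `cluster_result`
#' @return fraction in (0, 1]
#' @export
representative_fraction <- function(result) {
  stopifnot(inherits(result, "cluster_result"))
  result$largest_fraction
}

#' @export
#' @importFrom generics tidy
tidy.cluster_result <- function(x, ...) {
  tibble::tibble(
    cluster = seq_along(x$clusters),
    size = lengths(x$clusters),
    fraction = lengths(x$clusters) / x$n,
    centroid = x$centroids)
}

#' @export
#' @importFrom generics glance
glance.cluster_result <- function(x, ...) {
  tibble::tibble(n_structures = x$n, n_clusters = length(x$clusters),
                 cutoff = x$cutoff, largest_fraction = x$largest_fraction,
                 representative = x$centroids[1])
}

#' @export
autoplot.cluster_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$cutoff, .data$n_clusters)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "RMSD cutoff (Å)", y = "clusters remaining")
  sc <- attr(object, "suggested_cutoff")
  if (is.finite(sc))
    p <- p + ggplot2::geom_vline(xintercept = sc, linetype = "dashed")
  p
}
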