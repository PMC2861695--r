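test_that("optimal-superposition RMSD is zero for rigid copies", {
  set.seed(81)
  A <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_rmsd(A, A), 0, tolerance = 1e-12)
  # arbitrary proper rotation + translation
  ang <- c(0.4, -1.1, 2.2)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
              c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  B <- A %*% t(Rz %*% Rx) + matrix(rep(c(5, -3, 8), each = 10), 10, 3)
  expect_lt(kabsch_rmsd(A, B), 1e-9)
  expect_error(kabsch_rmsd(A, B[1:5, ]), "equal atom counts")
})

test_that("RMSD matches a brute-force rotation grid on planar toy sets", {
  # planar points: the optimal rotation is about z, so a fine 1D grid of
  # angles is an exhaustive oracle
  set.seed(82)
  A <- cbind(matrix(rnorm(8), 4, 2), 0)
  B <- cbind(matrix(rnorm(8), 4, 2), 0)
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  # proper 3D rotations acting within the plane: z-rotations plus
  # 180-degree flips about in-plane axes (2D reflections)
  grid_best <- min(vapply(seq(0, 2 * pi, by = 0.01 * pi / 180), function(th) {
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    F <- diag(c(1, -1, -1))              # proper flip about x
    min(sqrt(sum((Bc - Ac %*% t(R))^2) / 4),
        sqrt(sum((Bc - Ac %*% t(R %*% F))^2) / 4))
  }, numeric(1)))
  expect_equal(kabsch_rmsd(A, B), grid_best, tolerance = 1e-6)
})

test_that("RMSD is symmetric and respects the triangle inequality", {
  set.seed(83)
  xs <- replicate(6, matrix(rnorm(24), 8, 3), simplify = FALSE)
  for (i in 1:5) {
    expect_equal(kabsch_rmsd(xs[[i]], xs[[i + 1]]),
                 kabsch_rmsd(xs[[i + 1]], xs[[i]]), tolerance = 1e-9)
  }
  d <- function(i, j) kabsch_rmsd(xs[[i]], xs[[j]])
  for (tri in list(c(1, 2, 3), c(2, 4, 6), c(1, 3, 5))) {
    expect_lte(d(tri[1], tri[3]),
               d(tri[1], tri[2]) + d(tri[2], tri[3]) + 1e-9)
  }
})

test_that("frame subsampling honours the minimum time separation", {
  frames <- tibble::tibble(time = seq(10, 5000, by = 10))
  kept <- subsample_frames(frames, min_separation = 1000)
  expect_equal(kept$time, seq(10, 5000, by = 1000))  # every 100th frame
  expect_equal(nrow(subsample_frames(frames[3, ], 1000)), 1)
  expect_equal(nrow(subsample_frames(frames, 0)), nrow(frames))
  # per-replica application
  two <- dplyr::bind_rows(
    tibble::tibble(replica = 1, time = seq(10, 100, 10)),
    tibble::tibble(replica = 2, time = seq(10, 100, 10)))
  expect_equal(nrow(subsample_frames(two, 50)), 4)
})

test_that("single linkage equals connected components on random matrices", {
  set.seed(84)
  for (rep in 1:8) {
    n <- sample(c(20, 60, 120, 200), 1)
    P <- matrix(rnorm(n * 3), n, 3)
    D <- as.matrix(dist(P))
    cutoff <- quantile(D[upper.tri(D)], runif(1, 0.01, 0.3))
    res <- single_linkage(D, cutoff)
    oracle <- flood_fill_components(D, cutoff)
    # identical partitions up to label names
    expect_equal(length(res$clusters), length(unique(oracle)))
    cross <- table(res$membership, oracle)
    expect_true(all(rowSums(cross > 0) == 1))
    expect_true(all(colSums(cross > 0) == 1))
    # and the same partition as cutree on an hclust single-linkage tree
    hc <- stats::hclust(stats::as.dist(D), method = "single")
    ct <- stats::cutree(hc, h = cutoff * (1 - 1e-12))
    cross2 <- table(res$membership, ct)
    expect_true(all(rowSums(cross2 > 0) == 1))
  }
})

test_that("single linkage chains through intermediate structures", {
  D <- rbind(c(0, 1.5, 3.5), c(1.5, 0, 1.5), c(3.5, 1.5, 0))
  res <- single_linkage(D, 2)
  expect_equal(length(res$clusters), 1)   # A-B-C chained via B
  # trivial extremes
  expect_equal(length(single_linkage(D, 0.5)$clusters), 3)
  expect_equal(length(single_linkage(D, 100)$clusters), 1)
})

test_that("the cutoff curve is monotone with the right endpoints", {
  set.seed(85)
  P <- matrix(rnorm(60), 20, 3)
  D <- as.matrix(dist(P))
  cuts <- seq(1e-6, max(D) * 1.1, length.out = 30)
  curve <- cluster_curve(D, cuts)
  expect_true(all(diff(curve$n_clusters) <= 0))
  expect_equal(curve$n_clusters[1], 20)
  expect_equal(curve$n_clusters[nrow(curve)], 1)
  expect_error(cluster_curve(D, rev(cuts)), "ascending")
})

test_that("blob fixtures are recovered exactly with the expected fraction", {
  blobs <- make_cluster_blobs(sizes = c(50, 30, 20), spread = 0.1, seed = 86)
  D <- rmsd_matrix(blobs$structures)
  res <- single_linkage(D, 1)
  expect_equal(length(res$clusters), 3)
  cross <- table(res$membership, blobs$labels)
  expect_true(all(rowSums(cross > 0) == 1))
  expect_equal(representative_fraction(res), 0.5)
  expect_equal(lengths(res$clusters), c(50, 30, 20))
  # the cutoff curve plateaus at 3 across the within/between gap
  curve <- cluster_curve(D, c(0.5, 1, 2, 3))
  expect_true(all(curve$n_clusters[curve$cutoff %in% c(1, 2)] == 3))
})

test_that("centroids are the centermost members with deterministic ties", {
  # 3 points on a line at 0, 1, 3: the middle point minimizes distance sums
  D <- as.matrix(dist(c(0, 1, 3)))
  expect_equal(centroid(1:3, D), 2)
  expect_equal(centroid(2, D), 2)          # singleton is its own centroid
  expect_error(centroid(integer(0), D), "empty")
  # equilateral triple: tie broken to the lowest index
  De <- matrix(1, 3, 3) - diag(3)
  expect_equal(centroid(1:3, De), 1)
})

test_that("fractions count singletons and monoliths correctly", {
  D10 <- matrix(10, 10, 10) - diag(10) * 10
  allsing <- single_linkage(D10, 1)
  expect_equal(representative_fraction(allsing), 0.1)
  one <- single_linkage(D10, 20)
  expect_equal(representative_fraction(one), 1)
  expect_equal(glance(one)$n_clusters, 1)
  td <- tidy(allsing)
  expect_equal(nrow(td), 10)
  expect_equal(sum(td$fraction), 1)
})
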