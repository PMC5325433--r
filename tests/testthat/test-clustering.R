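test_that("log150 transform maps 1->0, 150->1, 150^2->2 and clips below 1", {
  expect_equal(log150_transform(c(1, 150, 22500)), c(0, 1, 2))
  expect_equal(log150_transform(0), 0)
  expect_equal(log150_transform(0.2), 0)
  expect_error(log150_transform(-1), "non-negative")
})

test_that("city-block distance averages over jointly observed components", {
  expect_equal(cityblock_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(cityblock_distance(c(1, 2), c(4, 6)), 3.5)
  expect_equal(cityblock_distance(c(1, NA, 3), c(2, 5, NA)), 1)
  expect_error(cityblock_distance(c(NA, NA), c(1, 2)), "jointly observed")
  expect_error(cityblock_distance(1:3, 1:2), "equal length")
})

test_that("correlation distance matches the Pearson formula", {
  b <- c(1, 3, 2, 5, 4)
  expect_equal(correlation_distance(2 * b + 1, b), 0)
  expect_equal(correlation_distance(-b, b), 2)
  set.seed(3)
  for (rep in 1:10) {
    a <- rnorm(8); b <- rnorm(8)
    num <- sum((a - mean(a)) * (b - mean(b)))
    den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(correlation_distance(a, b), 1 - num / den)
    expect_equal(correlation_distance(a, b, centered = FALSE),
                 1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
  }
  expect_error(correlation_distance(c(1, 1, 1), c(1, 2, 3)),
               "zero variance")
})

test_that("average linkage reproduces hand agglomeration and ties at zero", {
  d <- matrix(c(0, 2, 4,
                2, 0, 6,
                4, 6, 0), 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- average_linkage(d)
  expect_equal(hc$height, c(2, 5))
  expect_equal(unname(cut_tree(hc, 2)), c(1, 1, 2))
  # duplicates merge at height 0
  x <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 9, 9))
  hc2 <- average_linkage(pairwise_distances(x, "cityblock"))
  expect_equal(hc2$height[1], 0)
})

test_that("average linkage agrees with naive re-scan and hclust on random instances", {
  set.seed(21)
  for (rep in 1:12) {
    n <- sample(3:12, 1)
    x <- matrix(rnorm(n * 5), n,
                dimnames = list(paste0("i", seq_len(n)), NULL))
    d <- pairwise_distances(x, "cityblock")
    hc <- average_linkage(d)
    expect_equal(hc$height, naive_upgma_heights(d), tolerance = 1e-10)
    expect_true(all(diff(hc$height) >= -1e-12))  # monotone merges
    ref <- stats::hclust(stats::as.dist(d), method = "average")
    expect_equal(sort(hc$height), sort(ref$height), tolerance = 1e-10)
    for (k in c(2, min(4, n)))
      expect_equal(ari(stats::cutree(ref, k), cut_tree(hc, k)), 1)
  }
})

test_that("dendrogram is invariant to item input order", {
  set.seed(22)
  x <- matrix(rnorm(8 * 4), 8,
              dimnames = list(paste0("i", 1:8), NULL))
  d <- pairwise_distances(x, "cityblock")
  perm <- sample(8)
  hc1 <- average_linkage(d)
  hc2 <- average_linkage(d[perm, perm])
  expect_equal(hc1$height, hc2$height, tolerance = 1e-12)
  for (k in 2:4) {
    p1 <- cut_tree(hc1, k)
    p2 <- cut_tree(hc2, k)[hc1$labels]
    expect_equal(ari(p1, p2), 1)
  }
})

test_that("cut_tree spans single cluster to singletons", {
  d <- pairwise_distances(matrix(rnorm(20), 5), "cityblock")
  hc <- average_linkage(d)
  expect_equal(unname(cut_tree(hc, 1)), rep(1, 5))
  expect_equal(sort(unname(cut_tree(hc, 5))), 1:5)
  expect_error(cut_tree(hc, 6), "1..5")
  expect_error(average_linkage(d[1, 1, drop = FALSE]), "at least two")
})

test_that("two-way clustering separates planted row blocks and conserves values", {
  set.seed(23)
  block1 <- matrix(rnorm(12, mean = 0), 4, 3)
  block2 <- matrix(rnorm(12, mean = 50), 4, 3)
  x <- rbind(block1, block2) + matrix(rnorm(24, sd = 0.1), 8, 3)
  rownames(x) <- paste0("r", 1:8)
  colnames(x) <- paste0("m", 1:3)
  tw <- two_way_cluster(x, row_metric = "cityblock",
                        col_metric = "cityblock")
  labs <- cut_tree(tw$row_dendrogram, 2)
  expect_equal(ari(labs, rep(1:2, each = 4)), 1)
  expect_equal(sort(as.vector(tw$matrix)), sort(as.vector(x)))
  x_na <- x; x_na[, 2] <- NA
  expect_error(two_way_cluster(x_na, col_metric = "cityblock"), "m2")
})

test_that("row clustering of a strong three-group score matrix recovers the groups", {
  # noiseless latent structure: three well-separated score profiles
  set.seed(24)
  proto <- rbind(g1 = c(20, 20, 4, 4), g2 = c(12, 12, 10, 10),
                 g3 = c(2, 2, 18, 18))
  lab <- rep(1:3, times = c(6, 6, 8))
  x <- proto[lab, ] + matrix(sample(0:1, length(lab) * 4, TRUE),
                             length(lab))
  rownames(x) <- sprintf("case%02d", seq_along(lab))
  tw <- two_way_cluster(x, row_metric = "cityblock",
                        col_metric = "correlation")
  expect_equal(ari(cut_tree(tw$row_dendrogram, 3), lab), 1)
})

test_that("tree and clustered-table exports are written and well-formed", {
  set.seed(25)
  x <- matrix(rnorm(24), 6, 4,
              dimnames = list(paste0("r", 1:6), paste0("m", 1:4)))
  tw <- two_way_cluster(x, col_metric = "cityblock")
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tw$row_dendrogram, nwk)
  tree <- ape::read.tree(nwk)
  expect_setequal(tree$tip.label, rownames(x))
  base <- withr::local_tempfile()
  paths <- write_clustered_table(tw, base)
  expect_true(all(file.exists(paths)))
  cdt <- readLines(paths["cdt"])
  expect_equal(length(cdt), 2 + 6)  # header + AID row + 6 data rows
  gtr <- read.delim(paths["gtr"], header = FALSE)
  expect_equal(nrow(gtr), 5)        # n - 1 merges
})
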