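test_that("IBS and Modified Rogers distances hit their closed-form anchors", {
  d <- rbind(a = c(0L, 0L), b = c(2L, 2L), c = c(1L, 0L))
  ibs <- ibs_distance(d)
  expect_equal(unname(diag(ibs)), c(0, 0, 0))
  expect_equal(ibs["a", "b"], 1)                 # opposite homozygotes
  expect_equal(ibs["a", "c"], 0.25)              # one het over two sites
  expect_equal(ibs_distance(rbind(x = c(0L, 1L), y = c(1L, 1L)))["x", "y"],
               0.25)
  # single site, 0 vs 1 -> 0.5
  expect_equal(ibs_distance(rbind(x = 0L, y = 1L))["x", "y"], 0.5)

  mr <- modified_rogers_distance(d)
  expect_equal(mr["a", "b"], 1)
  expect_equal(unname(diag(mr)), c(0, 0, 0))
  # one of two sites differing by one dosage -> sqrt(1/8)
  expect_equal(mr["a", "c"], sqrt(0.125))
})

test_that("distance matrices are symmetric with zero diagonal on random panels", {
  set.seed(12)
  for (i in 1:5) {
    d <- matrix(rbinom(15 * 60, 2, runif(1, 0.2, 0.8)), 15)
    d[sample(length(d), 30)] <- NA
    rownames(d) <- paste0("a", 1:15)
    for (fun in list(ibs_distance, modified_rogers_distance)) {
      m <- fun(d)
      expect_equal(m, t(m))
      expect_equal(unname(diag(m)), rep(0, 15))
      expect_true(all(m >= 0 & m <= 1))
    }
  }
  # pair with no comparable sites errors
  bad <- rbind(a = c(1L, NA), b = c(NA, 1L))
  expect_error(ibs_distance(bad), "comparable")
})

test_that("GRM PCA separates simulated demes and orders variance", {
  b <- bn_two_pop_panel(n_per = 30, m = 1500, fst = 0.2, seed = 9)
  pca <- grm_pca(b$panel, n_components = 5)
  pc1 <- pca$coordinates[, 1]
  g1 <- pc1[b$popmap == "P1"]
  g2 <- pc1[b$popmap == "P2"]
  lo <- range(g1); hi <- range(g2)
  expect_true(max(lo) < min(hi) || max(hi) < min(lo))  # clean separation
  expect_true(all(diff(pca$variance_percent) <= 1e-9))
  expect_lte(sum(pca$variance_percent), 100 + 1e-9)

  # identical accessions: all eigenvalues zero
  same <- matrix(rep(c(0L, 1L, 2L, 1L), each = 6), nrow = 6)
  rownames(same) <- paste0("a", 1:6)
  expect_error(grm_pca(same, 2), NA)
  pca0 <- grm_pca(same, 2)
  expect_equal(max(abs(pca0$eigenvalues)), 0, tolerance = 1e-10)
  expect_error(grm_pca(same, 10), "components")
})

test_that("PCoA is exact on Euclidean input and splits two points evenly", {
  set.seed(20)
  pts <- matrix(runif(10), 5, 2)
  d <- as.matrix(dist(pts))
  fit <- pcoa(d, n_components = 4)
  rec <- as.matrix(dist(fit$coordinates))
  expect_lt(max(abs(rec - d)), 1e-8)

  two <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  fit2 <- pcoa(two, 1)
  expect_equal(sort(fit2$coordinates[, 1]), c(-0.5, 0.5), ignore_attr = TRUE)

  ns <- d; ns[1, 2] <- ns[1, 2] + 1
  expect_error(pcoa(ns), "symmetric")
})

test_that("PCoA of an IBS matrix groups the truth demes on axis 1", {
  b <- bn_two_pop_panel(n_per = 25, m = 1200, fst = 0.2, seed = 14)
  fit <- pcoa(ibs_distance(b$panel), 2)
  ax <- fit$coordinates[, 1]
  side <- ax > median(ax)
  lab <- b$popmap == "P1"
  expect_true(mean(side == lab) > 0.95 || mean(side != lab) > 0.95)
})

test_that("NJ reconstructs additive trees exactly", {
  # three leaves: closed-form three-point lengths
  d3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(d3)
  expect_equal(sort(t3$edge.length), c(1, 2, 4))
  # additive matrices from random trees, up to 8 taxa: exact recovery
  set.seed(6)
  for (n in c(4, 6, 8)) {
    tr <- ape::rtree(n, rooted = FALSE)
    d <- ape::cophenetic.phylo(tr)
    nt <- nj_tree(d)
    expect_lt(max(abs(ape::cophenetic.phylo(nt)[rownames(d), colnames(d)] - d)),
              1e-8)
  }
  expect_error(nj_tree(matrix(c(0, Inf, Inf, 0), 2, 2)), "finite")
})

test_that("NJ agrees with the least-squares topology-enumeration oracle", {
  skip_if_not_installed("phangorn")
  set.seed(23)
  for (i in 1:5) {
    n <- sample(4:6, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    tr$edge.length <- tr$edge.length + 0.1
    d <- ape::cophenetic.phylo(tr)
    mine <- nj_tree(d)
    oracle <- nj_enumeration_oracle(d)
    expect_lt(oracle$rss, 1e-12)
    expect_equal(phangorn::RF.dist(mine, oracle$tree), 0)
  }
})

test_that("NJ on ultrametric distances matches single-linkage topology", {
  skip_if_not_installed("phangorn")
  set.seed(27)
  tr <- ape::rcoal(6)                     # ultrametric
  d <- ape::cophenetic.phylo(tr)
  mine <- nj_tree(d)
  hc <- hclust(as.dist(d), method = "single")
  hc_tree <- ape::as.phylo(hc)
  expect_equal(phangorn::RF.dist(ape::unroot(mine), ape::unroot(hc_tree)), 0)
})

test_that("negative NJ branches are clamped with the deficit logged", {
  d <- matrix(c(0, 1, 6, 6,
                1, 0, 6, 6,
                6, 6, 0, 0.2,
                6, 6, 0.2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
  expect_gte(attr(tr, "negative_deficit"), 0)
})

test_that("phenotype clustering recovers planted blobs and handles k extremes", {
  set.seed(33)
  x <- rbind(matrix(rnorm(40 * 3, 0), ncol = 3),
             matrix(rnorm(40 * 3, 8), ncol = 3))
  rownames(x) <- paste0("a", 1:80)
  cl <- hclust_phenotypes(as.data.frame(x), k = 2)
  expect_equal(length(unique(cl[1:40])), 1)
  expect_equal(length(unique(cl[41:80])), 1)
  expect_false(cl[1] == cl[41])

  cl_n <- hclust_phenotypes(as.data.frame(x[1:5, ]), k = 5)
  expect_equal(sort(unique(cl_n)), 1:5)
  expect_error(hclust_phenotypes(as.data.frame(x[1:3, ]), k = 4), "exceeds")

  same <- as.data.frame(matrix(1, 6, 3))
  rownames(same) <- paste0("s", 1:6)
  cl_same <- hclust_phenotypes(same, k = 2)
  expect_true(length(unique(attr(cl_same, "hclust")$height)) == 1)
})

test_that("kinship matrix has unit diagonal and flags duplicates", {
  fx <- cached_fixture()
  k <- kinship_matrix(fx$panel)
  expect_equal(unname(diag(k)), rep(1, nrow(k)))
  for (pr in fx$fx$truth$duplicate_pairs) {
    expect_equal(k[pr[1], pr[2]], 1, tolerance = 1e-12)
  }
  # independent accessions from a uniform-frequency pool: |r| small
  set.seed(44)
  ind <- matrix(rbinom(2 * 10000, 2, 0.5), 2, byrow = TRUE)
  rownames(ind) <- c("x", "y")
  expect_lt(abs(kinship_matrix(ind)["x", "y"]), 0.05)
})

test_that("kinship bins partition all pairs with percentages summing to 100", {
  set.seed(50)
  n <- 12
  k <- matrix(runif(n * n, -0.5, 1), n)
  k <- (k + t(k)) / 2
  diag(k) <- 1
  b <- kinship_bins(k)
  expect_equal(sum(b$count), choose(n, 2))
  expect_equal(sum(b$percent), 100, tolerance = 1e-9)
  # all-identical panel -> every pair above 0.5
  same <- matrix(1, 3, 3)
  b2 <- kinship_bins(same)
  expect_equal(b2$count[b2$bin == ">0.5"], 3)
  expect_equal(b2$percent[b2$bin == ">0.5"], 100)
  # boundary: 0.5 falls in the [0.25, 0.5] bin, not above it
  kb <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  b3 <- kinship_bins(kb)
  expect_equal(b3$count[b3$bin == "[0.25,0.5]"], 1)
})

test_that("group composition cross-tabulates with row percentages", {
  a <- rep("G2", 152)
  b <- c(rep("C1", 69), rep("C2", 72), rep("C4", 11))
  gc <- group_composition(a, b)
  expect_equal(round(as.numeric(gc$percent["G2", c("C1", "C2", "C4")]), 2),
               c(45.39, 47.37, 7.24))
  expect_equal(sum(gc$counts["G2", ]), 152)

  ident <- group_composition(c(1, 2, 1), c(1, 2, 1))
  expect_true(all(gc <- diag(as.matrix(ident$counts)) == c(2, 1)))
})
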