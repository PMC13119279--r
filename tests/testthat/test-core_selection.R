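test_that("core sizes follow floor(n * fraction) with a floor of one", {
  expect_equal(core_fraction_size(313, 0.30), 93)
  expect_equal(core_fraction_size(313, 0.05), 15)
  expect_equal(core_fraction_size(100, 0.10), 10)
  expect_equal(core_fraction_size(10, 0.01), 1)
  expect_error(core_fraction_size(100, 0), "fraction")
  expect_error(core_fraction_size(100, 1.5), "fraction")
})

test_that("A-NE objective equals exhaustive evaluation on toy matrices", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2)
  expect_equal(ane_objective(d2, 1:2), 0.4)
  # duplicated entry pulls the objective toward zero
  d3 <- matrix(c(0, 0, 0.9, 0, 0, 0.9, 0.9, 0.9, 0), 3, 3)
  expect_lt(ane_objective(d3, 1:3), ane_objective(d3, 2:3))
  # 5-point matrix: agree with direct enumeration for every size-3 subset
  set.seed(61)
  d5 <- as.matrix(dist(runif(5)))
  for (s in utils::combn(5, 3, simplify = FALSE)) {
    direct <- mean(vapply(s, function(i) {
      min(d5[i, setdiff(s, i)])
    }, numeric(1)))
    expect_equal(ane_objective(d5, s), direct)
  }
  expect_error(ane_objective(d5, 2), "two entries")
})

test_that("subset optimisation attains the exhaustive optimum at n=12, k=4", {
  set.seed(11)
  d <- as.matrix(dist(matrix(runif(24), 12, 2)))
  best <- max(apply(utils::combn(12, 4), 2,
                    function(s) ane_objective(d, s)))
  res <- optimize_subset(d, 4, seed = 5, restarts = 10)
  expect_equal(res$objective, best)
  # local optimality: no single swap improves the returned subset
  outside <- setdiff(1:12, res$subset)
  for (i in seq_along(res$subset)) {
    for (u in outside) {
      cand <- res$subset
      cand[i] <- u
      expect_lte(ane_objective(d, cand), res$objective + 1e-12)
    }
  }
})

test_that("optimisation picks one entry per tight cluster and beats random", {
  pts <- rbind(matrix(rnorm(10, 0, 0.01), 5, 2),
               matrix(rnorm(10, 5, 0.01), 5, 2))
  d <- as.matrix(dist(pts))
  res <- optimize_subset(d, 2, seed = 1)
  expect_equal(sort(c(any(res$subset <= 5), any(res$subset > 5))),
               c(TRUE, TRUE))
  # random subsets never beat the optimised one (100 seeded draws)
  set.seed(71)
  dd <- as.matrix(dist(matrix(runif(40), 20, 2)))
  opt <- optimize_subset(dd, 6, seed = 2, restarts = 8)
  for (i in 1:100) {
    expect_lte(ane_objective(dd, sample(20, 6)), opt$objective + 1e-12)
  }
  # size = n returns the whole panel
  full <- optimize_subset(dd, 20, seed = 1)
  expect_equal(full$subset, 1:20)
  expect_error(optimize_subset(dd, 21, seed = 1), "exceeds")
})

test_that("gradient core search: identity at 100% and duplicate exclusion", {
  fx <- cached_fixture()
  pf <- subset_panel(fx$panel, sites = hard_filter(fx$panel)$keep)

  res1 <- gradient_core_search(pf, fractions = 1.0, seed = 3)
  full <- panel_diversity(pf)
  expect_equal(res1$table$He[1], full$He)
  expect_equal(res1$table$pi[1], full$pi)
  expect_equal(res1$chosen_fraction, 1.0)

  res <- gradient_core_search(pf, fractions = c(0.25, 0.5, 0.75), seed = 3,
                              restarts = 3)
  # one row per fraction plus the 100% reference
  expect_equal(nrow(res$table), 4)
  expect_equal(res$table$fraction, c(0.25, 0.5, 0.75, 1.0))
  # no planted duplicate pair is ever jointly selected
  for (f in names(res$subsets)) {
    ids <- res$subsets[[f]]
    if (length(ids) > nrow(pf$dosages) - 2) next
    for (pr in fx$fx$truth$duplicate_pairs) {
      expect_false(all(pr %in% ids))
    }
  }
})

test_that("core evaluation: identity, hand-computed CR, inflated VR", {
  set.seed(81)
  full <- data.frame(T1 = rnorm(40, 10, 2), T2 = rnorm(40, 20, 4))
  rownames(full) <- paste0("a", 1:40)
  for (conv in c("mixed", "significance-count", "relative-magnitude")) {
    ev <- evaluate_core_pheno(full, full, conv)
    expect_equal(ev$md_percent, 0)
    expect_equal(ev$vd_percent, 0)
    expect_equal(ev$cr_percent, 100)
    expect_equal(ev$vr_percent, 100)
  }

  # two-trait toy with ranges 8 vs 10 and 9 vs 10 -> CR = 85
  fullr <- data.frame(T1 = c(0, 5, 10, 4, 6), T2 = c(0, 5, 10, 3, 7))
  core <- data.frame(T1 = c(1, 5, 9), T2 = c(0.5, 5, 9.5))
  ev2 <- evaluate_core_pheno(core, fullr, "relative-magnitude")
  expect_equal(ev2$cr_percent, 85.0)

  # removing central values keeps CR at 100 and inflates VR
  full3 <- data.frame(T1 = c(0, 2, 4, 5, 6, 8, 10))
  core3 <- data.frame(T1 = c(0, 5, 10))
  ev3 <- evaluate_core_pheno(core3, full3, "relative-magnitude")
  expect_equal(ev3$cr_percent, 100)
  expect_gt(ev3$vr_percent, 100)

  # significance-count values are multiples of 100 / n_traits
  set.seed(82)
  shifted <- full
  shifted$T1 <- shifted$T1 + 10
  ev4 <- evaluate_core_pheno(shifted, full, "significance-count")
  expect_true(ev4$md_percent %in% c(0, 50, 100))
  expect_equal(ev4$md_percent, 50)
})

test_that("phenotype core selection preserves planted extremes", {
  set.seed(91)
  center <- data.frame(T1 = rnorm(36, 0, 0.3), T2 = rnorm(36, 0, 0.3))
  corners <- data.frame(T1 = c(-10, -10, 10, 10), T2 = c(-10, 10, -10, 10))
  full <- rbind(center, corners)
  rownames(full) <- paste0("a", 1:40)
  planted <- paste0("a", 37:40)
  res <- select_pheno_core(full, fractions = 0.15, seed = 4, restarts = 3)
  expect_equal(length(res$core_ids), 6)
  expect_true(all(planted %in% res$core_ids))
  expect_equal(res$evaluation$cr_percent, 100)
})

test_that("merging cores is a stable union with overlap accounting", {
  a <- sprintf("g%03d", 1:93)
  b <- c(sprintf("g%03d", 1:3), sprintf("x%02d", 1:12))  # overlap of 3
  m <- merge_cores(a, b)
  expect_equal(m$n_core1, 93)
  expect_equal(m$n_core2, 15)
  expect_equal(m$n_overlap, 3)
  expect_equal(m$n_merged, 105)
  # commutative and idempotent on the ID set
  m2 <- merge_cores(b, a)
  expect_setequal(m$merged_ids, m2$merged_ids)
  m3 <- merge_cores(m$merged_ids, m$merged_ids)
  expect_equal(m3$merged_ids, m$merged_ids)
  # disjoint and subset cases
  expect_equal(merge_cores(c("p", "q"), c("r", "s", "t"))$n_merged, 5)
  expect_equal(merge_cores(a, a[1:10])$merged_ids, a)
})

test_that("ANOVA validation matches hand-computed sums of squares", {
  g1 <- c(18, 20, 21, 22)
  g2 <- c(24, 26, 27, 25)
  g3 <- c(30, 31, 29, 32)
  # formula-level oracle: SSB / SSW by hand
  all_v <- c(g1, g2, g3)
  gm <- mean(all_v)
  ssb <- 4 * ((mean(g1) - gm)^2 + (mean(g2) - gm)^2 + (mean(g3) - gm)^2)
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2) +
    sum((g3 - mean(g3))^2)
  f_hand <- (ssb / 2) / (ssw / 9)

  tabs <- list(A = data.frame(y = g1), B = data.frame(y = g2),
               C = data.frame(y = g3))
  val <- validate_core(tabs)
  expect_equal(val$anova$F[1], f_hand, tolerance = 1e-6)
  expect_equal(nrow(val$tukey), 3)

  # three identical groups -> F = 0, all pairwise N.S.
  same <- data.frame(y = c(1, 2, 3, 4))
  val0 <- validate_core(list(A = same, B = same, C = same))
  expect_equal(val0$anova$F[1], 0)
  expect_true(all(val0$tukey$signif == "N.S."))

  # a 10-sigma shifted group is flagged ***
  set.seed(101)
  base <- data.frame(y = rnorm(20))
  far <- data.frame(y = rnorm(20) + 10)
  val1 <- validate_core(list(A = base, B = base, C = far))
  expect_lt(val1$anova$p[1], 0.001)
  expect_equal(val1$anova$signif[1], "***")
})
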