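test_that("substitutions classify by purine/pyrimidine class", {
  expect_equal(classify_substitution("A", "G"), "transition")
  expect_equal(classify_substitution("T", "C"), "transition")
  expect_equal(classify_substitution("C", "A"), "transversion")
  expect_equal(classify_substitution(c("A", "G", "C"), c("T", "C", "G")),
               c("transversion", "transversion", "transversion"))
  expect_error(classify_substitution("A", "N"), "A/C/G/T")
  expect_error(classify_substitution("A", "A"), "differ")
})

test_that("ts_tv_summary reproduces count ratios and degenerate cases", {
  # 68.22% transitions vs 31.78% transversions -> ratio 2.146
  v <- data.frame(ref = c(rep("A", 6822), rep("A", 3178)),
                  alt = c(rep("G", 6822), rep("C", 3178)))
  s <- ts_tv_summary(v)
  expect_equal(s$ratio, 2.146, tolerance = 0.001)
  expect_equal(s$transition_count + s$transversion_count, nrow(v))
  expect_equal(sum(s$type_percent), 100)

  expect_warning(s2 <- ts_tv_summary(data.frame(ref = "A", alt = "G")),
                 "infinite")
  expect_identical(s2$ratio, Inf)

  s3 <- ts_tv_summary(data.frame(ref = c("A", "A"), alt = c("G", "C")))
  expect_equal(s3$ratio, 1.0)
})

test_that("hard_filter applies OR-of-failures with absent-annotation pass", {
  base <- data.frame(chrom = "Chr1", pos = 1:4, ref = "A", alt = "G",
                     qual = 50, QD = 10, MQ = 55, FS = 10, SOR = 1,
                     MQRankSum = 0, ReadPosRankSum = 0)
  base$QD[2] <- 1.5                      # fails QD only
  base$FS[3] <- 60.0                     # boundary: strictly > 60 removes
  base[4, c("QD", "MQ", "FS", "SOR", "MQRankSum", "ReadPosRankSum")] <- NA
  res <- hard_filter(base)
  expect_identical(res$keep, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(unname(res$removed_by_rule["QD"]), 1)
  expect_equal(sum(res$removed_by_rule), 1)
  # idempotent
  again <- hard_filter(base[res$keep, ])
  expect_true(all(again$keep))
})

test_that("maf_filter keeps the inclusive boundary and drops monomorphs", {
  # 10 accessions, 2 ALT alleles -> MAF = 0.1 exactly, kept
  d <- rbind(matrix(0L, 9, 1), 2L)
  rownames(d) <- paste0("a", 1:10)
  expect_true(maf_filter(d, 0.1))
  # monomorphic REF site removed; (0,1,2) has MAF 0.5
  d2 <- cbind(rep(0L, 3), c(0L, 1L, 2L))
  rownames(d2) <- paste0("a", 1:3)
  expect_identical(unname(maf_filter(d2, 0.1)), c(FALSE, TRUE))
  # all-missing site removed with warning
  d3 <- cbind(c(0L, 1L), c(NA_integer_, NA_integer_))
  rownames(d3) <- c("a", "b")
  expect_warning(keep <- maf_filter(d3, 0.1), "all-missing")
  expect_false(keep[2])
})

test_that("ld_prune removes the later of correlated pairs deterministically", {
  set.seed(21)
  n <- 30
  g <- matrix(rbinom(n * 10, 2, 0.4), n)
  g <- cbind(g, g[, 3])                  # duplicate column appended last
  rownames(g) <- paste0("a", seq_len(n))
  v <- data.frame(chrom = "Chr1", pos = seq_len(ncol(g)) * 10,
                  ref = "A", alt = "G")
  kept <- ld_prune(g, window = 50, step = 10, r2_max = 0.2, variants = v)
  expect_true(3 %in% kept)
  expect_false(ncol(g) %in% kept)        # the later duplicate is dropped
  expect_error(ld_prune(g, window = 1, variants = v), "window")
})

test_that("ld_prune keeps independent sites and matches the brute-force oracle", {
  set.seed(99)
  n <- 80
  # independent sites: all kept
  g_ind <- matrix(rbinom(n * 20, 2, 0.5), n)
  rownames(g_ind) <- paste0("a", seq_len(n))
  v_ind <- data.frame(chrom = "Chr1", pos = seq_len(20) * 5, ref = "A",
                      alt = "G")
  expect_identical(ld_prune(g_ind, variants = v_ind), seq_len(20))

  # 60-site chromosome with planted correlated blocks, small window
  base <- matrix(rbinom(n * 60, 2, 0.5), n)
  for (j in c(5, 17, 33, 52)) {
    noisy <- base[, j]
    flip <- sample(n, 3)
    noisy[flip] <- rbinom(3, 2, 0.5)
    base[, j + 1] <- noisy               # strongly correlated neighbour
  }
  base[sample(length(base), 40)] <- NA   # some missing calls
  rownames(base) <- paste0("a", seq_len(n))
  v <- data.frame(chrom = "Chr1", pos = seq_len(60) * 1000, ref = "A",
                  alt = "G")
  kept <- ld_prune(base, window = 10, step = 3, r2_max = 0.2, variants = v)
  oracle <- ld_prune_oracle(base, v, window = 10, step = 3, r2_max = 0.2)
  expect_identical(kept, oracle)
  # pruning its own output changes nothing
  rerun <- ld_prune(base[, kept], window = 10, step = 3, r2_max = 0.2,
                    variants = v[kept, ])
  expect_identical(kept[rerun], kept)
})

test_that("snp_density computes per-chromosome and pooled densities", {
  v <- data.frame(chrom = c(rep("c1", 100), rep("c2", 100)),
                  pos = 1, ref = "A", alt = "G")
  layout <- c(c1 = 10000, c2 = 90000)
  d <- snp_density(v, layout)
  expect_equal(d$density_per_kb[d$chrom == "c1"], 10.0)
  expect_equal(d$density_per_kb[d$chrom == "overall"], 2.0)
  expect_equal(sum(d$n_snps[d$chrom != "overall"]),
               d$n_snps[d$chrom == "overall"])
  # zero SNPs on a declared contig
  d2 <- snp_density(v[v$chrom == "c1", ], c(c1 = 10000, c2 = 90000))
  expect_equal(d2$density_per_kb[d2$chrom == "c2"], 0)
  expect_error(snp_density(v, c(c1 = 10000)), "missing")
})

test_that("fixture hard-filter plants are each removed and attributed", {
  fx <- cached_fixture()
  res <- hard_filter(fx$panel)
  expect_equal(sum(!res$keep), 7)
  expect_true(all(res$removed_by_rule == 1))
})
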