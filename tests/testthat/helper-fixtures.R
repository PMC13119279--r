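# Shared fixtures, generated once per test run and cached.

.cache <- new.env(parent = emptyenv())

# Small deterministic panel with planted duplicates/outliers/filter
# failures, read back through the VCF round trip.
cached_fixture <- function() {
  if (is.null(.cache$fx)) {
    dir <- file.path(tempdir(), "germcore-fixture")
    .cache$fx <- fixture_suite(dir, seed = 313)
    .cache$panel <- read_vcf(.cache$fx$paths["vcf"])
    .cache$tables <- suppressWarnings(
      read_tables(.cache$fx$paths["pheno"], .cache$fx$paths["popmap"]))
  }
  list(fx = .cache$fx, panel = .cache$panel,
       phenotypes = .cache$tables$phenotypes,
       popmap = .cache$tables$popmap)
}

# Two-population Balding-Nichols panel with near-pure ancestry, built
# directly from simulated frequencies (no admixture blur) so the target
# Fst is the estimand.
bn_two_pop_panel <- function(n_per = 50, m = 5000, fst = 0.05, seed = 1) {
  fr <- simulate_frequencies(m, 2, fst, seed = seed)
  set.seed(seed + 1)
  d1 <- matrix(rbinom(n_per * m, 2, rep(fr$pop_freq[1, ], each = n_per)),
               n_per)
  d2 <- matrix(rbinom(n_per * m, 2, rep(fr$pop_freq[2, ], each = n_per)),
               n_per)
  d <- rbind(d1, d2)
  rownames(d) <- sprintf("S%03d", seq_len(2 * n_per))
  v <- data.frame(chrom = "Chr1", pos = seq_len(m) * 100,
                  ref = "A", alt = "G", stringsAsFactors = FALSE)
  list(panel = geno_panel(d, v, c(Chr1 = m * 100 + 1000)),
       popmap = stats::setNames(rep(c("P1", "P2"), each = n_per),
                                rownames(d)),
       truth = fr)
}

# Hand-written toy VCF (3 samples, mixed record types) for parser tests.
write_toy_vcf <- function(path, extra_records = character()) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=Chr1,length=100000>",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"QD\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "Chr1\t100\t.\tA\tG\t50\tPASS\tQD=20\tGT\t0/0\t0/1\t1/1",
    "Chr1\t200\t.\tC\tT\t60\tPASS\tQD=25\tGT\t1/1\t./.\t0/0",
    extra_records)
  writeLines(lines, path)
  path
}

# Independent brute-force LD pruning oracle: explicit loops, hand-rolled
# r^2 over complete pairs, same window/step/removal rule.
ld_prune_oracle <- function(dosages, variants, window = 50, step = 10,
                            r2_max = 0.2) {
  hand_r2 <- function(x, y) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 2) return(NA_real_)
    sx <- x - mean(x); sy <- y - mean(y)
    den <- sqrt(sum(sx^2) * sum(sy^2))
    if (den == 0) return(NA_real_)
    (sum(sx * sy) / den)^2
  }
  keep <- rep(TRUE, ncol(dosages))
  for (chr in unique(variants$chrom)) {
    idx <- which(variants$chrom == chr)
    m <- length(idx)
    for (start in seq(1, m, by = step)) {
      win <- idx[start:min(start + window - 1, m)]
      for (a in seq_along(win)) {
        for (b in seq_along(win)) {
          if (b <= a) next
          ia <- win[a]; ib <- win[b]
          if (!keep[ia] || !keep[ib]) next
          r2 <- hand_r2(dosages[, ia], dosages[, ib])
          if (!is.na(r2) && r2 > r2_max) keep[ib] <- FALSE
        }
      }
      if (start + window - 1 >= m) break
    }
  }
  which(keep)
}

# Independent transcription of the WC84 two-population component formulas,
# scalar form, for one site.
wc_oracle <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  n1 <- length(g1); n2 <- length(g2); r <- 2
  p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
  h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
  n_bar <- (n1 + n2) / r
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)
  a <- (n_bar / n_c) * (s2 - 1 / (n_bar - 1) *
                          (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4))
  b <- n_bar / (n_bar - 1) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
       (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  c(a = a, b = b, c = h_bar / 2)
}

# Least-squares topology-enumeration NJ oracle (<= 6 taxa): fit branch
# lengths of every unrooted topology, return the minimum-RSS tree.
nj_enumeration_oracle <- function(d) {
  n <- nrow(d)
  stopifnot(n <= 6)
  labs <- rownames(d)
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = labs)
  pairs <- t(combn(n, 2))
  best <- NULL
  best_rss <- Inf
  for (ti in seq_along(trees)) {
    tr <- trees[[ti]]   # [[ restores tip labels from the multiPhylo attr
    ne <- nrow(tr$edge)
    A <- matrix(0, nrow(pairs), ne)
    for (k in seq_len(nrow(pairs))) {
      path <- ape::nodepath(tr, pairs[k, 1], pairs[k, 2])
      for (e in seq_len(length(path) - 1)) {
        hit <- which((tr$edge[, 1] == path[e] & tr$edge[, 2] == path[e + 1]) |
                       (tr$edge[, 1] == path[e + 1] & tr$edge[, 2] == path[e]))
        A[k, hit] <- 1
      }
    }
    y <- d[pairs]
    fit <- qr.solve(A, y)
    rss <- sum((A %*% fit - y)^2)
    if (rss < best_rss) {
      best_rss <- rss
      tr$edge.length <- as.numeric(fit)
      best <- tr
    }
  }
  list(tree = best, rss = best_rss)
}
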