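# Synthetic germplasm panels: Balding-Nichols population structure,
# admixed genotypes, correlated quantitative traits, filterable site
# annotations, and a small deterministic fixture suite for tests.

DEFAULT_POP_SIZES <- c(DDB = 58, DDN = 40, DX = 18, DXB = 80,
                       DXN = 36, DZ = 42, YJZY = 39)

# Chromosome lengths (bp) emulating an 8-chromosome ~450 Mb genome with
# realistic length spread.
DEFAULT_CHROM_LENGTHS <- c(Chr1 = 71500000, Chr2 = 66600000, Chr3 = 52300000,
                           Chr4 = 56700000, Chr5 = 59000000, Chr6 = 47700000,
                           Chr7 = 51500000, Chr8 = 45000000)

#' Simulation configuration
#'
#' Defaults state the panel shape the pipeline targets: 313 accessions from
#' 7 admixed populations on 8 chromosomes with 4 correlated quantitative
#' traits. `n_snps` defaults to a desk-scale 20,000 sites.
#'
#' @param n_accessions total accessions.
#' @param pop_sizes named population sizes; must sum to `n_accessions`.
#' @param n_snps number of candidate SNP sites.
#' @param chrom_lengths named chromosome lengths in bp.
#' @param fst target pairwise differentiation in (0, 0.5).
#' @param alpha admixture concentration: small = near-pure ancestries,
#'   large = even admixture.
#' @param missing_rate missing-call rate in [0, 0.5).
#' @param trait_means,trait_sds base per-trait means / sds (BNMS, NNMS,
#'   SD, PH scale by default).
#' @param trait_cor common between-trait correlation of the noise.
#' @param cluster_shift cluster mean offset in trait-sd units.
#' @param n_trait_clusters phenotype cluster count.
#' @param fail_fraction fraction of sites drawn to fail each hard-filter
#'   rule.
#' @param seed RNG seed.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(n_accessions = 313,
                       pop_sizes = NULL,
                       n_snps = 20000,
                       chrom_lengths = DEFAULT_CHROM_LENGTHS,
                       fst = 0.05,
                       alpha = 0.1,
                       missing_rate = 0.02,
                       trait_means = c(BNMS = 6.8, NNMS = 19.1,
                                       SD = 9.8, PH = 151.3),
                       trait_sds = c(BNMS = 1.5, NNMS = 2.0,
                                     SD = 0.8, PH = 12.2),
                       trait_cor = 0.3,
                       cluster_shift = 1.5,
                       n_trait_clusters = 4,
                       fail_fraction = 0.02,
                       seed = 313) {
  if (is.null(pop_sizes)) {
    if (n_accessions == 313) {
      pop_sizes <- DEFAULT_POP_SIZES
    } else {
      k <- length(DEFAULT_POP_SIZES)
      base <- rep(n_accessions %/% k, k)
      base[seq_len(n_accessions %% k)] <- base[seq_len(n_accessions %% k)] + 1L
      pop_sizes <- stats::setNames(base, names(DEFAULT_POP_SIZES))
    }
  }
  cfg <- list(n_accessions = n_accessions, pop_sizes = pop_sizes,
              n_snps = n_snps, chrom_lengths = unlist(chrom_lengths),
              fst = fst, alpha = alpha, missing_rate = missing_rate,
              trait_means = trait_means, trait_sds = trait_sds,
              trait_cor = trait_cor, cluster_shift = cluster_shift,
              n_trait_clusters = n_trait_clusters,
              fail_fraction = fail_fraction, seed = seed)
  problems <- character()
  if (sum(pop_sizes) != n_accessions) {
    problems <- c(problems, "pop_sizes must sum to n_accessions")
  }
  if (fst <= 0 || fst >= 0.5) problems <- c(problems, "fst must be in (0, 0.5)")
  if (missing_rate < 0 || missing_rate >= 0.5) {
    problems <- c(problems, "missing_rate must be in [0, 0.5)")
  }
  if (any(cfg$chrom_lengths <= 0)) {
    problems <- c(problems, "chromosome lengths must be positive")
  }
  if (length(problems)) stop("invalid sim_config: ",
                             paste(problems, collapse = "; "))
  structure(cfg, class = "sim_config")
}

#' Simulate ancestral and per-population allele frequencies
#'
#' Balding-Nichols model: ancestral frequencies are Uniform(0.05, 0.95) and
#' each population's frequency is Beta(p (1 - F) / F, (1 - p) (1 - F) / F),
#' so E\\[p_pop\\] = p and Var = F p (1 - p).
#'
#' @param n_snps number of sites.
#' @param k_pops number of populations.
#' @param fst differentiation parameter F in (0, 0.5).
#' @param seed RNG seed.
#' @return list with `ancestral` (length n_snps) and `pop_freq`
#'   (k_pops x n_snps).
#' @export
simulate_frequencies <- function(n_snps, k_pops, fst, seed = 313) {
  set.seed(seed)
  p <- runif(n_snps, 0.05, 0.95)
  shape_scale <- (1 - fst) / fst
  pop_freq <- matrix(rbeta(k_pops * n_snps,
                           rep(p, each = k_pops) * shape_scale,
                           rep(1 - p, each = k_pops) * shape_scale),
                     nrow = k_pops)
  list(ancestral = p, pop_freq = pop_freq)
}

# Dirichlet draw via gammas.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Simulate a full germplasm panel
#'
#' Each accession belongs to a population but carries an admixed ancestry
#' vector Q ~ Dirichlet(alpha + 10 e_pop); its per-site allele frequency is
#' `Q %*% pop_freq` and the genotype is Binomial(2, .). Missing calls are
#' masked at the configured rate. Traits are multivariate Gaussian around
#' cluster means (populations grouped into `n_trait_clusters`), truncated
#' at a small positive floor. Site annotations are drawn passing, then a
#' `fail_fraction` of sites per rule are redrawn failing.
#'
#' @param config a [sim_config()].
#' @return list with `panel` (a `geno_panel`), `phenotypes`, `popmap` and
#'   `truth` (ancestral/pop frequencies, Q matrix, labels, trait clusters).
#' @export
simulate_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  k <- length(config$pop_sizes)
  pops <- names(config$pop_sizes)
  m <- config$n_snps
  n <- config$n_accessions

  freqs <- simulate_frequencies(m, k, config$fst, seed = config$seed + 1)
  pop_lab <- rep(pops, config$pop_sizes)
  ids <- sprintf("ACC%03d", seq_len(n))
  popmap <- stats::setNames(pop_lab, ids)

  q <- t(vapply(seq_len(n), function(i) {
    a <- rep(config$alpha, k)
    a[match(pop_lab[i], pops)] <- a[match(pop_lab[i], pops)] + 10
    rdirichlet1(a)
  }, numeric(k)))
  colnames(q) <- pops

  ind_freq <- q %*% freqs$pop_freq            # n x m
  dosages <- matrix(rbinom(n * m, 2L, ind_freq), nrow = n)
  if (config$missing_rate > 0) {
    dosages[runif(n * m) < config$missing_rate] <- NA_integer_
  }
  rownames(dosages) <- ids

  # site coordinates: proportional allocation across chromosomes, sorted
  # uniform positions
  lens <- config$chrom_lengths
  alloc <- round(m * lens / sum(lens))
  alloc[length(alloc)] <- m - sum(alloc[-length(alloc)])
  chrom <- rep(names(lens), alloc)
  pos <- unlist(lapply(seq_along(lens), function(i) {
    sort(sample.int(lens[i], alloc[i]))
  }), use.names = FALSE)

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  # transition-biased alternate alleles (Ts:Tv roughly 2:1)
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  alt <- vapply(ref, function(b) {
    if (runif(1) < 0.68) transition_of[[b]]
    else sample(setdiff(bases, c(b, transition_of[[b]])), 1)
  }, character(1))

  ann <- data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    qual = round(runif(m, 30, 1000), 2),
    QD = round(runif(m, 5, 35), 3),
    MQ = round(runif(m, 50, 60), 3),
    FS = round(runif(m, 0, 20), 3),
    SOR = round(runif(m, 0.3, 2.5), 3),
    MQRankSum = round(rnorm(m, 0, 1), 3),
    ReadPosRankSum = round(rnorm(m, 0, 1), 3),
    stringsAsFactors = FALSE)
  if (config$fail_fraction > 0) {
    nf <- max(1L, round(config$fail_fraction * m))
    pick <- function() sample.int(m, nf)
    ann$qual[pick()] <- round(runif(nf, 2, 19.9), 2)
    ann$QD[pick()] <- round(runif(nf, 0.1, 1.9), 3)
    ann$MQ[pick()] <- round(runif(nf, 20, 39.9), 3)
    ann$FS[pick()] <- round(runif(nf, 60.1, 120), 3)
    ann$SOR[pick()] <- round(runif(nf, 4.1, 8), 3)
    ann$MQRankSum[pick()] <- round(runif(nf, -20, -12.6), 3)
    ann$ReadPosRankSum[pick()] <- round(runif(nf, -15, -8.1), 3)
  }

  panel <- geno_panel(dosages, ann, lens)

  # traits: populations -> clusters round-robin; cluster mean offsets on a
  # shared correlation structure
  n_cl <- config$n_trait_clusters
  cluster_of_pop <- stats::setNames(((seq_len(k) - 1L) %% n_cl) + 1L, pops)
  cl <- cluster_of_pop[pop_lab]
  t_names <- names(config$trait_means)
  p_tr <- length(t_names)
  sigma <- config$trait_cor + diag(1 - config$trait_cor, p_tr)
  ch <- chol(sigma)
  offsets <- matrix(rnorm(n_cl * p_tr), n_cl, p_tr) * config$cluster_shift
  z <- matrix(rnorm(n * p_tr), n, p_tr) %*% ch
  traits <- sweep(sweep(z + offsets[cl, ], 2, config$trait_sds, "*"),
                  2, config$trait_means, "+")
  traits <- pmax(traits, 0.1)
  phen <- as.data.frame(traits)
  names(phen) <- t_names
  rownames(phen) <- ids

  list(panel = panel, phenotypes = phen, popmap = popmap,
       truth = list(ancestral = freqs$ancestral, pop_freq = freqs$pop_freq,
                    Q = q, labels = popmap, trait_clusters =
                      stats::setNames(as.integer(cl), ids)))
}

#' Write a simulated panel to standard-format files
#'
#' Emits `genotypes.vcf`, `phenotypes.csv`, `popmap.csv`, `layout.json` and
#' `truth.json` under `outdir`.
#'
#' @param sim result of [simulate_panel()].
#' @param outdir output directory (created if absent).
#' @return named vector of written paths, invisibly.
#' @export
write_panel <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(vcf = file.path(outdir, "genotypes.vcf"),
             pheno = file.path(outdir, "phenotypes.csv"),
             popmap = file.path(outdir, "popmap.csv"),
             layout = file.path(outdir, "layout.json"),
             truth = file.path(outdir, "truth.json"))
  write_vcf(sim$panel, paths["vcf"])
  ph <- data.frame(accession = rownames(sim$phenotypes),
                   round(sim$phenotypes, 4), check.names = FALSE)
  utils::write.csv(ph, paths["pheno"], row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(accession = names(sim$popmap),
                              population = unname(sim$popmap)),
                   paths["popmap"], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(as.list(sim$panel$layout), paths["layout"],
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(labels = as.list(sim$truth$labels),
                            trait_clusters = as.list(sim$truth$trait_clusters)),
                       paths["truth"], auto_unbox = TRUE)
  invisible(paths)
}

#' Deterministic small fixture suite
#'
#' Writes a tiny panel (24 accessions, ~600 SNPs, 2 chromosomes) with two
#' planted exact-duplicate accession pairs, two planted phenotype outliers,
#' and one site engineered to fail each hard-filter rule exactly once.
#' Byte-identical across runs at the same seed.
#'
#' @param outdir output directory.
#' @param seed RNG seed (default 313).
#' @return list with the written `paths` and the planted `truth`
#'   (duplicate pairs, outlier IDs, per-rule failing site positions).
#' @export
fixture_suite <- function(outdir, seed = 313) {
  cfg <- sim_config(
    n_accessions = 24,
    pop_sizes = c(DDB = 6, DDN = 4, DX = 2, DXB = 4, DXN = 3, DZ = 3,
                  YJZY = 2),
    n_snps = 600,
    chrom_lengths = c(Chr1 = 1200000, Chr2 = 900000),
    fst = 0.08, alpha = 0.1, missing_rate = 0.02,
    fail_fraction = 0, seed = seed)
  sim <- simulate_panel(cfg)
  set.seed(seed + 99)

  # planted duplicates: copy genotypes (and traits) of donors onto targets
  dup_pairs <- list(c("ACC001", "ACC013"), c("ACC007", "ACC019"))
  for (pr in dup_pairs) {
    sim$panel$dosages[pr[2], ] <- sim$panel$dosages[pr[1], ]
    sim$phenotypes[pr[2], ] <- sim$phenotypes[pr[1], ]
  }
  # planted phenotype outliers: push two accessions to the trait extremes
  outliers <- c("ACC005", "ACC023")
  sim$phenotypes[outliers[1], ] <- apply(sim$phenotypes, 2, max) * 1.4
  sim$phenotypes[outliers[2], ] <- apply(sim$phenotypes, 2, min) * 0.6

  # one site failing each hard-filter rule exactly once
  v <- sim$panel$variants
  fail_sites <- stats::setNames(seq(10, by = 10, length.out = 7),
                                c("qual", "QD", "MQ", "FS", "SOR",
                                  "MQRankSum", "ReadPosRankSum"))
  v$qual[fail_sites["qual"]] <- 12.5
  v$QD[fail_sites["QD"]] <- 1.5
  v$MQ[fail_sites["MQ"]] <- 31.0
  v$FS[fail_sites["FS"]] <- 75.0
  v$SOR[fail_sites["SOR"]] <- 5.2
  v$MQRankSum[fail_sites["MQRankSum"]] <- -13.4
  v$ReadPosRankSum[fail_sites["ReadPosRankSum"]] <- -9.6
  sim$panel$variants <- v

  paths <- write_panel(sim, outdir)
  list(paths = paths,
       truth = c(sim$truth,
                 list(duplicate_pairs = dup_pairs, outliers = outliers,
                      fail_sites = fail_sites)))
}
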