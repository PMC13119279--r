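# Genetic-diversity parameters (Ho, HE, pi, MAF, FIS, PIC) per population
# and descriptive/diversity statistics for quantitative traits.

#' Per-site allele statistics
#'
#' @param dosages dosage vector for one site (0/1/2/NA).
#' @return list with `p_alt` (ALT allele frequency over called genotypes),
#'   `n_called` (diploid calls) and `ho_site` (observed heterozygote
#'   proportion).
#' @export
allele_stats <- function(dosages) {
  called <- dosages[!is.na(dosages)]
  n <- length(called)
  if (n == 0L) stop("all calls missing at site")
  list(p_alt = sum(called) / (2 * n), n_called = n,
       ho_site = mean(called == 1L))
}

#' Expected heterozygosity at a biallelic site
#'
#' `HE = 2 p (1 - p)`, no finite-sample correction.
#'
#' @param p allele frequency (vectorised).
#' @return expected heterozygosity in [0, 0.5].
#' @export
expected_het <- function(p) 2 * p * (1 - p)

#' Polymorphism information content (biallelic, Botstein form)
#'
#' `PIC = 1 - (p^2 + q^2) - 2 p^2 q^2` with `q = 1 - p`.
#'
#' @param p allele frequency (vectorised).
#' @return PIC in [0, 0.375].
#' @export
pic_biallelic <- function(p) {
  q <- 1 - p
  1 - (p^2 + q^2) - 2 * p^2 * q^2
}

#' Inbreeding coefficient from mean heterozygosities
#'
#' Ratio-of-means form `FIS = 1 - Ho / HE`, the arithmetic implied by
#' standard germplasm diversity tables.
#'
#' @param ho_mean mean observed heterozygosity.
#' @param he_mean mean expected heterozygosity (> 0).
#' @return FIS; `NA` with a warning when `he_mean` is 0.
#' @export
fis <- function(ho_mean, he_mean) {
  if (he_mean == 0) {
    warning("HE is zero: FIS undefined")
    return(NA_real_)
  }
  1 - ho_mean / he_mean
}

#' Nucleotide diversity
#'
#' Per-site unbiased heterozygosity `(2n / (2n - 1)) * 2 p (1 - p)` summed
#' over polymorphic sites and divided by the total genome length `L`
#' (monomorphic genome positions contribute zero but stay in the
#' denominator).
#'
#' @param dosages dosage matrix (accessions x sites) or a `geno_panel`.
#' @param L total genome length in bp (> 0). Defaults to the panel layout sum.
#' @return pi per bp.
#' @export
nucleotide_diversity <- function(dosages, L = NULL) {
  if (inherits(dosages, "geno_panel")) {
    if (is.null(L)) L <- sum(dosages$layout)
    dosages <- dosages$dosages
  }
  if (is.null(L) || L <= 0) stop("total genome length L must be positive")
  n <- colSums(!is.na(dosages))
  p <- site_alt_freq(dosages)
  ok <- n > 0L & !is.na(p)
  h <- (2 * n[ok] / (2 * n[ok] - 1)) * expected_het(p[ok])
  sum(h) / L
}

# Per-site summary across a dosage matrix: p, n_called, ho.
site_summary <- function(dosages) {
  n <- colSums(!is.na(dosages))
  p <- site_alt_freq(dosages)
  ho <- colSums(dosages == 1L, na.rm = TRUE) / n
  ho[n == 0L] <- NA_real_
  list(p = p, n = n, ho = ho)
}

# Diversity row over one set of accessions; means taken over all sites with
# at least one call, num_snps over sites polymorphic within the set.
diversity_row <- function(dosages, L) {
  s <- site_summary(dosages)
  ok <- !is.na(s$p)
  p <- s$p[ok]
  he <- expected_het(p)
  ho_mean <- mean(s$ho[ok])
  he_mean <- mean(he)
  data.frame(num_snps = sum(p > 0 & p < 1),
             He = he_mean, Ho = ho_mean,
             pi = nucleotide_diversity(dosages, L),
             maf = mean(pmin(p, 1 - p)),
             fis = fis(ho_mean, he_mean),
             pic = mean(pic_biallelic(p)))
}

#' Per-population genetic diversity table
#'
#' One row per population (populations with fewer than two members are
#' excluded with a warning) plus a pooled `ALL` row equal to the unweighted
#' arithmetic mean of the per-population rows. `num_snps` counts sites
#' polymorphic within the population; the remaining statistics average over
#' all sites with data.
#'
#' @param panel a `geno_panel` (or dosage matrix).
#' @param popmap named character vector accession -> population code.
#' @param L total genome length in bp; defaults to the panel layout sum.
#' @return data.frame with columns population, num_snps, He, Ho, pi, maf,
#'   fis, pic.
#' @export
population_diversity <- function(panel, popmap, L = NULL) {
  dosages <- if (inherits(panel, "geno_panel")) panel$dosages else panel
  if (inherits(panel, "geno_panel") && is.null(L)) L <- sum(panel$layout)
  ids <- rownames(dosages)
  unmapped <- setdiff(ids, names(popmap))
  if (length(unmapped)) {
    stop("accessions missing from population map: ",
         paste(unmapped, collapse = ", "))
  }
  pops <- sort(unique(popmap[ids]))
  rows <- list()
  for (pop in pops) {
    members <- ids[popmap[ids] == pop]
    if (length(members) < 2L) {
      warning("population ", pop, " has fewer than 2 accessions; excluded")
      next
    }
    rows[[pop]] <- cbind(population = pop,
                         diversity_row(dosages[members, , drop = FALSE], L))
  }
  if (!length(rows)) stop("no population with >= 2 accessions")
  tab <- do.call(rbind, rows)
  all_row <- cbind(population = "ALL",
                   as.data.frame(lapply(tab[-1], mean)))
  out <- rbind(tab, all_row)
  rownames(out) <- NULL
  out
}

#' Whole-panel diversity row
#'
#' Convenience wrapper returning the single diversity row (num_snps, He, Ho,
#' pi, maf, fis, pic) of a panel or accession subset.
#'
#' @param panel a `geno_panel` or dosage matrix.
#' @param L total genome length; defaults to panel layout sum.
#' @return one-row data.frame.
#' @export
panel_diversity <- function(panel, L = NULL) {
  dosages <- if (inherits(panel, "geno_panel")) panel$dosages else panel
  if (inherits(panel, "geno_panel") && is.null(L)) L <- sum(panel$layout)
  diversity_row(dosages, L)
}

#' Descriptive statistics for a quantitative trait
#'
#' @param values numeric trait values (>= 2).
#' @param name optional trait name.
#' @param n_classes classes for the Shannon index.
#' @return one-row data.frame with trait, mean, max, min, range, sd
#'   (sample, n-1), cv_percent (100 sd / mean) and shannon_h.
#' @export
trait_descriptives <- function(values, name = "trait", n_classes = 10) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least two values")
  m <- mean(values)
  s <- sd(values)
  cv <- if (m == 0) {
    warning("mean is zero: CV undefined")
    NA_real_
  } else 100 * s / m
  data.frame(trait = name, mean = m, max = max(values), min = min(values),
             range = max(values) - min(values), sd = s, cv_percent = cv,
             shannon_h = shannon_index(values, n_classes))
}

#' Shannon diversity index of a quantitative trait
#'
#' Values are binned into `n_classes` classes spanning mean +/- 2 sd in
#' half-sd steps (class 1: below mean - 2 sd; top class: at or above
#' mean + 2 sd), and `H' = -sum p_i ln p_i` is computed over occupied
#' classes. Bounded above by `ln(n_classes)`.
#'
#' @param values numeric vector.
#' @param n_classes number of classes (default 10).
#' @return H' in nats; 0 when the sd is zero.
#' @export
shannon_index <- function(values, n_classes = 10) {
  values <- values[!is.na(values)]
  m <- mean(values)
  s <- sd(values)
  if (s == 0 || length(values) < 2L) return(0)
  breaks <- m + s * seq(-2, 2, length.out = n_classes - 1)
  cls <- findInterval(values, breaks, left.open = FALSE) + 1L
  p <- table(cls) / length(cls)
  -sum(p * log(p))
}

#' Trait summary table
#'
#' [trait_descriptives()] applied to every column of a phenotype table.
#'
#' @param phenotypes data.frame of numeric trait columns.
#' @param n_classes Shannon classes.
#' @return data.frame, one row per trait.
#' @export
trait_summary_table <- function(phenotypes, n_classes = 10) {
  out <- do.call(rbind, lapply(names(phenotypes), function(tr) {
    trait_descriptives(phenotypes[[tr]], tr, n_classes)
  }))
  rownames(out) <- NULL
  out
}
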