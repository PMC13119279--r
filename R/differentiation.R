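# Pairwise population differentiation: Weir-Cockerham (1984) two-population
# Fst in non-overlapping genomic windows, and island-model gene flow.

# Vectorised WC84 variance components for two populations at many sites.
# Inputs are dosage matrices (accessions x sites). Sites need >= 2 called
# diploids per population; others return NA components. Sites monomorphic
# across both populations get components (0, 0, 0).
wc_components_matrix <- function(d1, d2) {
  n1 <- colSums(!is.na(d1))
  n2 <- colSums(!is.na(d2))
  p1 <- site_alt_freq(d1)
  p2 <- site_alt_freq(d2)
  h1 <- colSums(d1 == 1L, na.rm = TRUE) / n1
  h2 <- colSums(d2 == 1L, na.rm = TRUE) / n2

  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2

  usable <- n1 >= 2L & n2 >= 2L
  mono <- usable & (pbar == 0 | pbar == 1)
  a[mono] <- 0; b[mono] <- 0; c[mono] <- 0
  a[!usable] <- NA_real_; b[!usable] <- NA_real_; c[!usable] <- NA_real_
  list(a = a, b = b, c = c)
}

#' Weir-Cockerham variance components at one site
#'
#' Two-population WC84 estimator components: `a` (among populations), `b`
#' (among individuals within populations) and `c` (within individuals).
#' The per-site Fst estimate is `a / (a + b + c)`; small negative values are
#' a signature of this estimator and are preserved.
#'
#' @param dosages_pop1,dosages_pop2 dosage vectors (0/1/2/NA) of the two
#'   populations at the site; each needs >= 2 called diploids.
#' @return named numeric `c(a, b, c)`; all zero when the site is
#'   monomorphic across both populations.
#' @export
wc_site_components <- function(dosages_pop1, dosages_pop2) {
  cmp <- wc_components_matrix(matrix(dosages_pop1, ncol = 1),
                              matrix(dosages_pop2, ncol = 1))
  if (is.na(cmp$a)) stop("need >= 2 called diploids in each population")
  c(a = cmp$a, b = cmp$b, c = cmp$c)
}

#' Windowed Weir-Cockerham Fst for one population pair
#'
#' Per non-overlapping window of `window_bp` base pairs, Fst is the ratio of
#' summed components `sum(a) / sum(a + b + c)` over the window's sites.
#' Genome-wide values are reported both as the weighted ratio of sums over
#' all sites (window-free) and as the unweighted mean of window values;
#' empty windows are omitted.
#'
#' @param panel a `geno_panel`.
#' @param popmap named vector accession -> population code.
#' @param pair character vector of two population codes.
#' @param window_bp window size in bp (default 500 kb).
#' @return list with `pair`, `windows` (data.frame chrom/start/end/n_snps/
#'   fst), `genome_wide_weighted`, `genome_wide_mean` and `nm` (from the
#'   weighted value).
#' @export
windowed_fst <- function(panel, popmap, pair, window_bp = 500000) {
  stopifnot(length(pair) == 2L)
  ids <- rownames(panel$dosages)
  m1 <- ids[popmap[ids] == pair[1]]
  m2 <- ids[popmap[ids] == pair[2]]
  if (length(m1) < 2L || length(m2) < 2L) {
    stop("both populations need >= 2 accessions")
  }
  cmp <- wc_components_matrix(panel$dosages[m1, , drop = FALSE],
                              panel$dosages[m2, , drop = FALSE])
  ok <- !is.na(cmp$a)
  a <- cmp$a[ok]
  abc <- cmp$a[ok] + cmp$b[ok] + cmp$c[ok]
  v <- panel$variants[ok, , drop = FALSE]

  win_id <- paste(v$chrom, (v$pos - 1) %/% window_bp, sep = ":")
  agg <- data.frame(chrom = tapply(v$chrom, win_id, `[`, 1),
                    start = as.numeric(tapply(v$pos, win_id, function(p)
                      ((p[1] - 1) %/% window_bp) * window_bp + 1)),
                    n_snps = as.integer(tapply(a, win_id, length)),
                    sum_a = as.numeric(tapply(a, win_id, sum)),
                    sum_abc = as.numeric(tapply(abc, win_id, sum)))
  agg$end <- agg$start + window_bp - 1
  agg$fst <- ifelse(agg$sum_abc > 0, agg$sum_a / agg$sum_abc, NA_real_)
  agg <- agg[order(agg$chrom, agg$start),
             c("chrom", "start", "end", "n_snps", "fst")]
  rownames(agg) <- NULL

  weighted <- if (sum(abc) > 0) sum(a) / sum(abc) else NA_real_
  list(pair = pair, windows = agg,
       genome_wide_weighted = weighted,
       genome_wide_mean = mean(agg$fst, na.rm = TRUE),
       nm = nm_from_fst(weighted))
}

#' Gene flow from Fst
#'
#' Island-model conversion `Nm = (1 - Fst) / (4 Fst)`, applied verbatim to
#' negative Fst as well (the resulting large negative Nm is not
#' interpretable as a migrant count and is flagged downstream).
#'
#' @param fst Fst estimate (vectorised); zero gives `NA` with a warning.
#' @return effective number of migrants per generation.
#' @export
nm_from_fst <- function(fst) {
  out <- ifelse(fst == 0, NA_real_, (1 - fst) / (4 * fst))
  if (any(!is.na(fst) & fst == 0)) warning("Nm undefined at Fst = 0")
  out
}

#' Pairwise Fst/Nm matrix across populations
#'
#' All C(k, 2) population pairs; the returned matrix carries genome-wide
#' weighted Fst below the diagonal and Nm above it, mirroring the standard
#' differentiation-table layout.
#'
#' @param panel a `geno_panel`.
#' @param popmap named vector accession -> population code.
#' @param window_bp window size passed to [windowed_fst()].
#' @return list with `matrix` (k x k, Fst lower / Nm upper triangle) and
#'   `pairs` (data.frame pop1/pop2/fst_weighted/fst_mean/nm).
#' @export
pairwise_matrix <- function(panel, popmap, window_bp = 500000) {
  ids <- rownames(panel$dosages)
  pops <- sort(unique(popmap[ids]))
  k <- length(pops)
  if (k < 2L) stop("need at least two populations")
  mat <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  rows <- list()
  for (i in seq_len(k - 1L)) {
    for (j in seq(i + 1L, k)) {
      res <- windowed_fst(panel, popmap, c(pops[i], pops[j]), window_bp)
      mat[j, i] <- res$genome_wide_weighted
      mat[i, j] <- res$nm
      rows[[length(rows) + 1L]] <- data.frame(
        pop1 = pops[i], pop2 = pops[j],
        fst_weighted = res$genome_wide_weighted,
        fst_mean = res$genome_wide_mean, nm = res$nm,
        interpretable = !is.na(res$genome_wide_weighted) &&
          res$genome_wide_weighted > 0)
    }
  }
  list(matrix = mat, pairs = do.call(rbind, rows))
}
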