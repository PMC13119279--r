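# Site-level quality filtering, MAF filtering, LD pruning and SNP accounting.

#' Hard-filter thresholds
#'
#' GATK-style site thresholds. A site fails when QUAL < qual_min, QD < qd_min,
#' MQ < mq_min, FS > fs_max, SOR > sor_max, MQRankSum < mqranksum_min or
#' ReadPosRankSum < readpos_min; failures combine by OR. An absent annotation
#' never triggers removal. `mqranksum_min` defaults to the conventional
#' -12.5.
#'
#' @param qual_min,qd_min,mq_min,fs_max,sor_max,mqranksum_min,readpos_min
#'   per-rule cutoffs.
#' @param maf_min minimum minor allele frequency (inclusive), in [0, 0.5].
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(qual_min = 20, qd_min = 2.0, mq_min = 40.0,
                              fs_max = 60.0, sor_max = 4.0,
                              mqranksum_min = -12.5, readpos_min = -8.0,
                              maf_min = 0.1) {
  th <- list(qual_min = qual_min, qd_min = qd_min, mq_min = mq_min,
             fs_max = fs_max, sor_max = sor_max,
             mqranksum_min = mqranksum_min, readpos_min = readpos_min,
             maf_min = maf_min)
  if (!all(vapply(th, is.finite, logical(1)))) stop("thresholds must be finite")
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must lie in [0, 0.5]")
  structure(th, class = "filter_thresholds")
}

#' Classify a substitution as transition or transversion
#'
#' A<->G and C<->T are transitions; every other base pair is a transversion.
#' Vectorised over `ref`/`alt`.
#'
#' @param ref,alt single bases in A/C/G/T, `ref != alt`.
#' @return character vector, "transition" or "transversion".
#' @export
classify_substitution <- function(ref, alt) {
  if (any(!(ref %in% c("A", "C", "G", "T")) |
          !(alt %in% c("A", "C", "G", "T")))) {
    stop("ref and alt must be single A/C/G/T bases")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  purine <- c("A", "G")
  ifelse((ref %in% purine) == (alt %in% purine), "transition", "transversion")
}

#' Transition/transversion accounting
#'
#' Counts transitions and transversions, their ratio, and the percentage of
#' sites attributable to each unordered substitution pair (A/G, C/T, A/C,
#' A/T, C/G, G/T).
#'
#' @param variants data.frame with `ref` and `alt` columns (or a `geno_panel`).
#' @return list with `transition_count`, `transversion_count`, `ratio` and
#'   `type_percent` (named numeric, sums to 100).
#' @export
ts_tv_summary <- function(variants) {
  if (inherits(variants, "geno_panel")) variants <- variants$variants
  if (nrow(variants) < 1L) stop("need at least one SNP")
  cls <- classify_substitution(variants$ref, variants$alt)
  ts <- sum(cls == "transition")
  tv <- sum(cls == "transversion")
  ratio <- if (tv == 0L) {
    warning("no transversions: Ts/Tv ratio is infinite")
    Inf
  } else ts / tv
  pair <- paste(pmin(variants$ref, variants$alt),
                pmax(variants$ref, variants$alt), sep = "/")
  type_percent <- 100 * table(pair) / length(pair)
  list(transition_count = ts, transversion_count = tv, ratio = ratio,
       type_percent = c(type_percent))
}

#' Apply hard filters to a variant table
#'
#' Removal is the OR of per-rule failures; a site missing an annotation
#' passes that sub-filter. Returns the keep mask and, because one site can
#' fail several rules, per-rule removal counts that may exceed the total
#' number of removed sites.
#'
#' @param variants data.frame of site records (or a `geno_panel`).
#' @param thresholds a [filter_thresholds()] object.
#' @return list with logical `keep` and named integer `removed_by_rule`.
#' @export
hard_filter <- function(variants, thresholds = filter_thresholds()) {
  if (inherits(variants, "geno_panel")) variants <- variants$variants
  fail <- cbind(
    qual = !is.na(variants$qual) & variants$qual < thresholds$qual_min,
    QD = !is.na(variants$QD) & variants$QD < thresholds$qd_min,
    MQ = !is.na(variants$MQ) & variants$MQ < thresholds$mq_min,
    FS = !is.na(variants$FS) & variants$FS > thresholds$fs_max,
    SOR = !is.na(variants$SOR) & variants$SOR > thresholds$sor_max,
    MQRankSum = !is.na(variants$MQRankSum) &
      variants$MQRankSum < thresholds$mqranksum_min,
    ReadPosRankSum = !is.na(variants$ReadPosRankSum) &
      variants$ReadPosRankSum < thresholds$readpos_min)
  list(keep = rowSums(fail) == 0L,
       removed_by_rule = colSums(fail))
}

# Per-site ALT allele frequency over non-missing calls; NA where no calls.
site_alt_freq <- function(dosages) {
  n <- colSums(!is.na(dosages))
  p <- colSums(dosages, na.rm = TRUE) / (2 * n)
  p[n == 0L] <- NA_real_
  p
}

#' Minor-allele-frequency filter
#'
#' Keeps sites whose minor allele frequency over non-missing calls is at
#' least `maf_min` (inclusive); monomorphic and all-missing sites are
#' removed.
#'
#' @param dosages dosage matrix (or a `geno_panel`).
#' @param maf_min inclusive MAF cutoff.
#' @return logical keep mask over sites.
#' @export
maf_filter <- function(dosages, maf_min = 0.1) {
  if (inherits(dosages, "geno_panel")) dosages <- dosages$dosages
  p <- site_alt_freq(dosages)
  if (anyNA(p)) warning(sum(is.na(p)), " all-missing site(s) removed")
  maf <- pmin(p, 1 - p)
  !is.na(maf) & maf >= maf_min & maf > 0
}

#' LD pruning (PLINK --indep-pairwise style)
#'
#' Sliding windows of `window` SNPs advancing by `step`, per chromosome in
#' (chrom, pos) order. Within a window, pairs are scanned in index order;
#' when the squared Pearson correlation of dosages (pairwise-complete
#' observations) exceeds `r2_max`, the later site of the pair is removed.
#' Deterministic; already-removed sites are not revisited.
#'
#' @param panel a `geno_panel` (or a dosage matrix with `variants` supplied).
#' @param window window size in SNPs (>= 2).
#' @param step window step in SNPs.
#' @param r2_max maximum allowed r^2.
#' @param variants variant table when `panel` is a bare matrix.
#' @return integer vector of kept site indices (relative to input order).
#' @export
ld_prune <- function(panel, window = 50, step = 10, r2_max = 0.2,
                     variants = NULL) {
  if (inherits(panel, "geno_panel")) {
    dosages <- panel$dosages
    variants <- panel$variants
  } else dosages <- panel
  if (window < 2) stop("window must cover at least 2 SNPs")
  r <- rle(variants$chrom)
  if (anyDuplicated(r$values)) {
    stop("sites must be grouped by chromosome")
  }
  by_pos <- tapply(variants$pos, variants$chrom,
                   function(p) !is.unsorted(p))
  if (!all(by_pos)) stop("sites must be ordered by position within chromosome")
  keep <- rep(TRUE, ncol(dosages))
  for (chr in unique(variants$chrom)) {
    idx <- which(variants$chrom == chr)
    m <- length(idx)
    if (m < 2L) next
    for (start in seq(1L, m, by = step)) {
      win <- idx[start:min(start + window - 1L, m)]
      live <- win[keep[win]]
      if (length(live) < 2L) next
      r2 <- suppressWarnings(
        cor(dosages[, live, drop = FALSE],
            use = "pairwise.complete.obs"))^2
      for (a in seq_len(length(live) - 1L)) {
        if (!keep[live[a]]) next
        for (b in seq(a + 1L, length(live))) {
          if (!keep[live[b]]) next
          if (!is.na(r2[a, b]) && r2[a, b] > r2_max) keep[live[b]] <- FALSE
        }
      }
      if (start + window - 1L >= m) break
    }
  }
  which(keep)
}

#' Per-chromosome SNP counts and densities
#'
#' @param variants variant table (or a `geno_panel`).
#' @param layout named chromosome lengths in bp; must cover every
#'   chromosome present.
#' @return data.frame with one row per chromosome plus an `overall` row;
#'   `density_per_kb` = count / (length / 1000).
#' @export
snp_density <- function(variants, layout) {
  if (inherits(variants, "geno_panel")) {
    if (is.null(layout)) layout <- variants$layout
    variants <- variants$variants
  }
  layout <- unlist(layout)
  chroms <- unique(variants$chrom)
  absent <- setdiff(chroms, names(layout))
  if (length(absent)) {
    stop("chromosome(s) missing from layout: ", paste(absent, collapse = ", "))
  }
  counts <- table(factor(variants$chrom, levels = names(layout)))
  df <- data.frame(chrom = names(layout),
                   n_snps = as.integer(counts),
                   length_bp = as.numeric(layout),
                   stringsAsFactors = FALSE)
  df$density_per_kb <- df$n_snps / (df$length_bp / 1000)
  rbind(df, data.frame(chrom = "overall", n_snps = sum(df$n_snps),
                       length_bp = sum(df$length_bp),
                       density_per_kb = sum(df$n_snps) /
                         (sum(df$length_bp) / 1000)))
}
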