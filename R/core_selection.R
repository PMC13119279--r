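# Core-collection construction: A-NE subset optimisation on genotype or
# phenotype distances, gradient-fraction search, MD/VD/CR/VR evaluation,
# core merging and ANOVA/Tukey validation.

#' Core subset size at a sampling fraction
#'
#' `floor(n * fraction)`, minimum 1 (reproduces 93 at 30% and 15 at 5% of
#' a 313-accession panel).
#'
#' @param n panel size (>= 1).
#' @param fraction sampling fraction in (0, 1].
#' @return integer subset size.
#' @export
core_fraction_size <- function(n, fraction) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  if (n < 1) stop("n must be >= 1")
  max(1L, as.integer(floor(n * fraction)))
}

#' Average entry-to-nearest-entry objective
#'
#' Mean, over selected entries, of the distance to the nearest *other*
#' selected entry. Maximising A-NE spreads the core across diversity space
#' and penalises redundant (near-duplicate) selections.
#'
#' @param distance symmetric distance matrix.
#' @param subset indices (or labels) of the selected entries, >= 2.
#' @return the A-NE value.
#' @export
ane_objective <- function(distance, subset) {
  if (length(subset) < 2L) stop("subset must contain at least two entries")
  d <- as.matrix(distance)[subset, subset, drop = FALSE]
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

# Steepest-ascent pass: repeatedly apply the best single swap until no swap
# improves the objective. O(k * (n - k)) objective evaluations per step.
steepest_ascent <- function(d, subset, tol = 1e-12) {
  n <- nrow(d)
  obj <- ane_objective(d, subset)
  repeat {
    outside <- setdiff(seq_len(n), subset)
    best <- list(obj = obj)
    for (s_i in seq_along(subset)) {
      cand <- subset
      for (u in outside) {
        cand[s_i] <- u
        val <- ane_objective(d, cand)
        if (val > best$obj + tol) best <- list(obj = val, subset = cand)
      }
      cand[s_i] <- subset[s_i]
    }
    if (is.null(best$subset)) break
    subset <- best$subset
    obj <- best$obj
  }
  list(subset = sort(subset), objective = obj)
}

#' Optimise a core subset by A-NE maximisation
#'
#' Random-restart steepest-ascent swap search: from each random start the
#' best single swap (selected vs unselected entry) is applied until the
#' subset is locally optimal; the best local optimum across restarts is
#' returned. Deterministic given `seed`. Stops early after `patience`
#' consecutive restarts without improvement.
#'
#' @param distance symmetric distance matrix.
#' @param size subset size (2 <= size <= n).
#' @param seed RNG seed (default 313).
#' @param restarts maximum random restarts.
#' @param patience restarts without improvement before stopping.
#' @return list with `subset` (sorted indices), `ids` (labels when the
#'   matrix has dimnames) and `objective`.
#' @export
optimize_subset <- function(distance, size, seed = 313, restarts = 10,
                            patience = 3) {
  d <- as.matrix(distance)
  n <- nrow(d)
  if (size > n) stop("size exceeds panel size")
  if (size < 2L) stop("size must be >= 2")
  if (size == n) {
    return(list(subset = seq_len(n), ids = rownames(d),
                objective = ane_objective(d, seq_len(n))))
  }
  set.seed(seed)
  best <- NULL
  stale <- 0L
  for (r in seq_len(restarts)) {
    start <- sample.int(n, size)
    res <- steepest_ascent(d, start)
    if (is.null(best) || res$objective > best$objective + 1e-12) {
      best <- res
      stale <- 0L
    } else stale <- stale + 1L
    if (stale >= patience) break
  }
  list(subset = best$subset, ids = rownames(d)[best$subset],
       objective = best$objective)
}

#' Gradient-fraction genotype core search
#'
#' For each sampling fraction, optimises an A-NE core on the Modified
#' Rogers distance and computes the subset's diversity row (num_snps, He,
#' Ho, pi, maf, fis, pic); a 100% reference row is appended. The chosen
#' fraction minimises the mean relative absolute difference of (Ho, He,
#' PIC) against the full panel, ties broken toward larger pi.
#'
#' @param panel a `geno_panel`.
#' @param fractions sampling fractions.
#' @param seed RNG seed.
#' @param restarts restarts per fraction for [optimize_subset()].
#' @return list with `table` (per-fraction diversity rows), `subsets`
#'   (accession IDs per fraction), `chosen_fraction` and `core_ids`.
#' @export
gradient_core_search <- function(panel, fractions = c(0.05, 0.10, 0.15,
                                                      0.20, 0.25, 0.30),
                                 seed = 313, restarts = 5) {
  if (!length(fractions)) stop("fractions must be non-empty")
  d <- modified_rogers_distance(panel)
  n <- nrow(panel$dosages)
  full_row <- panel_diversity(panel)
  rows <- list()
  subsets <- list()
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    size <- core_fraction_size(n, f)
    if (size < 2L) size <- 2L
    res <- if (size >= n) {
      list(subset = seq_len(n), ids = rownames(d),
           objective = ane_objective(d, seq_len(n)))
    } else {
      optimize_subset(d, size, seed = seed + i, restarts = restarts)
    }
    sub_panel <- subset_panel(panel, accessions = res$subset)
    rows[[i]] <- cbind(fraction = f, size = length(res$subset),
                       panel_diversity(sub_panel), ane = res$objective)
    subsets[[as.character(f)]] <- res$ids
  }
  tab <- do.call(rbind, rows)
  if (!any(fractions == 1)) {
    tab <- rbind(tab, cbind(fraction = 1.0, size = n, full_row,
                            ane = ane_objective(d, seq_len(n))))
  }
  rownames(tab) <- NULL

  cand <- tab[seq_along(fractions), , drop = FALSE]
  rel <- function(col) abs(cand[[col]] - full_row[[col]]) /
    abs(full_row[[col]])
  score <- (rel("Ho") + rel("He") + rel("pic")) / 3
  best <- which(score == min(score))
  if (length(best) > 1L) best <- best[which.max(cand$pi[best])]
  chosen <- cand$fraction[best]
  list(table = tab, subsets = subsets, chosen_fraction = chosen,
       core_ids = subsets[[as.character(chosen)]])
}

#' Evaluate a phenotype core against the full collection
#'
#' Two conventions for MD/VD:
#' * `significance-count`: MD% (VD%) is the percentage of traits whose
#'   core-vs-full two-sample t test (variance-ratio F test) is significant
#'   at 0.05 — multiples of 100 / n_traits.
#' * `relative-magnitude`: MD% (VD%) is the mean over traits of
#'   `100 |mean_core - mean_full| / mean_full` (same with variances).
#' * `mixed` (default): MD from significance counting, VD from relative
#'   magnitude.
#'
#' Under every convention `CR% = 100 mean_t (range_core / range_full)` and
#' `VR% = 100 mean_t (CV_core / CV_full)`. Traits with zero full-panel
#' range or CV are excluded with a warning.
#'
#' @param core_table,full_table data.frames with identical trait columns.
#' @param convention one of "mixed", "significance-count",
#'   "relative-magnitude".
#' @return list with md_percent, vd_percent, cr_percent, vr_percent,
#'   per-trait detail and the convention tag.
#' @export
evaluate_core_pheno <- function(core_table, full_table,
                                convention = c("mixed", "significance-count",
                                               "relative-magnitude")) {
  convention <- match.arg(convention)
  traits <- names(full_table)
  stopifnot(identical(sort(traits), sort(names(core_table))))
  keep <- vapply(traits, function(tr) {
    f <- full_table[[tr]]
    ok <- diff(range(f)) > 0 && sd(f) > 0 && mean(f) != 0
    if (!ok) warning("trait ", tr, " has zero full-panel range/CV; excluded")
    ok
  }, logical(1))
  traits <- traits[keep]

  detail <- do.call(rbind, lapply(traits, function(tr) {
    cv <- core_table[[tr]]
    fv <- full_table[[tr]]
    data.frame(
      trait = tr,
      t_p = t.test(cv, fv)$p.value,
      f_p = var.test(cv, fv)$p.value,
      mean_rel = 100 * abs(mean(cv) - mean(fv)) / abs(mean(fv)),
      var_rel = 100 * abs(var(cv) - var(fv)) / var(fv),
      range_ratio = 100 * diff(range(cv)) / diff(range(fv)),
      cv_ratio = 100 * (sd(cv) / mean(cv)) / (sd(fv) / mean(fv)))
  }))

  md_sig <- 100 * mean(detail$t_p < 0.05)
  vd_sig <- 100 * mean(detail$f_p < 0.05)
  md_rel <- mean(detail$mean_rel)
  vd_rel <- mean(detail$var_rel)
  md <- switch(convention, "relative-magnitude" = md_rel, md_sig)
  vd <- switch(convention, "significance-count" = vd_sig, vd_rel)
  list(md_percent = md, vd_percent = vd,
       cr_percent = mean(detail$range_ratio),
       vr_percent = mean(detail$cv_ratio),
       detail = detail, convention = convention)
}

#' Select a phenotype core at gradient fractions
#'
#' Candidates are generated per fraction by A-NE optimisation on the Gower
#' distance over the traits; each candidate is scored with
#' [evaluate_core_pheno()]. The chosen candidate maximises CR + VR among
#' candidates meeting the MD constraint (MD = 0 under significance
#' counting by default); when none qualifies the lowest-MD candidate is
#' returned with a warning.
#'
#' @param full_table phenotype data.frame, rownames = accession IDs.
#' @param fractions candidate sampling fractions.
#' @param seed RNG seed.
#' @param convention evaluation convention (see [evaluate_core_pheno()]).
#' @param md_max maximum admissible MD% (default 0).
#' @param restarts optimiser restarts per fraction.
#' @return list with `core_ids`, `fraction`, `evaluation` (chosen
#'   candidate) and `candidates` (per-fraction metric table).
#' @export
select_pheno_core <- function(full_table, fractions = c(0.05, 0.10, 0.15,
                                                        0.20, 0.25, 0.30),
                              seed = 313, convention = "mixed", md_max = 0,
                              restarts = 3) {
  if (!length(fractions)) stop("fractions must be non-empty")
  n <- nrow(full_table)
  d <- gower_distance(full_table)
  cands <- list()
  metrics <- list()
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    size <- max(2L, core_fraction_size(n, f))
    res <- if (size >= n) {
      list(subset = seq_len(n), ids = rownames(full_table))
    } else {
      optimize_subset(d, size, seed = seed + i, restarts = restarts)
    }
    ids <- rownames(full_table)[res$subset]
    ev <- evaluate_core_pheno(full_table[ids, , drop = FALSE], full_table,
                              convention)
    cands[[i]] <- list(fraction = f, ids = ids, evaluation = ev)
    metrics[[i]] <- data.frame(fraction = f, size = length(ids),
                               md = ev$md_percent, vd = ev$vd_percent,
                               cr = ev$cr_percent, vr = ev$vr_percent)
  }
  metrics <- do.call(rbind, metrics)
  ok <- which(metrics$md <= md_max)
  if (!length(ok)) {
    warning("no candidate meets the MD constraint; returning lowest-MD one")
    ok <- which(metrics$md == min(metrics$md))
  }
  best <- ok[which.max(metrics$cr[ok] + metrics$vr[ok])]
  list(core_ids = cands[[best]]$ids, fraction = metrics$fraction[best],
       evaluation = cands[[best]]$evaluation, candidates = metrics)
}

#' Merge two core subsets
#'
#' Order-stable set union with overlap accounting.
#'
#' @param core1_ids,core2_ids character vectors of accession IDs.
#' @return list with `merged_ids`, `n_core1`, `n_core2`, `n_overlap`,
#'   `n_merged`.
#' @export
merge_cores <- function(core1_ids, core2_ids) {
  a <- unique(core1_ids)
  b <- unique(core2_ids)
  merged <- c(a, setdiff(b, a))
  list(merged_ids = merged, n_core1 = length(a), n_core2 = length(b),
       n_overlap = length(intersect(a, b)), n_merged = length(merged))
}

p_to_stars <- function(p) {
  ifelse(p <= 0.001, "***",
         ifelse(p <= 0.01, "**",
                ifelse(p <= 0.05, "*", "N.S.")))
}

#' Validate core collections by ANOVA and Tukey HSD
#'
#' One-way ANOVA per trait across the supplied groups (e.g. original,
#' Core1, Core-Merge) followed by Tukey honest-significant-difference
#' pairwise comparisons, with N.S./*/**/*** notation at 0.05/0.01/0.001.
#'
#' @param trait_tables named list (>= 2 groups) of phenotype data.frames
#'   sharing trait columns; each group needs >= 2 rows.
#' @return list with `anova` (trait, F, p, signif) and `tukey` (trait,
#'   comparison, diff, p_adj, signif).
#' @export
validate_core <- function(trait_tables) {
  if (length(trait_tables) < 2L) stop("need at least two groups")
  if (any(vapply(trait_tables, nrow, integer(1)) < 2L)) {
    stop("every group needs at least two observations")
  }
  traits <- names(trait_tables[[1]])
  grp <- factor(rep(names(trait_tables),
                    vapply(trait_tables, nrow, integer(1))),
                levels = names(trait_tables))
  anova_rows <- list()
  tukey_rows <- list()
  for (tr in traits) {
    y <- unlist(lapply(trait_tables, `[[`, tr), use.names = FALSE)
    if (all(tapply(y, grp, var) == 0)) {
      warning("trait ", tr, ": zero within-group variance; F undefined")
      anova_rows[[tr]] <- data.frame(trait = tr, F = NA_real_, p = NA_real_,
                                     signif = NA_character_)
      next
    }
    fit <- aov(y ~ grp)
    s <- summary(fit)[[1]]
    fval <- s$`F value`[1]
    pval <- s$`Pr(>F)`[1]
    anova_rows[[tr]] <- data.frame(trait = tr, F = fval, p = pval,
                                   signif = p_to_stars(pval))
    tk <- TukeyHSD(fit)$grp
    tukey_rows[[tr]] <- data.frame(trait = tr, comparison = rownames(tk),
                                   diff = tk[, "diff"],
                                   p_adj = tk[, "p adj"],
                                   signif = p_to_stars(tk[, "p adj"]),
                                   row.names = NULL)
  }
  list(anova = do.call(rbind, c(anova_rows, list(make.row.names = FALSE))),
       tukey = do.call(rbind, c(tukey_rows, list(make.row.names = FALSE))))
}
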