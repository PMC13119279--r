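# Population structure: genotype distances, PCA/PCoA, neighbor-joining,
# phenotype clustering, kinship.

# Pairwise sums of |gi - gj| (ibs) or (gi - gj)^2 (rogers) over non-missing
# site pairs, via dosage-category indicator cross-products (BLAS-fast).
pair_diff_sums <- function(dosages, squared = FALSE) {
  ind <- lapply(0:2, function(v) {
    m <- dosages == v
    m[is.na(m)] <- FALSE
    storage.mode(m) <- "double"
    m
  })
  cross <- function(i, j) tcrossprod(ind[[i + 1L]], ind[[j + 1L]])
  one <- cross(0, 1) + cross(1, 0) + cross(1, 2) + cross(2, 1)
  two <- cross(0, 2) + cross(2, 0)
  called <- !is.na(dosages)
  storage.mode(called) <- "double"
  list(diff = one + (if (squared) 4 else 2) * two,
       n = tcrossprod(called))
}

finish_distance <- function(d, n_comp, metric, ids) {
  offdiag <- n_comp[upper.tri(n_comp)]
  if (any(offdiag == 0)) {
    stop("accession pair(s) share no comparable sites")
  }
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  attr(d, "metric") <- metric
  d
}

#' Identity-by-state distance matrix
#'
#' `d(i, j) = 1 - mean per-site shared-allele score`, with per-site score
#' `(2 - |g_i - g_j|) / 2` over pairwise non-missing sites. Identical
#' genotypes give 0; opposite homozygotes at every site give 1.
#'
#' @param panel a `geno_panel` or dosage matrix (>= 2 accessions).
#' @return symmetric matrix in [0, 1], zero diagonal, metric tag "IBS".
#' @export
ibs_distance <- function(panel) {
  dosages <- if (inherits(panel, "geno_panel")) panel$dosages else panel
  if (nrow(dosages) < 2L) stop("need at least two accessions")
  s <- pair_diff_sums(dosages, squared = FALSE)
  finish_distance(s$diff / (2 * s$n), s$n, "IBS", rownames(dosages))
}

#' Modified Rogers distance matrix
#'
#' `d(i, j) = sqrt(mean per-site (g_i - g_j)^2 / 4)` over pairwise
#' non-missing sites; a Euclidean-type genotype distance scaled to [0, 1],
#' the conventional genotype metric for core-subset optimisation.
#'
#' @param panel a `geno_panel` or dosage matrix (>= 2 accessions).
#' @return symmetric matrix in [0, 1], metric tag "ModifiedRogers".
#' @export
modified_rogers_distance <- function(panel) {
  dosages <- if (inherits(panel, "geno_panel")) panel$dosages else panel
  if (nrow(dosages) < 2L) stop("need at least two accessions")
  s <- pair_diff_sums(dosages, squared = TRUE)
  finish_distance(sqrt(s$diff / (4 * s$n)), s$n, "ModifiedRogers",
                  rownames(dosages))
}

#' Gower distance over quantitative traits
#'
#' Range-normalised mean absolute difference: for numeric traits Gower's
#' coefficient reduces to `mean_t |x_it - x_jt| / range_t`. Traits with zero
#' range are dropped with a warning.
#'
#' @param phenotypes data.frame or matrix of numeric trait columns.
#' @return symmetric matrix in [0, 1], metric tag "Gower".
#' @export
gower_distance <- function(phenotypes) {
  x <- as.matrix(phenotypes)
  rng <- apply(x, 2, function(v) diff(range(v, na.rm = TRUE)))
  if (any(rng == 0)) {
    warning("trait(s) with zero range dropped: ",
            paste(colnames(x)[rng == 0], collapse = ", "))
    x <- x[, rng > 0, drop = FALSE]
    rng <- rng[rng > 0]
  }
  xs <- sweep(x, 2, rng, "/")
  n <- nrow(xs)
  d <- matrix(0, n, n)
  for (t in seq_len(ncol(xs))) {
    d <- d + abs(outer(xs[, t], xs[, t], "-"))
  }
  d <- d / ncol(xs)
  finish_distance(d, matrix(1, n, n), "Gower", rownames(x))
}

#' Genotype PCA on the standardised relationship matrix
#'
#' Dosages are centred by `2p` and scaled by `sqrt(2 p (1 - p))` per site
#' (sites with MAF 0 dropped), missing calls imputed to the site mean, and
#' the accession covariance eigendecomposed.
#'
#' @param panel a `geno_panel` or dosage matrix.
#' @param n_components number of axes to return.
#' @return list with `coordinates` (accessions x components),
#'   `variance_percent` (non-increasing, sums <= 100) and `eigenvalues`.
#' @export
grm_pca <- function(panel, n_components = 10) {
  dosages <- if (inherits(panel, "geno_panel")) panel$dosages else panel
  n <- nrow(dosages)
  if (n_components > n) stop("more components requested than accessions")
  p <- site_alt_freq(dosages)
  keep <- !is.na(p) & p > 0 & p < 1
  x <- dosages[, keep, drop = FALSE]
  p <- p[keep]
  xs <- sweep(sweep(x, 2, 2 * p, "-"), 2, sqrt(expected_het(p)), "/")
  xs[is.na(xs)] <- 0
  k <- tcrossprod(xs) / ncol(xs)
  eig <- eigen(k, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  coords <- eig$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(vals[seq_len(n_components)]), n_components)
  rownames(coords) <- rownames(dosages)
  colnames(coords) <- paste0("PC", seq_len(n_components))
  list(coordinates = coords,
       variance_percent = 100 * vals[seq_len(n_components)] / sum(vals),
       eigenvalues = vals)
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Double-centres `-D^2 / 2`, eigendecomposes, and keeps axes with positive
#' eigenvalues. Exact on Euclidean-embeddable distance matrices.
#'
#' @param distance symmetric distance matrix.
#' @param n_components maximum number of axes.
#' @return list with `coordinates`, `eigenvalues` (positive ones) and
#'   `variance_percent`.
#' @export
pcoa <- function(distance, n_components = 3) {
  d <- as.matrix(distance)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  n <- nrow(d)
  # cmdscale warns when fewer than k eigenvalues are positive; we trim to
  # the positive ones below, so the warning is expected
  fit <- suppressWarnings(cmdscale(d, k = min(n_components, n - 1L),
                                   eig = TRUE))
  pos <- fit$eig[fit$eig > 1e-12]
  k_eff <- min(ncol(fit$points), length(pos))
  coords <- fit$points[, seq_len(k_eff), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(k_eff))
  list(coordinates = coords, eigenvalues = pos,
       variance_percent = 100 * pos[seq_len(k_eff)] / sum(pos))
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q criterion. Ties in Q are
#' broken deterministically toward the pair with the lowest node indices
#' (original leaf order first); negative branch lengths are clamped to zero
#' and the clamped deficit recorded in attribute `negative_deficit`.
#'
#' @param distance symmetric distance matrix with >= 3 leaves; dimnames
#'   provide the leaf labels.
#' @return an [ape::phylo] unrooted tree with branch lengths.
#' @export
nj_tree <- function(distance) {
  d <- as.matrix(distance)
  if (any(!is.finite(d))) stop("distances must be finite")
  n <- nrow(d)
  if (n < 3L) stop("need at least three leaves")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  rep_nwk <- labels      # Newick fragment per active node
  deficit <- 0

  clamp <- function(x) {
    if (x < 0) deficit <<- deficit + (-x)
    max(x, 0)
  }

  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    # lowest (i, j), i < j, among minimal Q entries
    idx <- which(q == min(q), arr.ind = TRUE)
    idx <- t(apply(idx, 1, sort))
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    vi <- clamp(d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    vj <- clamp(d[i, j] - (d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))))
    new_nwk <- sprintf("(%s:%.10g,%s:%.10g)", rep_nwk[i], vi, rep_nwk[j], vj)
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    d <- d2
    rep_nwk <- c(rep_nwk[keep], new_nwk)
  }
  # three-point closure
  v1 <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  v2 <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  v3 <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 rep_nwk[1], v1, rep_nwk[2], v2, rep_nwk[3], v3)
  tree <- ape::read.tree(text = nwk)
  attr(tree, "negative_deficit") <- deficit
  tree
}

#' Hierarchical clustering of phenotypes
#'
#' Traits are standardised (zero mean, unit sd), accessions clustered on
#' Euclidean distance with Ward linkage and the dendrogram cut to `k`
#' clusters. Deterministic.
#'
#' @param phenotypes data.frame of numeric trait columns, rownames =
#'   accession IDs.
#' @param k number of clusters (<= n).
#' @param linkage hclust method (default "ward.D2").
#' @return named integer vector of cluster labels; the `hclust` object is
#'   attached as attribute `hclust`.
#' @export
hclust_phenotypes <- function(phenotypes, k = 4, linkage = "ward.D2") {
  x <- as.matrix(phenotypes)
  if (k > nrow(x)) stop("k exceeds the number of accessions")
  sds <- apply(x, 2, sd)
  xs <- scale(x, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  hc <- hclust(dist(xs), method = linkage)
  labels <- cutree(hc, k = k)
  attr(labels, "hclust") <- hc
  labels
}

#' Kinship matrix from genotype correlation
#'
#' Pearson correlation between accession dosage vectors over pairwise
#' non-missing sites; the diagonal is 1 by construction. Zero-variance
#' accession vectors yield NA entries and a warning.
#'
#' @param panel a `geno_panel` or dosage matrix.
#' @return symmetric matrix in [-1, 1] with unit diagonal.
#' @export
kinship_matrix <- function(panel) {
  dosages <- if (inherits(panel, "geno_panel")) panel$dosages else panel
  k <- suppressWarnings(cor(t(dosages), use = "pairwise.complete.obs"))
  if (anyNA(k)) warning("zero-variance accession(s): NA kinship entries")
  diag(k) <- 1
  k
}

#' Bin kinship coefficients of accession pairs
#'
#' Upper-triangle (off-diagonal) pairs are binned at the conventional
#' relatedness cutpoints; counts and percentages are reported per bin.
#'
#' @param kinship kinship matrix.
#' @param cuts bin boundaries (default 0.125, 0.25, 0.5).
#' @return data.frame with bin, count and percent (percentages sum to 100).
#' @export
kinship_bins <- function(kinship, cuts = c(0.125, 0.25, 0.5)) {
  vals <- kinship[upper.tri(kinship)]
  k <- length(cuts)
  lo <- c(-Inf, cuts)
  hi <- c(cuts, Inf)
  # half-open [lo, hi) bins, except the top cut is inclusive below
  counts <- vapply(seq_len(k + 1L), function(i) {
    if (i == k) sum(vals >= lo[i] & vals <= hi[i])
    else if (i == k + 1L) sum(vals > lo[i])
    else sum(vals >= lo[i] & vals < hi[i])
  }, integer(1))
  labels <- c(sprintf("<%g", cuts[1]),
              if (k > 2) sprintf("[%g,%g)", cuts[seq_len(k - 2)],
                                 cuts[seq_len(k - 2) + 1L]),
              sprintf("[%g,%g]", cuts[k - 1], cuts[k]),
              sprintf(">%g", cuts[k]))
  data.frame(bin = labels, count = counts,
             percent = 100 * counts / length(vals))
}

#' Cross-tabulate two clusterings
#'
#' Contingency counts of `labels_a` groups against `labels_b` groups with
#' row-wise percentages (each source group sums to 100).
#'
#' @param labels_a,labels_b label vectors over the same accessions.
#' @return list with `counts` (table) and `percent` (row percentages).
#' @export
group_composition <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  counts <- table(source = labels_a, target = labels_b)
  percent <- 100 * sweep(counts, 1, rowSums(counts), "/")
  list(counts = counts, percent = percent)
}
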