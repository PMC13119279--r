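# Input/output: VCF genotype panels, phenotype/population tables, Newick trees.
#
# The in-memory data model is a "geno_panel": a list with
#   $dosages  - n_accessions x n_sites integer matrix of ALT-allele counts
#               (0/1/2, NA = missing call), rownames = accession IDs
#   $variants - data.frame of per-site records (chrom, pos, ref, alt, qual,
#               QD, MQ, FS, SOR, MQRankSum, ReadPosRankSum; annotation
#               columns may be NA where the caller did not emit them)
#   $layout   - named numeric vector of chromosome lengths in bp

VARIANT_ANNOTATIONS <- c("QD", "MQ", "FS", "SOR", "MQRankSum", "ReadPosRankSum")

#' Construct a genotype panel object
#'
#' Bundles a dosage matrix, its per-site variant table and a genome layout
#' into the container consumed by every downstream analysis function.
#'
#' @param dosages integer matrix, accessions x sites, entries 0/1/2 or NA.
#' @param variants data.frame with at least `chrom`, `pos`, `ref`, `alt`.
#' @param layout named numeric vector of chromosome lengths (bp). Optional.
#' @return An object of class `geno_panel`.
#' @export
geno_panel <- function(dosages, variants, layout = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (is.null(rownames(dosages))) {
    stop("dosage matrix must carry accession IDs as rownames")
  }
  if (anyDuplicated(rownames(dosages))) {
    stop("duplicate accession IDs in genotype panel")
  }
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  if (nrow(variants) != ncol(dosages)) {
    stop("variant table row count (", nrow(variants),
         ") does not match site count (", ncol(dosages), ")")
  }
  for (col in VARIANT_ANNOTATIONS) {
    if (is.null(variants[[col]])) variants[[col]] <- NA_real_
  }
  if (is.null(variants$qual)) variants$qual <- NA_real_
  if (any(variants$pos < 1)) stop("variant positions must be >= 1")
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
  if (!is.null(layout)) {
    layout <- unlist(layout)
    if (any(layout <= 0)) stop("chromosome lengths must be positive")
    extra <- setdiff(unique(variants$chrom), names(layout))
    if (length(extra)) {
      stop("variants on chromosomes absent from layout: ",
           paste(extra, collapse = ", "))
    }
  }
  structure(list(dosages = dosages, variants = variants, layout = layout),
            class = "geno_panel")
}

#' @export
print.geno_panel <- function(x, ...) {
  cat("geno_panel:", nrow(x$dosages), "accessions x", ncol(x$dosages),
      "sites on", length(unique(x$variants$chrom)), "chromosome(s)\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing call rate: %.3f\n", miss))
  invisible(x)
}

#' Subset a genotype panel
#'
#' @param panel a `geno_panel`.
#' @param accessions accession IDs or row indices to keep (NULL = all).
#' @param sites site indices or logical mask to keep (NULL = all).
#' @return A `geno_panel` restricted to the requested accessions/sites.
#' @export
subset_panel <- function(panel, accessions = NULL, sites = NULL) {
  d <- panel$dosages
  v <- panel$variants
  if (!is.null(accessions)) d <- d[accessions, , drop = FALSE]
  if (!is.null(sites)) {
    d <- d[, sites, drop = FALSE]
    v <- v[sites, , drop = FALSE]
    rownames(v) <- NULL
  }
  geno_panel(d, v, panel$layout)
}

#' Read a multi-sample VCF into a genotype panel
#'
#' Retains biallelic SNP records only; multiallelic and non-SNP records are
#' skipped and counted. Dosage is the ALT-allele count of the GT call;
#' half-calls and `./.` become missing. Site annotations (QD, MQ, FS, SOR,
#' MQRankSum, ReadPosRankSum) are taken from INFO when declared; absent
#' annotations are NA, which downstream hard filters treat as passing
#' (GATK convention). Contig lengths come from `##contig` header lines
#' unless overridden.
#'
#' @param path path to an uncompressed or gzipped VCF (VCFv4.x subset).
#' @param contig_filter optional character vector: keep only these contigs.
#' @param layout_override optional named vector of contig lengths (bp)
#'   used instead of (or when missing from) the header.
#' @return A `geno_panel`; attribute `skipped` holds the per-reason counts
#'   of records not retained.
#' @export
read_vcf <- function(path, contig_filter = NULL, layout_override = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  gt <- tryCatch(VariantAnnotation::geno(vcf)$GT,
                 error = function(e) NULL)
  if (is.null(gt)) stop("VCF has no GT genotype field")
  samples <- colnames(gt)
  if (anyDuplicated(samples)) stop("duplicate accession IDs in VCF header")

  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.vector(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(n_alt))
  alt1[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))

  multi <- n_alt != 1L
  nonsnp <- !multi & (nchar(ref) != 1L | is.na(alt1) | nchar(alt1) != 1L |
                        !(ref %in% c("A", "C", "G", "T")) |
                        !(alt1 %in% c("A", "C", "G", "T")))
  nonsnp[is.na(nonsnp)] <- TRUE
  offcontig <- rep(FALSE, length(chrom))
  if (!is.null(contig_filter)) offcontig <- !(chrom %in% contig_filter)
  keep <- !multi & !nonsnp & !offcontig
  skipped <- c(multiallelic = sum(multi), non_snp = sum(nonsnp & !multi),
               off_contig = sum(offcontig & !multi & !nonsnp))
  if (!any(keep)) stop("no biallelic SNP records retained from ", path)

  info <- VariantAnnotation::info(vcf)
  ann <- lapply(VARIANT_ANNOTATIONS, function(a) {
    if (a %in% colnames(info)) suppressWarnings(as.numeric(info[[a]][keep]))
    else rep(NA_real_, sum(keep))
  })
  names(ann) <- VARIANT_ANNOTATIONS
  variants <- data.frame(chrom = chrom[keep], pos = pos[keep],
                         ref = ref[keep], alt = alt1[keep],
                         qual = as.numeric(VariantAnnotation::qual(vcf))[keep],
                         ann, stringsAsFactors = FALSE)

  dosages <- t(gt_to_dosage(gt[keep, , drop = FALSE]))
  dimnames(dosages) <- list(samples, NULL)

  sl <- GenomeInfoDb::seqlengths(rr)
  layout <- sl[!is.na(sl)]
  if (!is.null(layout_override)) {
    layout_override <- unlist(layout_override)
    layout[names(layout_override)] <- layout_override
    layout <- c(layout,
                layout_override[setdiff(names(layout_override), names(layout))])
  }
  layout <- layout[names(layout) %in% unique(variants$chrom)]
  if (length(layout) == 0L) layout <- NULL

  panel <- geno_panel(dosages, variants, layout)
  attr(panel, "skipped") <- skipped
  panel
}

# "0/1", "1|0" -> 1; "./." or half-calls -> NA; genotypes with alleles
# other than 0/1 -> NA (cannot occur after biallelic restriction).
gt_to_dosage <- function(gt) {
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  d <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  ok <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
  d[ok] <- as.integer(a1[ok]) + as.integer(a2[ok])
  dimnames(d) <- dimnames(gt)
  d
}

#' Write a genotype panel as VCF text
#'
#' Emits a minimal VCFv4.2 file (GT-only sample fields, the six hard-filter
#' annotations in INFO, `##contig` lines from the layout). Deterministic
#' formatting so fixture files are byte-reproducible.
#'
#' @param panel a `geno_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  v <- panel$variants
  hdr <- c("##fileformat=VCFv4.2", "##source=germcore")
  if (!is.null(panel$layout)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(panel$layout), as.integer(panel$layout)))
  }
  hdr <- c(hdr,
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
            VARIANT_ANNOTATIONS, VARIANT_ANNOTATIONS),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(panel$dosages)), collapse = "\t"))

  info_str <- vapply(seq_len(nrow(v)), function(i) {
    vals <- vapply(VARIANT_ANNOTATIONS, function(a) v[[a]][i], numeric(1))
    ok <- !is.na(vals)
    if (!any(ok)) return(".")
    paste(sprintf("%s=%.4f", VARIANT_ANNOTATIONS[ok], vals[ok]),
          collapse = ";")
  }, character(1))
  gt_txt <- matrix(c("0/0", "0/1", "1/1")[panel$dosages + 1L],
                   nrow = nrow(panel$dosages))
  gt_txt[is.na(panel$dosages)] <- "./."
  qual <- ifelse(is.na(v$qual), ".", sprintf("%.2f", v$qual))
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, qual, "PASS", info_str,
                "GT", apply(gt_txt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read phenotype and population-map tables
#'
#' Both files are delimited text with a header; the first column is the
#' accession ID. The phenotype table must contain the four trait columns
#' (BNMS, NNMS, SD, PH by default); the population map a single population
#' column. IDs are cross-checked and unmatched accessions reported.
#'
#' @param pheno_path path to the phenotype CSV/TSV.
#' @param popmap_path path to the population-map CSV/TSV.
#' @param traits expected trait column names.
#' @return list with `phenotypes` (data.frame, rownames = accession) and
#'   `popmap` (named character vector accession -> population code).
#' @export
read_tables <- function(pheno_path, popmap_path,
                        traits = c("BNMS", "NNMS", "SD", "PH")) {
  ph <- utils::read.table(pheno_path, header = TRUE, sep = guess_sep(pheno_path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  pm <- utils::read.table(popmap_path, header = TRUE, sep = guess_sep(popmap_path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(ph[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate accession in phenotype table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  missing_tr <- setdiff(traits, names(ph))
  if (length(missing_tr)) {
    stop("phenotype table lacks trait column(s): ",
         paste(missing_tr, collapse = ", "))
  }
  for (tr in traits) {
    val <- suppressWarnings(as.numeric(ph[[tr]]))
    bad <- which(is.na(val) & !is.na(ph[[tr]]))
    if (length(bad)) {
      stop("non-numeric value in phenotype column '", tr, "', row ", bad[1])
    }
    ph[[tr]] <- val
  }
  phen <- ph[, traits, drop = FALSE]
  rownames(phen) <- ids

  pop_ids <- as.character(pm[[1]])
  if (anyDuplicated(pop_ids)) {
    stop("duplicate accession in population map: ",
         paste(unique(pop_ids[duplicated(pop_ids)]), collapse = ", "))
  }
  popmap <- as.character(pm[[2]])
  names(popmap) <- pop_ids

  only_pm <- setdiff(pop_ids, ids)
  only_ph <- setdiff(ids, pop_ids)
  if (length(only_pm)) {
    warning("accessions in population map but not phenotype table: ",
            paste(only_pm, collapse = ", "))
  }
  if (length(only_ph)) {
    warning("accessions in phenotype table but not population map: ",
            paste(only_ph, collapse = ", "))
  }
  list(phenotypes = phen, popmap = popmap)
}

guess_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Write a tree in Newick format
#'
#' Labels containing Newick-reserved characters (comma, parentheses, colon,
#' semicolon, whitespace) are rejected rather than quoted: the dialect used
#' throughout the package is the plain unquoted-label Newick that PLINK/iTOL
#' workflows expect.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param path optional output path; when NULL the Newick string is returned.
#' @param digits significant digits for branch lengths (>= 6).
#' @return The Newick string, invisibly when written to `path`.
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  if (digits < 6) stop("branch lengths must keep at least 6 significant digits")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  if (any(grepl("[,;:() \t]", tree$tip.label))) {
    stop("leaf labels may not contain Newick-reserved characters")
  }
  txt <- ape::write.tree(tree, digits = digits)
  if (!endsWith(txt, ";")) txt <- paste0(txt, ";")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
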