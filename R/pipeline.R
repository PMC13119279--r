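# End-to-end orchestration: filter -> diversity -> fst -> structure ->
# core -> validate, with file outputs per stage and a run log.

#' Build a validated run configuration
#'
#' @param vcf,pheno,popmap input file paths.
#' @param outdir output directory.
#' @param layout optional named chromosome lengths (bp) overriding the VCF
#'   header.
#' @param thresholds a [filter_thresholds()] object.
#' @param ld_window,ld_step,ld_r2 LD-pruning parameters.
#' @param fst_window_bp Fst window size in bp.
#' @param fractions core sampling fractions.
#' @param n_pheno_clusters clusters for phenotype hclust.
#' @param convention MD/VD convention for phenotype core evaluation.
#' @param seed master seed; every stochastic stage derives from it.
#' @param restarts optimiser restarts.
#' @return a `run_config` list.
#' @export
run_config <- function(vcf, pheno, popmap, outdir,
                       layout = NULL,
                       thresholds = filter_thresholds(),
                       ld_window = 50, ld_step = 10, ld_r2 = 0.2,
                       fst_window_bp = 500000,
                       fractions = c(0.05, 0.10, 0.15, 0.20, 0.25, 0.30),
                       n_pheno_clusters = 4,
                       convention = "mixed",
                       seed = 313, restarts = 3) {
  stopifnot(inherits(thresholds, "filter_thresholds"),
            ld_window >= 2, fst_window_bp > 0,
            length(fractions) >= 1, all(fractions > 0 & fractions <= 1))
  structure(list(vcf = vcf, pheno = pheno, popmap = popmap, outdir = outdir,
                 layout = layout, thresholds = thresholds,
                 ld_window = ld_window, ld_step = ld_step, ld_r2 = ld_r2,
                 fst_window_bp = fst_window_bp, fractions = fractions,
                 n_pheno_clusters = n_pheno_clusters,
                 convention = convention, seed = seed, restarts = restarts),
            class = "run_config")
}

stage <- function(name, log, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

log_line <- function(log_path, ...) {
  cat(paste0(..., "\n"), file = log_path, append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Reads the genotype, phenotype and population inputs, applies hard/MAF
#' filters and LD pruning, and produces the full report bundle: diversity
#' table, pairwise Fst/Nm table, trait summary, gradient-core table, core
#' ID lists, NJ tree (Newick), PCA/PCoA coordinates, kinship bins,
#' evaluation and validation outputs, plus a plain-text run log. Pure
#' function of (inputs, config, seed).
#'
#' @param config a [run_config()].
#' @return list of the main result objects, invisibly; files are written
#'   under `config$outdir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run_log.txt")
  cat("germcore run\n", file = log_path)
  log_line(log_path, "seed: ", config$seed)

  # --- input ---------------------------------------------------------
  panel <- stage("read_vcf", log_path,
                 read_vcf(config$vcf, layout_override = config$layout))
  tabs <- stage("read_tables", log_path,
                read_tables(config$pheno, config$popmap))
  phen <- tabs$phenotypes[rownames(panel$dosages), , drop = FALSE]
  popmap <- tabs$popmap
  log_line(log_path, "input sites: ", ncol(panel$dosages),
           "; accessions: ", nrow(panel$dosages))

  # --- filtering -----------------------------------------------------
  hf <- stage("hard_filter", log_path, hard_filter(panel, config$thresholds))
  panel_f <- subset_panel(panel, sites = hf$keep)
  maf_keep <- stage("maf_filter", log_path,
                    maf_filter(panel_f, config$thresholds$maf_min))
  panel_f <- subset_panel(panel_f, sites = maf_keep)
  pruned <- stage("ld_prune", log_path,
                  ld_prune(panel_f, config$ld_window, config$ld_step,
                           config$ld_r2))
  panel_p <- subset_panel(panel_f, sites = pruned)
  filter_report <- list(
    input_sites = ncol(panel$dosages),
    hard_filter_removed = sum(!hf$keep),
    removed_by_rule = as.list(hf$removed_by_rule),
    maf_removed = sum(!maf_keep),
    after_filters = ncol(panel_f$dosages),
    after_ld_prune = ncol(panel_p$dosages))
  jsonlite::write_json(filter_report, file.path(outdir, "filter_report.json"),
                       auto_unbox = TRUE)
  log_line(log_path, "sites after hard+MAF filters: ",
           ncol(panel_f$dosages), "; after LD pruning: ",
           ncol(panel_p$dosages))

  # --- diversity -----------------------------------------------------
  div <- stage("diversity", log_path,
               population_diversity(panel_f, popmap))
  utils::write.csv(div, file.path(outdir, "diversity_table.csv"),
                   row.names = FALSE)
  dens <- stage("snp_density", log_path, snp_density(panel_f, panel_f$layout))
  utils::write.csv(dens, file.path(outdir, "snp_density.csv"),
                   row.names = FALSE)
  tstv <- stage("tstv", log_path, ts_tv_summary(panel_f))

  # --- differentiation ----------------------------------------------
  fstres <- stage("fst", log_path,
                  pairwise_matrix(panel_f, popmap, config$fst_window_bp))
  utils::write.csv(as.data.frame(fstres$matrix),
                   file.path(outdir, "fst_nm_matrix.csv"))
  utils::write.csv(fstres$pairs, file.path(outdir, "fst_pairs.csv"),
                   row.names = FALSE)

  # --- traits --------------------------------------------------------
  traits <- stage("traits", log_path, trait_summary_table(phen))
  utils::write.csv(traits, file.path(outdir, "trait_summary.csv"),
                   row.names = FALSE)

  # --- structure -----------------------------------------------------
  ibs <- stage("ibs", log_path, ibs_distance(panel_p))
  tree <- stage("nj_tree", log_path, nj_tree(ibs))
  write_newick(tree, file.path(outdir, "nj_tree.nwk"))
  pca <- stage("pca", log_path,
               grm_pca(panel_p, n_components = min(10, nrow(ibs) - 1)))
  utils::write.csv(data.frame(accession = rownames(pca$coordinates),
                              pca$coordinates,
                              check.names = FALSE),
                   file.path(outdir, "pca_coordinates.csv"),
                   row.names = FALSE)
  pheno_cl <- stage("hclust", log_path,
                    hclust_phenotypes(phen, k = config$n_pheno_clusters))
  utils::write.csv(data.frame(accession = names(pheno_cl),
                              cluster = as.integer(pheno_cl)),
                   file.path(outdir, "phenotype_clusters.csv"),
                   row.names = FALSE)

  # --- core selection ------------------------------------------------
  core1 <- stage("core_genotype", log_path,
                 gradient_core_search(panel_f, config$fractions,
                                      seed = config$seed,
                                      restarts = config$restarts))
  utils::write.csv(core1$table, file.path(outdir, "gradient_core_table.csv"),
                   row.names = FALSE)
  writeLines(core1$core_ids, file.path(outdir, "core1_ids.txt"))
  core2 <- stage("core_phenotype", log_path,
                 select_pheno_core(phen, config$fractions,
                                   seed = config$seed + 1000,
                                   convention = config$convention,
                                   restarts = config$restarts))
  writeLines(core2$core_ids, file.path(outdir, "core2_ids.txt"))
  merged <- merge_cores(core1$core_ids, core2$core_ids)
  writeLines(merged$merged_ids, file.path(outdir, "core_merge_ids.txt"))
  jsonlite::write_json(
    list(core1_fraction = core1$chosen_fraction,
         core2_fraction = core2$fraction,
         core2_evaluation = core2$evaluation[c("md_percent", "vd_percent",
                                               "cr_percent", "vr_percent",
                                               "convention")],
         merge = merged[c("n_core1", "n_core2", "n_overlap", "n_merged")],
         tstv_ratio = tstv$ratio),
    file.path(outdir, "core_report.json"), auto_unbox = TRUE, digits = NA)

  # --- validation ----------------------------------------------------
  val <- stage("validate", log_path, validate_core(list(
    original = phen,
    core1 = phen[core1$core_ids, , drop = FALSE],
    core_merge = phen[merged$merged_ids, , drop = FALSE])))
  utils::write.csv(val$anova, file.path(outdir, "validation_anova.csv"),
                   row.names = FALSE)
  utils::write.csv(val$tukey, file.path(outdir, "validation_tukey.csv"),
                   row.names = FALSE)
  pco <- stage("pcoa", log_path, pcoa(ibs, n_components = 3))
  utils::write.csv(data.frame(accession = rownames(pco$coordinates),
                              pco$coordinates, check.names = FALSE),
                   file.path(outdir, "pcoa_coordinates.csv"),
                   row.names = FALSE)
  kin <- stage("kinship", log_path,
               kinship_matrix(subset_panel(panel_f,
                                           accessions = merged$merged_ids)))
  utils::write.csv(kinship_bins(kin), file.path(outdir, "kinship_bins.csv"),
                   row.names = FALSE)

  log_line(log_path, "core1: ", merged$n_core1, "; core2: ", merged$n_core2,
           "; overlap: ", merged$n_overlap, "; merged: ", merged$n_merged)
  log_line(log_path, "done")

  invisible(list(filter_report = filter_report, diversity = div,
                 fst = fstres, traits = traits, tree = tree, pca = pca,
                 core1 = core1, core2 = core2, merged = merged,
                 validation = val))
}

#' Command-line interface
#'
#' Subcommands: `simulate` (write a synthetic panel), `run-all` (full
#' pipeline) and `fixture` (tiny deterministic test panel). Example:
#' `germcore run-all --vcf in.vcf --pheno pheno.csv --popmap pops.csv
#' --out results/ --seed 313`.
#'
#' @param args command-line arguments (default: the process's).
#' @return exit status, invisibly.
#' @export
germcore_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: germcore <simulate|fixture|run-all> [options]",
    "  simulate --out DIR [--seed N] [--n-snps N] [--n-accessions N]",
    "  fixture  --out DIR [--seed N]",
    "  run-all  --vcf F --pheno F --popmap F --out DIR [--seed N]",
    sep = "\n")
  if (!length(args)) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- args[1]
  if (!cmd %in% c("simulate", "fixture", "run-all")) {
    message(usage)
    return(invisible(1L))
  }
  opts <- list()
  rest <- args[-1]
  i <- 1
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    opts[[key]] <- rest[i + 1]
    i <- i + 2
  }
  seed <- as.integer(opts[["seed"]] %||% 313)
  out <- opts[["out"]]
  if (is.null(out)) stop("--out is required")
  if (cmd == "simulate") {
    cfg <- sim_config(
      n_accessions = as.integer(opts[["n-accessions"]] %||% 313),
      n_snps = as.integer(opts[["n-snps"]] %||% 20000),
      seed = seed)
    write_panel(simulate_panel(cfg), out)
  } else if (cmd == "fixture") {
    fixture_suite(out, seed = seed)
  } else if (cmd == "run-all") {
    cfg <- run_config(vcf = opts[["vcf"]], pheno = opts[["pheno"]],
                      popmap = opts[["popmap"]], outdir = out, seed = seed)
    run_pipeline(cfg)
  }
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
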