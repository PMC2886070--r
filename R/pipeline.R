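#' Write a numeric matrix as TSV with a leading id column
#' @keywords internal
#' @noRd
write_matrix_tsv <- function(m, path, id_col = "locus") {
  d <- data.frame(rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d)[1] <- id_col
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a TSV written by [write_matrix_tsv] back into a matrix
#' @keywords internal
#' @noRd
read_matrix_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' Write a spectral-count table (counts + MW + peptides) as TSV
#'
#' @param x an [spc_table].
#' @param path output file.
#' @export
write_spc_tsv <- function(x, path) {
  stopifnot(inherits(x, "spc_table"))
  d <- data.frame(protein_id = rownames(x$counts),
                  locus_id = sub("\\.\\d+$", "", rownames(x$counts)),
                  mw_kda = x$mw_kda, n_peptides = x$n_peptides,
                  x$counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a spectral-count TSV
#'
#' Expects columns `protein_id, locus_id, mw_kda, n_peptides` followed by
#' one column per replicate.
#'
#' @param path input TSV.
#' @param species named character vector replicate -> species.
#' @return an [spc_table].
#' @export
read_spc_tsv <- function(path, species) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  fixed <- c("protein_id", "locus_id", "mw_kda", "n_peptides")
  if (!all(fixed %in% names(d))) {
    stop_data("spectral-count TSV needs columns ", paste(fixed, collapse = ", "))
  }
  reps <- setdiff(names(d), fixed)
  cnt <- as.matrix(d[, reps, drop = FALSE])
  rownames(cnt) <- d$protein_id
  spc_table(cnt, d$mw_kda, d$n_peptides, species[reps])
}

#' Default pipeline configuration
#'
#' @param outdir output directory.
#' @param seed root seed (simulation and permutation streams derive from
#'   it).
#' @param alpha significance level for regulation calls.
#' @param fraction spectral pseudo-fraction for the t-test path.
#' @param n_perm permutation draws for overlap significance.
#' @param simulate a [sim_config] (or list of its arguments) describing the
#'   synthetic dataset; alternatively supply `transcript_tsv`,
#'   `protein_tsv`, `metabolite_tsv` and `species_map` entries to run on
#'   files.
#' @param ... further entries merged into the config.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(outdir = tempfile("omicsconcord_run_"),
                       seed = 1L, alpha = 0.05, fraction = 0.5,
                       n_perm = 10000, simulate = NULL, ...) {
  cfg <- c(list(outdir = outdir, seed = as.integer(seed), alpha = alpha,
                fraction = fraction, n_perm = n_perm, simulate = simulate),
           list(...))
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with fields as in [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Run the full concordance pipeline
#'
#' Orchestrates the stages simulate (or load) -> NSAF quantitation ->
#' differential expression (per-gene OLS contrasts for transcripts;
#' Wilcoxon one-vs-rest and pairwise t-tests for proteins) -> cross-layer
#' correlation and size-corrected overlap with permutation significance ->
#' metabolite clustering and chemotype prediction/evaluation. All stage
#' outputs are written as TSV under `config$outdir` and listed, with MD5
#' checksums, in a JSON manifest; re-running with the same configuration
#' reproduces every output bit for bit.
#'
#' @param config a [run_config()] (or path to a YAML file).
#' @return an object of class `concordance_run`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$outdir, f)
  files <- character(0)

  # ---- stage: data -------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_cfg <- if (inherits(config$simulate, "sim_config")) config$simulate
               else do.call(sim_config, config$simulate)
    ds <- generate_dataset(sim_cfg)
    tmat <- ds$transcript
    t_species <- attr(tmat, "species")
    spc <- ds$spectral_counts
    metab <- ds$metabolites
    write_matrix_tsv(tmat, out("transcript_log2.tsv"))
    write_spc_tsv(spc, out("spectral_counts.tsv"))
    write_matrix_tsv(metab$conc, out("metabolites.tsv"), id_col = "compound")
    utils::write.table(ds$truth, out("truth.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, "transcript_log2.tsv", "spectral_counts.tsv",
               "metabolites.tsv", "truth.tsv")
  } else {
    for (f in c("transcript_tsv", "protein_tsv", "metabolite_tsv")) {
      if (is.null(config[[f]])) {
        stop_config("config needs either a simulate block or ", f)
      }
      if (!file.exists(config[[f]])) stop_config("missing input: ", config[[f]])
    }
    ds <- NULL
    tmat <- read_matrix_tsv(config$transcript_tsv)
    t_species <- unlist(config$species_map$arrays)[colnames(tmat)]
    spc <- read_spc_tsv(config$protein_tsv,
                        unlist(config$species_map$replicates))
    mm <- read_matrix_tsv(config$metabolite_tsv)
    metab <- metabolite_profile(mm,
      species = unlist(config$species_map$metabolites)[colnames(mm)])
  }
  species <- unique(spc$species)

  # ---- stage: nsaf -------------------------------------------------------
  spc_locus <- combine_isoforms(spc)
  spc_f <- filter_proteins(spc_locus, min_peptides = 2, scope = "any")
  nsaf <- nsaf_matrix(spc_f)
  nsaf_s <- compute_nsaf_summed(spc_f)
  write_matrix_tsv(nsaf, out("nsaf_per_replicate.tsv"))
  write_matrix_tsv(nsaf_s, out("nsaf_summed.tsv"))
  files <- c(files, "nsaf_per_replicate.tsv", "nsaf_summed.tsv")

  # ---- stage: de ---------------------------------------------------------
  contrasts <- study_contrasts(species)
  t_de <- fit_transcript_contrasts(tmat, t_species, contrasts,
                                   alpha = config$alpha)
  grp <- Filter(function(ct) ct$kind == "group", contrasts)
  pw <- Filter(function(ct) ct$kind == "pairwise", contrasts)
  p_de <- rbind(
    do.call(rbind, lapply(grp, function(ct) {
      protein_group_test(spc_f, ct$target, ct$others, alpha = config$alpha,
                         fraction = config$fraction)
    })),
    do.call(rbind, lapply(pw, function(ct) {
      protein_pairwise_test(spc_f, ct$target, ct$others,
                            alpha = config$alpha,
                            fraction = config$fraction, var_equal = TRUE)
    }))
  )
  utils::write.table(t_de, out("de_transcript.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(p_de, out("de_protein.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, "de_transcript.tsv", "de_protein.tsv")

  # ---- stage: concord ----------------------------------------------------
  common <- common_gene_set(rownames(tmat), rownames(spc_f$counts))
  t_means <- sapply(species, function(s)
    rowMeans(tmat[, t_species == s, drop = FALSE]))
  p_log2 <- log2(nsaf_s + .Machine$double.xmin)
  cormat <- correlation_matrix(t_means, p_log2, common)
  write_matrix_tsv(unclass(cormat), out("correlation_matrix.tsv"),
                   id_col = "label")
  t_calls <- call_regulated(t_de, config$alpha)
  p_calls <- call_regulated(p_de, config$alpha)
  perm_seed <- config$seed + 1000L
  overlaps <- list()
  for (ct in contrasts) {
    for (dir in c("up", "down")) {
      ov <- overlap_analysis(t_calls[[ct$name]][[dir]],
                             p_calls[[ct$name]][[dir]], common,
                             contrast = paste0(ct$name, ":", dir))
      perm_seed <- perm_seed + 1L
      ov <- add_overlap_pvalue(ov, length(common$loci),
                               n_perm = config$n_perm, seed = perm_seed)
      overlaps[[ov$contrast]] <- ov
    }
  }
  ov_df <- do.call(rbind, lapply(overlaps, function(o) {
    data.frame(comparison = o$contrast, a = o$a, b = o$b, k = o$k,
               upper_pct = o$upper_pct_display, lower_pct = o$lower_pct_display,
               p_perm = o$p_perm, significant = !is.na(o$p_perm) &
                 o$p_perm < config$alpha, stringsAsFactors = FALSE)
  }))
  rownames(ov_df) <- NULL
  utils::write.table(ov_df, out("overlap.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, "correlation_matrix.tsv", "overlap.tsv")

  # ---- stage: chemotype --------------------------------------------------
  prop <- to_proportions(metab)
  dendro <- cluster_profiles(prop)
  export_newick(dendro, out("metabolite_dendrogram.nwk"))
  calls <- de_call_table(t_de, p_de)
  preds <- predict_chemotype(calls)
  eval_res <- evaluate_predictions(preds, metab, alpha = config$alpha)
  utils::write.table(as.data.frame(preds), out("chemotype_predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(eval_res$claims, out("chemotype_claims.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, "metabolite_dendrogram.nwk", "chemotype_predictions.tsv",
             "chemotype_claims.tsv")

  # ---- manifest ----------------------------------------------------------
  cfg_path <- out("config.yaml")
  cfg_clean <- config
  class(cfg_clean) <- NULL
  cfg_clean$outdir <- NULL
  if (inherits(cfg_clean$simulate, "sim_config")) {
    cfg_clean$simulate <- unclass(cfg_clean$simulate)
  }
  yaml::write_yaml(cfg_clean, cfg_path)
  manifest <- list(
    package = "omicsconcord",
    version = as.character(utils::packageVersion("omicsconcord")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    files = lapply(stats::setNames(files, files), function(f)
      list(md5 = unname(tools::md5sum(out(f))), bytes = file.size(out(f))))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  structure(list(config = config, dataset = ds, spc = spc_f, nsaf = nsaf,
                 nsaf_summed = nsaf_s, de_transcript = t_de,
                 de_protein = p_de, common = common,
                 correlation = cormat, overlap = ov_df,
                 dendrogram = dendro, predictions = preds,
                 evaluation = eval_res, manifest = manifest,
                 outdir = config$outdir),
            class = "concordance_run")
}

#' @export
print.concordance_run <- function(x, ...) {
  cat("Cross-omics concordance run\n")
  cat(sprintf("  common locus set: %d of %d transcript / %d protein loci\n",
              length(x$common$loci), x$common$n_transcript,
              x$common$n_protein))
  cat(sprintf("  overlap comparisons: %d (%d significant at alpha=%g)\n",
              nrow(x$overlap), sum(x$overlap$significant), x$config$alpha))
  cat(sprintf("  chemotype claims: %d; outputs in %s\n",
              nrow(x$evaluation$claims), x$outdir))
  invisible(x)
}

#' @export
summary.concordance_run <- function(object, ...) {
  cat("== Correlation (Spearman, common loci) ==\n")
  print(object$correlation)
  cat("\n== Overlap of regulated lists ==\n")
  print(object$overlap)
  cat("\n== Chemotype evaluation ==\n")
  print(object$evaluation)
  invisible(object)
}
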