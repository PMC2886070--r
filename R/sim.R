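#' Simulation configuration for a multi-species multi-omics study
#'
#' Defines the dimensions and noise structure of a synthetic three-layer
#' dataset: a transcript universe, a protein universe overlapping it in a
#' shared locus set, replicate structure per species, the target rank
#' correlation between the transcript and protein layers, and injected
#' species-specific regulation with known sign and magnitude. Defaults
#' reproduce a three-species alpine Brassicaceae study design: a 9404-gene
#' transcript universe, 1489 detected proteins, 1074 shared loci, 3 arrays
#' and 3 proteomic replicates per species, 12 metabolite replicates per
#' species, and about 50 expected spectra per protein and replicate.
#'
#' @param n_species number of species (labels `CH, EX, NZ` when 3, else
#'   `S1, S2, ...`).
#' @param n_genes_transcript transcript universe size.
#' @param n_genes_protein protein universe size.
#' @param n_shared loci present in both universes
#'   (<= min of the two).
#' @param n_array_samples_per_species arrays per species.
#' @param n_protein_reps_per_species proteomic replicates per species.
#' @param n_metabolite_reps_per_species metabolite samples per species.
#' @param coupling_rho target Spearman correlation between transcript and
#'   protein latent abundance within a species, in \[0, 1\].
#' @param frac_de fraction of shared loci given a species-specific effect.
#'   The default 0.2 matches the order of differential-expression rates
#'   observed between closely related species.
#' @param de_log2fc injected effect size (log2 units), applied to both
#'   layers.
#' @param count_depth expected total spectral counts per replicate; the
#'   default gives about 50 expected counts per protein.
#' @param noise_sd log2-scale replicate noise (arrays and proteomic
#'   replicates), beyond counting noise.
#' @param sd_base log2 SD of baseline abundance across loci.
#' @param sd_species log2 SD of species-specific deviations shared by both
#'   layers (drives between-species correlation structure).
#' @param metabolite_cv log-scale coefficient of variation of metabolite
#'   concentrations between individual plants.
#' @param overdispersion negative-binomial over-dispersion of spectral
#'   counts (0 = Poisson, the default).
#' @param pathway_loci when `TRUE` (default, three-species designs only)
#'   the canonical glucosinolate-pathway loci (AOP2, AOP3, MAM1, MAM-I,
#'   MAM-D, ESP, ESM1) are placed in the shared set with layer-specific
#'   regulation mirroring the chemotype differences of the default
#'   metabolite means, so the chemotype rule engine has matching evidence.
#' @param seed integer root seed; all component streams derive from it.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_species = 3,
                       n_genes_transcript = 9404,
                       n_genes_protein = 1489,
                       n_shared = 1074,
                       n_array_samples_per_species = 3,
                       n_protein_reps_per_species = 3,
                       n_metabolite_reps_per_species = 12,
                       coupling_rho = 0.5,
                       frac_de = 0.2,
                       de_log2fc = 2,
                       count_depth = 50 * n_genes_protein,
                       noise_sd = 0.15,
                       sd_base = 1.0,
                       sd_species = 0.5,
                       metabolite_cv = 0.2,
                       overdispersion = 0,
                       pathway_loci = TRUE,
                       seed = 1L) {
  cfg <- list(n_species = n_species,
              n_genes_transcript = n_genes_transcript,
              n_genes_protein = n_genes_protein,
              n_shared = n_shared,
              n_array_samples_per_species = n_array_samples_per_species,
              n_protein_reps_per_species = n_protein_reps_per_species,
              n_metabolite_reps_per_species = n_metabolite_reps_per_species,
              coupling_rho = coupling_rho, frac_de = frac_de,
              de_log2fc = de_log2fc, count_depth = count_depth,
              noise_sd = noise_sd, sd_base = sd_base,
              sd_species = sd_species, metabolite_cv = metabolite_cv,
              overdispersion = overdispersion,
              pathway_loci = isTRUE(pathway_loci), seed = as.integer(seed))
  counts <- c("n_species", "n_genes_transcript", "n_genes_protein",
              "n_shared", "n_array_samples_per_species",
              "n_protein_reps_per_species", "n_metabolite_reps_per_species")
  for (f in counts) {
    if (!is_count(cfg[[f]])) stop_config(f, " must be a positive integer")
  }
  if (cfg$n_shared > min(cfg$n_genes_transcript, cfg$n_genes_protein)) {
    stop_config("n_shared exceeds a universe size")
  }
  if (!is_prob(cfg$coupling_rho)) stop_config("coupling_rho must be in [0, 1]")
  if (!is_prob(cfg$frac_de)) stop_config("frac_de must be in [0, 1]")
  if (cfg$count_depth <= 0) stop_config("count_depth must be positive")
  if (cfg$noise_sd < 0 || cfg$metabolite_cv < 0 || cfg$overdispersion < 0) {
    stop_config("noise parameters must be non-negative")
  }
  cfg$species <- if (n_species == 3) c("CH", "EX", "NZ") else
    paste0("S", seq_len(n_species))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "Simulation config: %d species (%s), %d transcript / %d protein loci ",
    "(%d shared)\n  %d arrays, %d protein reps, %d metabolite reps per ",
    "species; coupling rho %.2f, %.0f%% DE at log2FC %.1f; seed %d\n"),
    x$n_species, paste(x$species, collapse = ", "), x$n_genes_transcript,
    x$n_genes_protein, x$n_shared, x$n_array_samples_per_species,
    x$n_protein_reps_per_species, x$n_metabolite_reps_per_species,
    x$coupling_rho, 100 * x$frac_de, x$de_log2fc, x$seed))
  invisible(x)
}

#' Sample spectral counts from latent protein abundance
#'
#' Draws integer spectral counts whose expectation is proportional to
#' abundance times molecular weight (larger proteins yield more peptides and
#' spectra), scaled to the requested sequencing depth; NSAF computed on such
#' counts therefore recovers relative abundance. Counts are Poisson, or
#' negative binomial when over-dispersion is positive. Uses the caller's RNG
#' stream.
#'
#' @param abundance non-negative linear-scale abundances per locus.
#' @param mw molecular weights in kDa, strictly positive.
#' @param depth expected total counts for the sample.
#' @param overdispersion NB over-dispersion (variance = mu + od * mu^2);
#'   0 gives Poisson.
#' @return integer vector of counts, names taken from `abundance`.
#' @export
sample_spectral_counts <- function(abundance, mw, depth, overdispersion = 0) {
  if (any(mw <= 0)) stop_data("molecular weights must be positive")
  if (any(abundance < 0)) stop_data("abundances must be non-negative")
  tot <- sum(abundance * mw)
  if (tot == 0) {
    return(stats::setNames(integer(length(abundance)), names(abundance)))
  }
  mu <- depth * abundance * mw / tot
  cnt <- if (overdispersion > 0) {
    stats::rnbinom(length(mu), mu = mu, size = 1 / overdispersion)
  } else {
    stats::rpois(length(mu), mu)
  }
  stats::setNames(as.integer(cnt), names(abundance))
}

#' Default glucosinolate chemotype means per species
#'
#' Species mean concentrations (umol/g dry weight) over the fourteen
#' profiled glucosinolates, chosen so that two of the three species share
#' their major alkenyl compounds (allyl and S-2-hydroxy-3-butenyl) while the
#' third accumulates methylsulfinyl and long-chain compounds instead, with
#' class totals of 85 vs 77.8 umol/g alkenyl and 48 vs 59 umol/g C4 in the
#' two alkenyl-producing species.
#'
#' @param species species labels; the first three receive the distinct
#'   profiles (further species recycle them).
#' @return numeric matrix, 14 compounds x species.
#' @export
default_chemotypes <- function(species = c("CH", "EX", "NZ")) {
  ann <- compound_annotations()
  m <- matrix(0, nrow(ann), length(species),
              dimnames = list(ann$compound, species))
  profiles <- list(
    c(allyl = 37, `S-2OH3-butenyl` = 48, `3MSOP` = 1,
      `4OHI3M` = 1.5, `1MOI3M` = 0.8, `4MOI3M` = 0.7),
    c(`3MSOP` = 30, `3MTP` = 5, `6MSOH` = 10, `7MTH` = 3, `7MSOH` = 8,
      `8MSOO` = 6, `4OHI3M` = 2, `1MOI3M` = 1, `4MOI3M` = 1),
    c(allyl = 24.8, `S-2OH3-butenyl` = 45, `3-butenyl` = 8, `4MTB` = 4,
      `4MSOB` = 2, `3MTP` = 1.5, `4OHI3M` = 1.2, `1MOI3M` = 0.6,
      `4MOI3M` = 0.5)
  )
  for (j in seq_along(species)) {
    pr <- profiles[[(j - 1) %% 3 + 1]]
    m[names(pr), j] <- pr
  }
  m
}

#' Generate metabolite profiles around species chemotype means
#'
#' Per-sample concentrations are the species chemotype mean under
#' multiplicative log-normal noise, mean-corrected so that species means
#' converge to the configured chemotype (`conc = mean * exp(cv*Z - cv^2/2)`).
#' A compound with mean zero is exactly zero in every sample of that
#' species. Uses the caller's RNG stream.
#'
#' @param config a [sim_config].
#' @param chemotype_means compounds x species matrix of class means;
#'   defaults to [default_chemotypes()].
#' @return a [metabolite_profile] with
#'   `n_metabolite_reps_per_species` samples per species.
#' @export
generate_metabolite_profiles <- function(config,
                                         chemotype_means = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(chemotype_means)) {
    chemotype_means <- default_chemotypes(config$species)
  }
  if (any(chemotype_means < 0)) stop_config("chemotype means must be non-negative")
  cv <- config$metabolite_cv
  nrep <- config$n_metabolite_reps_per_species
  cols <- lapply(config$species, function(s) {
    sapply(seq_len(nrep), function(r) {
      chemotype_means[, s] * exp(cv * stats::rnorm(nrow(chemotype_means)) -
                                 cv^2 / 2)
    })
  })
  conc <- do.call(cbind, cols)
  colnames(conc) <- as.vector(vapply(config$species, function(s)
    sprintf("%s_m%02d", s, seq_len(nrep)), character(nrep)))
  rownames(conc) <- rownames(chemotype_means)
  metabolite_profile(conc, species = rep(config$species, each = nrep))
}

# study-like regulation of the canonical glucosinolate pathway loci:
# side-chain modification transcripts up in CH, chain-elongation and
# epithiospecifier proteins up in NZ, epithiospecifier-modifier transcript up
# in EX; MAM-I carries the transcript/protein conflict
pathway_regulation <- function(config) {
  empty <- data.frame(locus = character(), species = character(),
                      layer = character(), sign = numeric())
  if (!config$pathway_loci || !identical(config$species, c("CH", "EX", "NZ")) ||
      config$n_shared < 8) {
    return(empty)
  }
  data.frame(
    locus = c("At4g03050", "At4g03060", "At5g23010", "At2g43100",
              "At2g43100", "At5g14200", "At1g31180", "At1g54040",
              "At3g14210"),
    species = c("CH", "CH", "CH", "CH", "NZ", "NZ", "NZ", "NZ", "EX"),
    layer = c("T", "T", "T", "T", "P", "P", "P", "P", "T"),
    sign = 1,
    stringsAsFactors = FALSE)
}

# deterministic child seeds so adding a component never perturbs another
component_seeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 6),
                  c("ids", "latent", "transcript", "counts", "peptides",
                    "metabolite"))
}

#' Generate a synthetic multi-species multi-omics dataset
#'
#' Simulates coupled transcriptome, proteome and metabolome data with known
#' ground truth. Per-locus baseline log2 abundance and species-specific
#' deviations define the transcript latent layer; the protein latent layer
#' mixes it with independent variation using the bivariate-normal weight
#' `rho_pearson = 2*sin(pi*coupling_rho/6)` so the within-species Spearman
#' correlation between layers targets `coupling_rho`. A fraction of shared
#' loci receives a species-specific shift of `de_log2fc` (random sign,
#' recorded in the truth table) applied to both layers; regulated loci have
#' their incidental species deviations zeroed so the injected shift is the
#' exact between-species difference in the latent means. Arrays add Gaussian
#' log2 noise; spectral counts are drawn per replicate with
#' [sample_spectral_counts()]; metabolite profiles come from
#' [generate_metabolite_profiles()].
#'
#' @param config a [sim_config].
#' @param chemotype_means optional compounds x species means for the
#'   metabolite layer.
#' @return object of class `synthetic_dataset`: list with `transcript`
#'   (matrix genes x arrays with `species` attribute), `spectral_counts`
#'   (an [spc_table]), `metabolites` (a [metabolite_profile]), `truth`
#'   (data.frame: locus, in_transcript, in_protein, shared, de_species,
#'   direction, log2fc, layer — `"both"` for generic injected regulation,
#'   `"T"`/`"P"` for layer-specific pathway loci), `pathway` (the injected
#'   pathway-locus regulation), `latent` (list of transcript/protein latent
#'   matrices over the shared loci) and `config`.
#' @export
generate_dataset <- function(config = sim_config(), chemotype_means = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- component_seeds(config$seed)
  S <- config$species

  # locus universes
  set.seed(seeds[["ids"]])
  n_total <- config$n_genes_transcript +
    (config$n_genes_protein - config$n_shared)
  num <- sample.int(99999L, n_total)
  chr <- sample.int(5L, n_total, replace = TRUE)
  ids <- sprintf("At%dg%05d", chr, num)
  pathway <- pathway_regulation(config)
  if (nrow(pathway)) {
    # canonical pathway loci take the first shared slots (ids are unique:
    # random draws colliding with a canonical id are overwritten in place)
    ids <- ids[!ids %in% pathway$locus]
    ids <- c(unique(pathway$locus), ids)[seq_len(n_total)]
  }
  shared <- ids[seq_len(config$n_shared)]
  t_only <- ids[config$n_shared + seq_len(config$n_genes_transcript -
                                          config$n_shared)]
  p_only <- if (n_total > config$n_genes_transcript) {
    ids[(config$n_genes_transcript + 1):n_total]
  } else character(0)
  t_ids <- c(shared, t_only)
  p_ids <- c(shared, p_only)

  # latent layers and injected regulation
  set.seed(seeds[["latent"]])
  base <- stats::setNames(stats::rnorm(n_total, 7, config$sd_base), ids)
  sdev <- matrix(stats::rnorm(n_total * length(S), 0, config$sd_species),
                 n_total, dimnames = list(ids, S))
  # protein-layer mixing noise: a locus component shared across species plus
  # a species component, in the same proportion as in the transcript layer,
  # so species proteomes diverge more than transcriptomes (the independent
  # noise is the larger variance share) and sd_species = 0 gives a true null
  sigma_t <- sqrt(config$sd_base^2 + config$sd_species^2)
  phi <- config$sd_species^2 / sigma_t^2
  eta_locus <- stats::rnorm(n_total)
  xi <- matrix(stats::rnorm(n_total * length(S)), n_total,
               dimnames = list(ids, S))

  n_de <- round(config$frac_de * config$n_shared)
  de_loci <- sample(shared, n_de)
  de_species <- sample(S, n_de, replace = TRUE)
  de_sign <- sample(c(-1, 1), n_de, replace = TRUE)
  if (nrow(pathway)) {
    de_keep <- !de_loci %in% pathway$locus
    de_loci <- de_loci[de_keep]
    de_species <- de_species[de_keep]
    de_sign <- de_sign[de_keep]
    n_de <- length(de_loci)
  }
  # regulated loci (injected or pathway) carry exactly the configured shift:
  # their incidental species deviations are zeroed in both layers
  fixed <- unique(c(de_loci, pathway$locus))
  sdev[fixed, ] <- 0
  xi[fixed, ] <- 0

  t_latent0 <- base + sdev
  # Spearman target via the bivariate-normal rank-correlation identity
  rho_p <- 2 * sin(pi * config$coupling_rho / 6)
  eta <- (sqrt(1 - phi) * eta_locus + sqrt(phi) * xi) * sigma_t
  p_latent0 <- 7 + rho_p * (t_latent0 - 7) + sqrt(1 - rho_p^2) * eta
  effect <- matrix(0, n_total, length(S), dimnames = list(ids, S))
  effect[cbind(de_loci, de_species)] <- de_sign * config$de_log2fc
  t_latent <- t_latent0 + effect
  p_latent <- p_latent0 + effect
  for (i in seq_len(nrow(pathway))) {
    shift <- pathway$sign[i] * config$de_log2fc
    if (pathway$layer[i] %in% c("T", "both")) {
      t_latent[pathway$locus[i], pathway$species[i]] <-
        t_latent[pathway$locus[i], pathway$species[i]] + shift
    }
    if (pathway$layer[i] %in% c("P", "both")) {
      p_latent[pathway$locus[i], pathway$species[i]] <-
        p_latent[pathway$locus[i], pathway$species[i]] + shift
    }
  }

  # transcript arrays
  set.seed(seeds[["transcript"]])
  n_arr <- config$n_array_samples_per_species
  tmat <- do.call(cbind, lapply(S, function(s) {
    sapply(seq_len(n_arr), function(a) {
      t_latent[t_ids, s] + stats::rnorm(length(t_ids), 0, config$noise_sd)
    })
  }))
  colnames(tmat) <- as.vector(vapply(S, function(s)
    sprintf("%s_a%d", s, seq_len(n_arr)), character(n_arr)))
  rownames(tmat) <- t_ids
  attr(tmat, "species") <- stats::setNames(rep(S, each = n_arr),
                                           colnames(tmat))

  # proteomic replicates
  set.seed(seeds[["counts"]])
  mw <- stats::setNames(stats::rlnorm(length(p_ids), log(40), 0.4), p_ids)
  n_rep <- config$n_protein_reps_per_species
  cmat <- do.call(cbind, lapply(S, function(s) {
    sapply(seq_len(n_rep), function(r) {
      lat <- p_latent[p_ids, s] + stats::rnorm(length(p_ids), 0,
                                               config$noise_sd)
      sample_spectral_counts(2^lat, mw, config$count_depth,
                             config$overdispersion)
    })
  }))
  colnames(cmat) <- as.vector(vapply(S, function(s)
    sprintf("%s_r%d", s, seq_len(n_rep)), character(n_rep)))
  rownames(cmat) <- p_ids
  set.seed(seeds[["peptides"]])
  npep <- 1L + stats::rpois(length(p_ids), 4)
  spc <- spc_table(cmat, mw, npep, rep(S, each = n_rep))

  # metabolite layer
  set.seed(seeds[["metabolite"]])
  metab <- generate_metabolite_profiles(config, chemotype_means)

  truth <- data.frame(
    locus = ids,
    in_transcript = ids %in% t_ids,
    in_protein = ids %in% p_ids,
    shared = ids %in% shared,
    de_species = NA_character_, direction = NA_character_,
    log2fc = 0, layer = NA_character_, stringsAsFactors = FALSE)
  idx <- match(de_loci, truth$locus)
  truth$de_species[idx] <- de_species
  truth$direction[idx] <- ifelse(de_sign > 0, "up", "down")
  truth$log2fc[idx] <- de_sign * config$de_log2fc
  truth$layer[idx] <- "both"
  if (nrow(pathway)) {
    truth <- truth[!truth$locus %in% pathway$locus, , drop = FALSE]
    truth <- rbind(truth, data.frame(
      locus = pathway$locus, in_transcript = TRUE, in_protein = TRUE,
      shared = TRUE, de_species = pathway$species,
      direction = ifelse(pathway$sign > 0, "up", "down"),
      log2fc = pathway$sign * config$de_log2fc, layer = pathway$layer,
      stringsAsFactors = FALSE))
    rownames(truth) <- NULL
  }

  structure(list(transcript = tmat, spectral_counts = spc,
                 metabolites = metab, truth = truth, pathway = pathway,
                 latent = list(transcript = t_latent[shared, , drop = FALSE],
                               protein = p_latent[shared, , drop = FALSE]),
                 config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic multi-omics dataset\n")
  cat(sprintf("  transcript: %d genes x %d arrays\n",
              nrow(x$transcript), ncol(x$transcript)))
  cat(sprintf("  proteome: %d proteins x %d replicates\n",
              nrow(x$spectral_counts$counts), ncol(x$spectral_counts$counts)))
  cat(sprintf("  metabolome: %d compounds x %d samples\n",
              nrow(x$metabolites$conc), ncol(x$metabolites$conc)))
  cat(sprintf("  injected DE loci: %d\n", sum(!is.na(x$truth$de_species))))
  invisible(x)
}
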