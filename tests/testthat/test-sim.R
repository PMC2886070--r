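test_that("sim_config validates its parameters", {
  cfg <- sim_config()
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$species, c("CH", "EX", "NZ"))
  expect_equal(cfg$n_shared, 1074)
  expect_equal(sim_config(n_species = 2)$species, c("S1", "S2"))
  expect_error(sim_config(n_shared = 2000, n_genes_protein = 1489),
               "exceeds")
  expect_error(sim_config(coupling_rho = 1.2), "coupling_rho")
  expect_error(sim_config(frac_de = -0.1), "frac_de")
  expect_error(sim_config(n_genes_protein = 0), "positive integer")
  expect_error(sim_config(noise_sd = -1), "non-negative")
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(n_genes_transcript = 200, n_genes_protein = 150,
                    n_shared = 100, seed = 42)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$transcript, d2$transcript)
  expect_identical(d1$spectral_counts$counts, d2$spectral_counts$counts)
  expect_identical(d1$metabolites$conc, d2$metabolites$conc)
  expect_identical(d1$truth, d2$truth)
  d3 <- generate_dataset(sim_config(n_genes_transcript = 200,
                                    n_genes_protein = 150,
                                    n_shared = 100, seed = 43))
  expect_false(identical(d1$transcript, d3$transcript))
})

test_that("dataset dimensions and truth table are internally consistent", {
  cfg <- sim_config(n_genes_transcript = 300, n_genes_protein = 220,
                    n_shared = 150, frac_de = 0.2, seed = 5)
  ds <- generate_dataset(cfg)
  expect_equal(dim(ds$transcript), c(300, 9))
  expect_equal(dim(ds$spectral_counts$counts), c(220, 9))
  expect_equal(ncol(ds$metabolites$conc), 36)
  # truth has one row per locus except pathway loci with claims in both
  # layers, so count universes on de-duplicated loci
  u <- ds$truth[!duplicated(ds$truth$locus), ]
  expect_equal(sum(u$in_transcript), 300)
  expect_equal(sum(u$in_protein), 220)
  expect_equal(sum(u$shared), 150)
  expect_true(all(grepl("^At[1-5]g\\d{5}$", ds$truth$locus)))
  de <- ds$truth[!is.na(ds$truth$de_species), ]
  expect_true(all(de$shared))
  expect_true(all(abs(de$log2fc) == cfg$de_log2fc))
  # DE rows are the generic injections plus one row per pathway claim
  expect_equal(nrow(de), sum(de$layer == "both") + nrow(ds$pathway))
  # pathway loci sit in the shared set with layer-specific truth
  expect_true(all(ds$pathway$locus %in% ds$truth$locus[ds$truth$shared]))
  expect_true(all(ds$truth$layer[!is.na(ds$truth$layer)] %in%
                  c("both", "T", "P")))
})

test_that("injected shifts appear exactly in the latent means", {
  cfg <- sim_config(n_genes_transcript = 400, n_genes_protein = 300,
                    n_shared = 200, frac_de = 0.15, pathway_loci = FALSE,
                    seed = 11)
  ds <- generate_dataset(cfg)
  de <- ds$truth[!is.na(ds$truth$de_species), ]
  for (i in seq_len(nrow(de))) {
    lt <- ds$latent$transcript[de$locus[i], ]
    lp <- ds$latent$protein[de$locus[i], ]
    other <- setdiff(cfg$species, de$de_species[i])
    # the regulated species differs from both others by exactly log2fc
    expect_equal(unname(lt[de$de_species[i]] - lt[other]),
                 rep(de$log2fc[i], 2), tolerance = 1e-12)
    expect_equal(unname(lp[de$de_species[i]] - lp[other]),
                 rep(de$log2fc[i], 2), tolerance = 1e-12)
  }
})

test_that("degenerate noiseless configuration couples the layers perfectly", {
  cfg <- sim_config(n_genes_transcript = 250, n_genes_protein = 250,
                    n_shared = 250, noise_sd = 0, coupling_rho = 1,
                    frac_de = 0, pathway_loci = FALSE, seed = 3)
  ds <- generate_dataset(cfg)
  for (s in cfg$species) {
    expect_equal(cor(ds$latent$transcript[, s], ds$latent$protein[, s],
                     method = "spearman"), 1)
  }
  # zero array noise: arrays equal the latent values exactly
  expect_equal(unname(ds$transcript[, "CH_a1"]),
               unname(ds$latent$transcript[rownames(ds$transcript), "CH"]))
})

test_that("latent Spearman coupling hits the configured target", {
  rhos <- vapply(1:20, function(s) {
    cfg <- sim_config(n_genes_transcript = 1000, n_genes_protein = 1000,
                      n_shared = 1000, coupling_rho = 0.5, frac_de = 0,
                      pathway_loci = FALSE, seed = s)
    ds <- generate_dataset(cfg)
    mean(vapply(cfg$species, function(sp) {
      cor(ds$latent$transcript[, sp], ds$latent$protein[, sp],
          method = "spearman")
    }, numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(rhos) - 0.5), 0.05)
})

test_that("spectral-count sampling honours the abundance-times-weight expectation", {
  set.seed(1)
  expect_equal(unname(sample_spectral_counts(c(0, 0), c(10, 20), 100)),
               c(0L, 0L))
  # equal abundance, MW 10 vs 20 kDa: expected count ratio 1:2
  cnt <- sample_spectral_counts(c(a = 1, b = 1), c(10, 20), 3e5)
  expect_lt(abs(cnt[["b"]] / cnt[["a"]] - 2), 0.05)
  # single locus: sampled-table NSAF is 1
  one <- sample_spectral_counts(c(x = 3), 50, 200)
  expect_equal(unname(compute_nsaf(one, 50)), 1)
  expect_error(sample_spectral_counts(c(1, 2), c(0, 1), 10), "positive")
  expect_error(sample_spectral_counts(c(-1, 2), c(1, 1), 10), "non-negative")
  # overdispersed counts inflate the variance beyond Poisson
  set.seed(2)
  pois <- replicate(400, sample_spectral_counts(c(x = 1), 10, 50)[["x"]])
  nb <- replicate(400, sample_spectral_counts(c(x = 1), 10, 50,
                                              overdispersion = 0.5)[["x"]])
  expect_gt(var(nb), 2 * var(pois))
})

test_that("metabolite generation reproduces the chemotype means", {
  cfg <- sim_config(metabolite_cv = 0, seed = 1)
  pr <- generate_metabolite_profiles(cfg)
  means <- default_chemotypes()
  for (s in cfg$species) {
    cols <- names(pr$species)[pr$species == s]
    for (cl in cols) expect_equal(unname(pr$conc[, cl]), unname(means[, s]))
  }
  # zero-mean compound stays exactly zero under noise
  cfg2 <- sim_config(metabolite_cv = 0.4, seed = 2)
  set.seed(7)
  pr2 <- generate_metabolite_profiles(cfg2)
  ex_cols <- names(pr2$species)[pr2$species == "EX"]
  expect_true(all(pr2$conc["allyl", ex_cols] == 0))
  # class totals of the defaults match the design: alkenyl 85 vs 77.8,
  # C4 48 vs 59, none in EX
  ann <- compound_annotations()
  alk <- colSums(means[ann$compound[ann$alkenyl], ])
  c4 <- colSums(means[ann$compound[ann$chain_class == "C4"], ])
  expect_equal(unname(alk), c(85, 0, 77.8))
  expect_equal(unname(c4), c(48, 0, 59))
})

test_that("CH and NZ metabolite samples cluster apart from EX", {
  cfg <- sim_config(seed = 19)
  set.seed(19)
  pr <- generate_metabolite_profiles(cfg)
  h <- cluster_profiles(to_proportions(pr))
  grp <- cutree(h, k = 2)
  sp <- substr(names(grp), 1, 2)
  # one cluster is exactly the EX samples
  tab <- table(sp, grp)
  ex_cluster <- which.max(tab["EX", ])
  expect_equal(sum(tab[, ex_cluster]), tab["EX", ex_cluster])
  expect_equal(unname(tab["EX", ex_cluster]), cfg$n_metabolite_reps_per_species)
})
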