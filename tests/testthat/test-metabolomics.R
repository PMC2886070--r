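test_that("to_proportions normalizes per sample", {
  m1 <- matrix(5, 1, 1, dimnames = list("allyl", "s1"))
  expect_equal(unname(to_proportions(m1)), matrix(1))
  m2 <- matrix(c(2, 2), 2, 1, dimnames = list(c("allyl", "3MSOP"), "s1"))
  expect_equal(unname(to_proportions(m2)[, 1]), c(0.5, 0.5))
  m3 <- matrix(1:4, 4, 1, dimnames = list(paste0("c", 1:4), "s1"))
  expect_equal(unname(to_proportions(m3)[, 1]), c(0.1, 0.2, 0.3, 0.4))
  m4 <- cbind(s1 = c(1, 1), s2 = c(0, 0))
  rownames(m4) <- c("a", "b")
  expect_warning(pr <- to_proportions(m4), "zero-total")
  expect_equal(colnames(pr), "s1")
  expect_error(to_proportions(matrix(-1)), "negative")
})

test_that("metabolite_profile validates annotations and species assignment", {
  conc <- matrix(c(1, 2), 2, 1,
                 dimnames = list(c("allyl", "4MTB"), "CH_m01"))
  pr <- metabolite_profile(conc, species = "CH")
  expect_s3_class(pr, "metabolite_profile")
  expect_equal(pr$annotations$compound, c("allyl", "4MTB"))
  expect_true(pr$annotations$alkenyl[1])
  rownames(conc)[1] <- "mystery"
  expect_error(metabolite_profile(conc, species = "CH"), "unannotated")
  rownames(conc)[1] <- "allyl"
  expect_error(metabolite_profile(conc, species = c("CH", "NZ")),
               "every sample")
  expect_error(metabolite_profile(-conc, species = "CH"), "negative")
})

test_that("Ward clustering follows the minimum-variance criterion", {
  # identical samples merge first at height 0
  m <- cbind(s1 = c(0.5, 0.5), s2 = c(0.5, 0.5), s3 = c(0.9, 0.1))
  h <- cluster_profiles(m)
  expect_equal(h$height[1], 0)
  expect_equal(sort(h$labels[-h$merge[1, ]]), c("s1", "s2"))
  # d(AB)=1, d(AC)=d(BC)=10: A and B merge first
  m2 <- cbind(A = c(0, 0), B = c(1, 0), C = c(0, 10))
  h2 <- cluster_profiles(m2)
  expect_equal(sort(h2$labels[-h2$merge[1, ]]), c("A", "B"))
  expect_error(cluster_profiles(m2[, 1, drop = FALSE]), "two samples")
  expect_error(cluster_profiles(cbind(A = c(1, 0), A = c(0, 1))), "duplicate")
})

test_that("Ward merge heights equal twice the ESS increase (brute-force oracle)", {
  set.seed(21)
  for (i in 1:8) {
    n <- sample(3:6, 1)
    X <- matrix(rnorm(n * 4), n, 4)
    rownames(X) <- paste0("s", 1:n)   # lexicographic == input order
    h <- cluster_profiles(t(X))
    oracle <- brute_ward_oracle(X)
    expect_equal(h$height, 2 * oracle$heights, tolerance = 1e-8)
    expect_equal(hclust_merge_sets(h), oracle$merges)
  }
})

test_that("Newick export round-trips tip labels and topology", {
  m <- cbind(A = c(0, 0), B = c(0.1, 0), C = c(5, 5), D = c(5.1, 5))
  h <- cluster_profiles(m)
  nwk <- export_newick(h)
  expect_match(nwk, "^\\(.*\\);$")
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("A", "B", "C", "D"))
  # A,B and C,D are sister pairs
  expect_true(ape::is.monophyletic(phy, c("A", "B")))
  expect_true(ape::is.monophyletic(phy, c("C", "D")))
  f <- tempfile(fileext = ".nwk")
  export_newick(h, f)
  expect_equal(readLines(f), nwk)
})

test_that("hydrolysis partition reproduces the published percentages", {
  tab <- hydrolysis_products()
  nz <- hydrolysis_partition(tab, "NZ")
  pick <- function(p, cmp) p$compounds$pct_display[p$compounds$compound == cmp]
  expect_equal(pick(nz, "goitrin"), 12.4)
  expect_equal(pick(nz, "epithio-2OH3B-I"), 21.8)
  expect_equal(pick(nz, "allyl-ITC"), 14.4)
  ch <- hydrolysis_partition(tab, "CH")
  expect_equal(pick(ch, "goitrin"), 60.7)
  expect_equal(pick(ch, "allyl-ITC"), 38.7)
  # full-precision class fractions are an exact partition
  expect_equal(sum(nz$classes$pct_full), 100)
  expect_equal(sum(ch$classes$pct_full), 100)
  # class totals are sums of the rounded compound percentages
  for (p in list(nz, ch)) {
    for (cl in p$classes$class) {
      expect_equal(p$classes$pct_rounded[p$classes$class == cl],
                   sum(p$compounds$pct_display[p$compounds$class == cl]))
    }
  }
  # nitriles dominate in NZ, isothiocyanates in CH
  expect_gt(nz$classes$pct_full[nz$classes$class == "nitrile"], 50)
  expect_gt(ch$classes$pct_full[ch$classes$class == "isothiocyanate"], 99)

  # single-product species
  one <- data.frame(species = "XX", parent = "allyl", compound = "allyl-ITC",
                    class = "isothiocyanate", mean_nmol_g = 123, sd_nmol_g = 1)
  px <- hydrolysis_partition(one, "XX")
  expect_equal(px$compounds$pct_display, 100)
  expect_error(hydrolysis_partition(tab, "EX"), "no hydrolysis data")
})

test_that("rounding convention is half away from zero, not banker's", {
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(22.5), 23)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(c(1.4, 1.6)), c(1, 2))
})

test_that("chemotype rule engine emits and flags predictions", {
  rules <- chemotype_rules()
  expect_true(all(c("At1g54040", "At3g14210", "At5g23010") %in% rules$locus))

  # empty DE tables: no predictions
  none <- predict_chemotype(de_call_table(NULL, NULL))
  expect_equal(nrow(none), 0L)

  # ESP protein up in NZ: nitriles predicted for NZ
  pde <- data.frame(locus = "At1g54040", contrast = "NZ_vs_CH+EX",
                    log2fc = 3, stat = NA, p_raw = 0.001, p_adj = 0.004,
                    call = "up")
  pr <- predict_chemotype(de_call_table(protein_de = pde))
  expect_equal(pr$species, "NZ")
  expect_equal(pr$phenotype, "nitriles_hydrolysis")
  expect_equal(pr$layer, "P")
  expect_false(any(pr$conflict))

  # MAM-I protein up in NZ but MAM1 transcript up in CH: conflicting C4 claims
  tde <- data.frame(locus = "At5g23010", contrast = "CH_vs_EX+NZ",
                    log2fc = 2, stat = 2, p_raw = 0.001, p_adj = 0.01,
                    call = "up")
  pde2 <- data.frame(locus = "At2g43100", contrast = "NZ_vs_CH+EX",
                     log2fc = 2, stat = NA, p_raw = 0.001, p_adj = 0.01,
                     call = "up")
  pr2 <- predict_chemotype(de_call_table(tde, pde2))
  expect_equal(nrow(pr2), 2L)
  expect_setequal(pr2$species, c("CH", "NZ"))
  expect_true(all(pr2$phenotype == "C4_higher"))
  expect_true(all(pr2$conflict))

  # both hydrolysis outcomes for one species are flagged
  pde3 <- rbind(pde, transform(pde, locus = "At3g14210"))
  tde3 <- data.frame(locus = "At3g14210", contrast = "NZ_vs_CH+EX",
                     log2fc = 2, stat = 2, p_raw = 0.001, p_adj = 0.01,
                     call = "up")
  pr3 <- predict_chemotype(de_call_table(tde3, pde))
  expect_setequal(pr3$phenotype,
                  c("nitriles_hydrolysis", "isothiocyanates_hydrolysis"))
  expect_true(all(pr3$conflict))
})

test_that("prediction evaluation favours the layer with correct rules", {
  set.seed(8)
  means <- default_chemotypes()
  cfg <- sim_config(seed = 8)
  profile <- generate_metabolite_profiles(cfg, means)

  # supported: nitrile fraction > 50% in NZ hydrolysis data
  good <- data.frame(species = "NZ", comparators = "CH+EX",
                     phenotype = "nitriles_hydrolysis", layer = "P",
                     locus = "At1g54040", symbol = "ESP",
                     contrast = "NZ_vs_CH+EX", note = "", conflict = FALSE)
  class(good) <- c("chemotype_predictions", "data.frame")
  ev <- evaluate_predictions(good, profile)
  expect_equal(ev$claims$status, "supported")

  # tie in class sums: untestable, not contradicted
  flat <- matrix(1, 2, 4, dimnames = list(c("allyl", "3-butenyl"),
                                          c("A_1", "A_2", "B_1", "B_2")))
  pflat <- metabolite_profile(flat, species = c("A", "A", "B", "B"))
  tie <- data.frame(species = "A", comparators = "B",
                    phenotype = "alkenyl_higher", layer = "T",
                    locus = "At4g03050", symbol = "AOP2",
                    contrast = "A_vs_B", note = "", conflict = FALSE)
  class(tie) <- c("chemotype_predictions", "data.frame")
  expect_equal(evaluate_predictions(tie, pflat)$claims$status, "untestable")

  # mirror of the study outcome: protein rules right (C4 higher in NZ,
  # nitriles in NZ), the transcript rule attributes the C4 phenotype to the
  # wrong species (CH), which the NZ comparison contradicts
  preds <- data.frame(
    species = c("NZ", "NZ", "CH"),
    comparators = c("CH+EX", "CH+EX", "EX+NZ"),
    phenotype = c("C4_higher", "nitriles_hydrolysis", "C4_higher"),
    layer = c("P", "P", "T"),
    locus = c("At2g43100", "At1g54040", "At5g23010"),
    symbol = c("MAM-I", "ESP", "MAM1"),
    contrast = c("NZ_vs_CH+EX", "NZ_vs_CH+EX", "CH_vs_EX+NZ"),
    note = "", conflict = FALSE)
  class(preds) <- c("chemotype_predictions", "data.frame")
  ev2 <- evaluate_predictions(preds, profile)
  expect_gt(ev2$accuracy[["P_layer"]], ev2$accuracy[["T_layer"]])
  # the CH-vs-EX half of the transcript claim holds (EX lacks C4 compounds),
  # but NZ's higher C4 content contradicts the CH-vs-NZ half
  tcl <- ev2$claims[ev2$claims$layer == "T", ]
  expect_equal(tcl$status[tcl$comparator == "EX"], "supported")
  expect_equal(tcl$status[tcl$comparator == "NZ"], "contradicted")
})
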