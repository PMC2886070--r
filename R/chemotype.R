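#' Bundled glucosinolate chemotype rules
#'
#' Maps differential regulation of glucosinolate-pathway loci (side-chain
#' elongation: MAM1, MAM-I, MAM-D; side-chain modification: AOP2, AOP3;
#' hydrolysis specifiers: ESP, ESM1) to predicted metabolite phenotypes. The
#' table is editable TSV: each row says that a locus called in `direction`
#' on evidence layer `layer` (`T` transcript, `P` protein) in some species
#' predicts `phenotype` for that species.
#'
#' @param path optional path to an alternative rule TSV.
#' @return data.frame with columns `locus`, `symbol`, `layer`, `direction`,
#'   `phenotype`, `note`.
#' @export
chemotype_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "glucosinolate_rules.tsv",
                        package = "omicsconcord", mustWork = TRUE)
  }
  r <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus", "symbol", "layer", "direction", "phenotype")
  if (!all(need %in% names(r))) {
    stop_data("malformed rule table; need columns ",
              paste(need, collapse = ", "))
  }
  if (any(!grepl("^At[1-5Mg]g\\d{5}$", r$locus))) {
    stop_data("malformed AGI locus id in rule table")
  }
  if (!"note" %in% names(r)) r$note <- ""
  r$note[is.na(r$note)] <- ""
  r
}

#' Combine differential-expression tables into a call table
#'
#' Stacks DE tables from the transcript and protein layers into the flat
#' call table consumed by [predict_chemotype()]. The target and comparator
#' species are parsed from the contrast names (`"<target>_vs_<o1>+<o2>"`).
#'
#' @param transcript_de,protein_de DE data.frames (may be `NULL`).
#' @return data.frame with columns `locus`, `layer`, `target`, `others`,
#'   `contrast`, `call`, keeping only up/down calls.
#' @export
de_call_table <- function(transcript_de = NULL, protein_de = NULL) {
  stack <- function(d, layer) {
    if (is.null(d) || nrow(d) == 0) return(NULL)
    d <- d[d$call %in% c("up", "down"), , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    parts <- strsplit(d$contrast, "_vs_", fixed = TRUE)
    data.frame(locus = d$locus, layer = layer,
               target = vapply(parts, `[`, "", 1),
               others = vapply(parts, `[`, "", 2),
               contrast = d$contrast, call = d$call,
               row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- rbind(stack(transcript_de, "T"), stack(protein_de, "P"))
  if (is.null(out)) {
    out <- data.frame(locus = character(), layer = character(),
                      target = character(), others = character(),
                      contrast = character(), call = character())
  }
  out
}

#' Predict chemotypes from differential expression of pathway loci
#'
#' Applies a chemotype rule table to a differential-expression call table:
#' every rule whose locus is called in the rule's direction on the rule's
#' evidence layer emits a phenotype claim for the target species of that
#' contrast. Conflicting claims (the same class-abundance phenotype claimed
#' for different species, or both hydrolysis outcomes claimed for one
#' species) are all emitted and flagged rather than resolved.
#'
#' @param de_calls a call table from [de_call_table()].
#' @param rules a rule table from [chemotype_rules()].
#' @return data.frame of class `chemotype_predictions` with columns
#'   `species`, `comparators`, `phenotype`, `layer`, `locus`, `symbol`,
#'   `contrast`, `note`, `conflict`.
#' @export
predict_chemotype <- function(de_calls, rules = chemotype_rules()) {
  rules <- if (is.data.frame(rules)) rules else chemotype_rules(rules)
  preds <- lapply(seq_len(nrow(rules)), function(i) {
    r <- rules[i, ]
    hit <- de_calls[de_calls$locus == r$locus & de_calls$layer == r$layer &
                    de_calls$call == r$direction, , drop = FALSE]
    if (nrow(hit) == 0) return(NULL)
    data.frame(species = hit$target, comparators = hit$others,
               phenotype = r$phenotype, layer = r$layer, locus = r$locus,
               symbol = r$symbol, contrast = hit$contrast, note = r$note,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  preds <- do.call(rbind, preds)
  if (is.null(preds)) {
    preds <- data.frame(species = character(), comparators = character(),
                        phenotype = character(), layer = character(),
                        locus = character(), symbol = character(),
                        contrast = character(), note = character())
  }
  preds$conflict <- logical(nrow(preds))
  higher <- grepl("_higher$", preds$phenotype)
  for (ph in unique(preds$phenotype[higher])) {
    rows <- preds$phenotype == ph
    if (length(unique(preds$species[rows])) > 1) preds$conflict[rows] <- TRUE
  }
  hyd <- preds$phenotype %in% c("nitriles_hydrolysis",
                                "isothiocyanates_hydrolysis")
  for (s in unique(preds$species[hyd])) {
    rows <- hyd & preds$species == s
    if (length(unique(preds$phenotype[rows])) > 1) preds$conflict[rows] <- TRUE
  }
  class(preds) <- c("chemotype_predictions", "data.frame")
  preds
}

#' @export
print.chemotype_predictions <- function(x, ...) {
  cat(sprintf("Chemotype predictions: %d claim(s), %d flagged conflicting\n",
              nrow(x), sum(x$conflict)))
  if (nrow(x)) print.data.frame(x[, c("species", "phenotype", "layer",
                                      "symbol", "contrast", "conflict")])
  invisible(x)
}

# annotation-driven compound selection per class phenotype
phenotype_compounds <- function(phenotype, ann) {
  switch(phenotype,
    alkenyl_higher = ann$compound[ann$alkenyl],
    C4_higher = ann$compound[ann$chain_class == "C4"],
    hydroxyalkyl_higher =
      ann$compound[grepl("hydroxy", ann$name) & !ann$alkenyl],
    stop_data("unknown class phenotype: ", phenotype))
}

#' Evaluate chemotype predictions against measured profiles
#'
#' Each class-abundance prediction ("species A has higher X than B and C")
#' is expanded into one claim per comparator species and tested on the
#' per-sample class sums with a two-sided Welch t-test: a claim is
#' `supported` when the target's class sum is significantly higher,
#' `contradicted` when significantly lower, and `untestable` otherwise
#' (including exact ties). Hydrolysis predictions are checked against the
#' dominant product class (> 50% of total product content) of the species in
#' the hydrolysis table; species without hydrolysis data are `untestable`.
#' Per-layer accuracy is supported / (supported + contradicted) over claims.
#'
#' @param predictions a [predict_chemotype()] result.
#' @param profile a [metabolite_profile].
#' @param hydrolysis a hydrolysis table ([hydrolysis_products()]).
#' @param alpha significance level for the class-sum comparisons.
#' @return object of class `chemotype_eval`: list with `claims` (data.frame)
#'   and `accuracy` (named numeric per layer, `NaN` when no claim was
#'   testable).
#' @export
evaluate_predictions <- function(predictions, profile,
                                 hydrolysis = hydrolysis_products(),
                                 alpha = 0.05) {
  stopifnot(inherits(profile, "metabolite_profile"))
  ann <- profile$annotations
  dominant <- function(s) {
    part <- try(hydrolysis_partition(hydrolysis, s), silent = TRUE)
    if (inherits(part, "try-error")) return(NA_character_)
    ni <- part$classes$pct_full[part$classes$class == "nitrile"]
    ni <- if (length(ni)) ni else 0
    if (ni > 50) "nitrile" else if (ni < 50) "isothiocyanate" else NA_character_
  }
  claims <- lapply(seq_len(nrow(predictions)), function(i) {
    p <- predictions[i, ]
    if (p$phenotype %in% c("nitriles_hydrolysis", "isothiocyanates_hydrolysis")) {
      dom <- dominant(p$species)
      want <- if (p$phenotype == "nitriles_hydrolysis") "nitrile" else "isothiocyanate"
      status <- if (is.na(dom)) "untestable"
                else if (dom == want) "supported" else "contradicted"
      return(data.frame(species = p$species, comparator = NA_character_,
                        phenotype = p$phenotype, layer = p$layer,
                        status = status, stringsAsFactors = FALSE))
    }
    comps <- phenotype_compounds(p$phenotype, ann)
    sums <- colSums(profile$conc[rownames(profile$conc) %in% comps, ,
                                 drop = FALSE])
    comparators <- strsplit(p$comparators, "+", fixed = TRUE)[[1]]
    do.call(rbind, lapply(comparators, function(cmp) {
      sa <- sums[profile$species == p$species]
      sb <- sums[profile$species == cmp]
      status <- if (length(sa) < 2 || length(sb) < 2) {
        "untestable"
      } else {
        tp <- welch_t(sa, sb)
        if (tp[2] < alpha && mean(sa) > mean(sb)) "supported"
        else if (tp[2] < alpha && mean(sa) < mean(sb)) "contradicted"
        else "untestable"
      }
      data.frame(species = p$species, comparator = cmp,
                 phenotype = p$phenotype, layer = p$layer, status = status,
                 stringsAsFactors = FALSE)
    }))
  })
  claims <- if (length(claims)) do.call(rbind, claims) else
    data.frame(species = character(), comparator = character(),
               phenotype = character(), layer = character(),
               status = character())
  acc <- vapply(c(T_layer = "T", P_layer = "P"), function(l) {
    cl <- claims[claims$layer == l, , drop = FALSE]
    sum(cl$status == "supported") /
      sum(cl$status %in% c("supported", "contradicted"))
  }, numeric(1))
  structure(list(claims = claims, accuracy = acc), class = "chemotype_eval")
}

#' @export
print.chemotype_eval <- function(x, ...) {
  cat(sprintf("Chemotype evaluation: %d claim(s)\n", nrow(x$claims)))
  if (nrow(x$claims)) print(table(x$claims$layer, x$claims$status))
  cat(sprintf("Accuracy — transcript layer: %s, protein layer: %s\n",
              format(x$accuracy[["T_layer"]], digits = 3),
              format(x$accuracy[["P_layer"]], digits = 3)))
  invisible(x)
}
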