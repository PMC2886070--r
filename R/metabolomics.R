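#' Metabolite concentration profile
#'
#' Compound-by-sample concentration matrix with per-compound annotations
#' (side-chain class and alkenyl flag) and a recorded unit. Annotations drive
#' the class sums used when chemotype predictions are evaluated.
#'
#' @param conc numeric matrix, compounds x samples, non-negative
#'   concentrations; rownames are compound abbreviations.
#' @param annotations data.frame with columns `compound`, `chain_class`
#'   (one of `"C3"`, `"C4"`, `"long-chain"`, `"indolic"`) and `alkenyl`
#'   (logical). Defaults to the bundled glucosinolate annotation table.
#' @param species character vector assigning each sample (column) to a
#'   species.
#' @param unit concentration unit label (e.g. `"umol/g dry wt"`).
#' @return object of class `metabolite_profile`.
#' @export
metabolite_profile <- function(conc, annotations = NULL, species,
                               unit = "umol/g dry wt") {
  conc <- as.matrix(conc)
  if (any(conc < 0)) stop_data("negative metabolite concentration")
  if (is.null(rownames(conc)) || is.null(colnames(conc))) {
    stop_data("concentration matrix needs compound and sample names")
  }
  if (is.null(annotations)) annotations <- compound_annotations()
  missing_ann <- setdiff(rownames(conc), annotations$compound)
  if (length(missing_ann)) {
    stop_data("unannotated compounds: ", paste(missing_ann, collapse = ", "))
  }
  if (length(species) != ncol(conc)) {
    stop_data("species must assign every sample to a species")
  }
  structure(list(conc = conc,
                 annotations = annotations[match(rownames(conc),
                                                 annotations$compound), ],
                 species = stats::setNames(as.character(species),
                                           colnames(conc)),
                 unit = unit),
            class = "metabolite_profile")
}

#' @export
print.metabolite_profile <- function(x, ...) {
  cat(sprintf("Metabolite profile: %d compounds x %d samples (%s), unit %s\n",
              nrow(x$conc), ncol(x$conc),
              paste(sprintf("%s:%d", names(table(x$species)),
                            as.integer(table(x$species))), collapse = ", "),
              x$unit))
  invisible(x)
}

#' Bundled glucosinolate compound annotations
#'
#' Side-chain classes and alkenyl flags for the fourteen glucosinolates
#' commonly profiled in Brassicaceae leaf extracts, keyed by the standard
#' abbreviations (3MTP, 4MTB, allyl, S-2OH3-butenyl, ...).
#'
#' @return data.frame with columns `compound`, `name`, `chain_class`,
#'   `alkenyl`.
#' @export
compound_annotations <- function() {
  path <- system.file("extdata", "compound_annotations.tsv",
                      package = "omicsconcord", mustWork = TRUE)
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  ann$alkenyl <- as.logical(ann$alkenyl)
  ann
}

#' Per-sample compound proportions
#'
#' Converts concentrations to proportions of the sample's total content, the
#' scale on which chemotype profiles are clustered (so overall concentration
#' differences between individuals do not drive the dendrogram).
#'
#' @param x a [metabolite_profile] or a non-negative compounds x samples
#'   matrix.
#' @return matrix of proportions; every retained column sums to 1. Samples
#'   with zero total content are dropped with a warning.
#' @export
to_proportions <- function(x) {
  m <- if (inherits(x, "metabolite_profile")) x$conc else as.matrix(x)
  if (any(m < 0)) stop_data("negative metabolite concentration")
  tot <- colSums(m)
  if (any(tot == 0)) {
    warning("dropping zero-total sample(s): ",
            paste(colnames(m)[tot == 0], collapse = ", "))
    m <- m[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  sweep(m, 2, tot, "/")
}

#' Ward hierarchical clustering of metabolite profiles
#'
#' Agglomerative clustering of samples using Euclidean distance and Ward's
#' minimum-variance criterion (Lance-Williams update on squared distances,
#' so each merge height equals twice the increase in within-cluster error
#' sum of squares). Samples are ordered lexicographically before clustering,
#' making tie-breaks deterministic.
#'
#' @param proportions numeric matrix, compounds x samples (typically from
#'   [to_proportions()]).
#' @return an object of class `hclust`; export with [export_newick()].
#' @export
cluster_profiles <- function(proportions) {
  m <- as.matrix(proportions)
  if (ncol(m) < 2) stop_data("need at least two samples to cluster")
  if (anyDuplicated(colnames(m))) stop_data("duplicate sample ids")
  m <- m[, order(colnames(m)), drop = FALSE]
  d2 <- stats::dist(t(m))^2
  stats::hclust(d2, method = "ward.D")
}

#' Export a dendrogram as a Newick string
#'
#' @param h an `hclust` object.
#' @param file optional path; when given the tree is written there.
#' @return the Newick string, invisibly when written to file.
#' @export
export_newick <- function(h, file = NULL) {
  phy <- ape::as.phylo(h)
  if (is.null(file)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = file)
  invisible(ape::write.tree(phy))
}

#' Bundled glucosinolate hydrolysis-product measurements
#'
#' Mean concentrations (nmol/g fresh weight, with SD) of isothiocyanate and
#' nitrile/epithionitrile hydrolysis products per parent glucosinolate for
#' the two species with available plant material.
#'
#' @return data.frame with columns `species`, `parent`, `compound`, `class`
#'   (`"isothiocyanate"` or `"nitrile"`), `mean_nmol_g`, `sd_nmol_g`.
#' @export
hydrolysis_products <- function() {
  path <- system.file("extdata", "hydrolysis_products.tsv",
                      package = "omicsconcord", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Partition hydrolysis products into compound and class percentages
#'
#' Expresses each hydrolysis product as a percentage of the species' total
#' product content (rounded half-up to one decimal for display, full
#' precision retained) and sums the isothiocyanate versus
#' nitrile/epithionitrile fractions. Class totals are reported both as sums
#' of full-precision percentages and as sums of the rounded per-compound
#' percentages; displayed class totals follow the rounded-sum convention.
#'
#' @param tab a hydrolysis table as returned by [hydrolysis_products()].
#' @param species species label to partition.
#' @return list with `compounds` (data.frame: compound, class, mean, pct,
#'   pct_display) and `classes` (data.frame: class, pct_full, pct_rounded).
#' @export
hydrolysis_partition <- function(tab = hydrolysis_products(), species) {
  d <- tab[tab$species == species, , drop = FALSE]
  if (nrow(d) == 0) stop_data("no hydrolysis data for species ", species)
  total <- sum(d$mean_nmol_g)
  if (total <= 0) {
    warning("zero total hydrolysis product content; percentages undefined")
    return(list(compounds = transform(d, pct = NA_real_, pct_display = NA_real_),
                classes = data.frame(class = unique(d$class),
                                     pct_full = NA_real_, pct_rounded = NA_real_)))
  }
  pct <- 100 * d$mean_nmol_g / total
  comp <- data.frame(compound = d$compound, class = d$class,
                     mean_nmol_g = d$mean_nmol_g,
                     pct = pct, pct_display = round_half_up(pct, 1),
                     stringsAsFactors = FALSE)
  cls <- data.frame(
    class = sort(unique(d$class)),
    stringsAsFactors = FALSE
  )
  cls$pct_full <- vapply(cls$class, function(cl) sum(pct[d$class == cl]),
                         numeric(1))
  cls$pct_rounded <- vapply(cls$class, function(cl)
    sum(round_half_up(pct[d$class == cl], 1)), numeric(1))
  list(compounds = comp, classes = cls)
}
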