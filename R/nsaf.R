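#' Spectral-count table
#'
#' Container for label-free shotgun proteomics quantitation: one row per
#' protein (or locus after isoform merging), integer MS/MS spectral counts per
#' replicate, the protein molecular weight in kDa and the number of distinct
#' peptides supporting the identification. Each replicate column is assigned
#' to exactly one species.
#'
#' @param counts numeric matrix, proteins x replicates, non-negative integer
#'   spectral counts; rownames are protein identifiers (AGI locus codes,
#'   possibly with an isoform suffix such as `".1"`), colnames are replicate
#'   identifiers.
#' @param mw_kda numeric vector of molecular weights in kDa, one per row,
#'   strictly positive.
#' @param n_peptides integer vector of distinct-peptide counts, one per row.
#' @param species character vector mapping each replicate (column) to a
#'   species label; recycled names are taken from `colnames(counts)`.
#' @return an object of class `spc_table`: a list with elements `counts`,
#'   `mw_kda`, `n_peptides`, `species`.
#' @examples
#' cnt <- matrix(c(4L, 6L, 5L, 7L), 2, 2,
#'               dimnames = list(c("At1g01010", "At1g01020"), c("r1", "r2")))
#' spc_table(cnt, mw_kda = c(50, 30), n_peptides = c(3L, 2L),
#'           species = c(r1 = "CH", r2 = "CH"))
#' @export
spc_table <- function(counts, mw_kda, n_peptides, species) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      is.null(colnames(counts))) {
    stop_data("spectral-count matrix needs row (protein) and column (replicate) names")
  }
  if (any(counts < 0) || any(is.na(counts))) {
    stop_data("spectral counts must be non-negative and non-missing")
  }
  if (length(mw_kda) != nrow(counts) || any(mw_kda <= 0)) {
    stop_data("mw_kda must be positive, one value per protein")
  }
  if (length(n_peptides) != nrow(counts) || any(n_peptides < 0)) {
    stop_data("n_peptides must be non-negative, one value per protein")
  }
  if (length(species) != ncol(counts)) {
    stop_data("species must assign every replicate to a species")
  }
  species <- stats::setNames(as.character(species), colnames(counts))
  structure(
    list(counts = counts,
         mw_kda = stats::setNames(as.numeric(mw_kda), rownames(counts)),
         n_peptides = stats::setNames(as.integer(round(n_peptides)), rownames(counts)),
         species = species),
    class = "spc_table"
  )
}

#' @export
print.spc_table <- function(x, ...) {
  cat(sprintf("Spectral-count table: %d proteins x %d replicates (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s:%d", names(table(x$species)),
                            as.integer(table(x$species))), collapse = ", ")))
  cat(sprintf("Total spectra: %s; MW %.1f-%.1f kDa\n",
              format(sum(x$counts), big.mark = ","),
              min(x$mw_kda), max(x$mw_kda)))
  invisible(x)
}

#' @export
dim.spc_table <- function(x) dim(x$counts)

#' Merge protein isoforms onto their gene locus
#'
#' Spectral counts identifying more than one isoform of a gene locus are
#' combined so that downstream abundance is expressed per locus. Per-replicate
#' counts and peptide numbers are summed; the molecular weight of the merged
#' record is the spectral-count-weighted mean of the isoform weights, so a
#' dominant isoform dominates the weight (a simple mean is used when all
#' isoform counts are zero).
#'
#' @param x an [spc_table].
#' @param locus_map named character vector mapping each protein id to its
#'   locus id. By default, isoform suffixes (`".1"`, `".2"`, ...) are stripped
#'   from the row names.
#' @return an [spc_table] keyed by locus.
#' @export
combine_isoforms <- function(x, locus_map = NULL) {
  stopifnot(inherits(x, "spc_table"))
  ids <- rownames(x$counts)
  if (is.null(locus_map)) {
    locus_map <- stats::setNames(sub("\\.\\d+$", "", ids), ids)
  }
  unmapped <- setdiff(ids, names(locus_map))
  if (length(unmapped)) {
    stop_data("isoforms missing from locus map: ", paste(unmapped, collapse = ", "))
  }
  locus <- unname(locus_map[ids])
  f <- factor(locus, levels = unique(locus))   # preserve first-appearance order
  counts <- rowsum(x$counts, f, reorder = FALSE)
  npep <- as.integer(rowsum(as.numeric(x$n_peptides), f, reorder = FALSE))
  tot <- rowSums(x$counts)
  w_num <- rowsum(x$mw_kda * pmax(tot, 0), f, reorder = FALSE)[, 1]
  w_den <- rowsum(pmax(tot, 0), f, reorder = FALSE)[, 1]
  mw <- ifelse(w_den > 0, w_num / w_den,
               rowsum(x$mw_kda, f, reorder = FALSE)[, 1] / tabulate(f))
  spc_table(counts, mw, npep, x$species)
}

#' Filter proteins on reproducible presence and peptide evidence
#'
#' Retains proteins identified by at least `min_peptides` distinct peptides
#' and reproducibly present (spectral count > 0) in every replicate of at
#' least one species (`scope = "any"`), or of one named species.
#'
#' @param x an [spc_table].
#' @param min_peptides minimum distinct-peptide count (default 2).
#' @param scope `"any"` (default) or a species label.
#' @return the filtered [spc_table]; row order preserved.
#' @export
filter_proteins <- function(x, min_peptides = 2, scope = "any") {
  stopifnot(inherits(x, "spc_table"))
  sp <- unique(x$species)
  if (!identical(scope, "any") && !scope %in% sp) {
    stop_data("unknown species label: ", scope)
  }
  check <- if (identical(scope, "any")) sp else scope
  complete <- vapply(check, function(s) {
    cols <- names(x$species)[x$species == s]
    rowSums(x$counts[, cols, drop = FALSE] > 0) == length(cols)
  }, logical(nrow(x$counts)))
  keep <- x$n_peptides >= min_peptides & apply(as.matrix(complete), 1, any)
  spc_table(x$counts[keep, , drop = FALSE], x$mw_kda[keep],
            x$n_peptides[keep], x$species)
}

#' Normalized spectral abundance factor for one sample
#'
#' NSAF for protein k in a sample: the spectral count divided by the protein's
#' molecular weight, normalized to the sum of SpC/MW over all N proteins,
#' `NSAF_k = (SpC_k/MW_k) / sum_j (SpC_j/MW_j)`. NSAF values sum to one per
#' sample and serve as a relative abundance measure.
#'
#' @param counts numeric vector of spectral counts for one sample.
#' @param mw numeric vector of molecular weights (kDa), positive wherever the
#'   count is positive.
#' @return numeric vector of NSAF values summing to 1. A sample with zero
#'   total counts returns all zeros with a warning and attribute
#'   `degenerate = TRUE`.
#' @examples
#' compute_nsaf(c(4, 6), c(2, 3))   # SpC/MW = (2, 2) -> (0.5, 0.5)
#' @export
compute_nsaf <- function(counts, mw) {
  if (any(counts < 0)) stop_data("negative spectral counts")
  if (any(mw[counts > 0] <= 0)) stop_data("non-positive molecular weight")
  saf <- ifelse(counts > 0, counts / mw, 0)
  tot <- sum(saf)
  if (tot == 0) {
    warning("sample has zero total spectral counts; returning all-zero NSAF")
    return(structure(counts * 0, degenerate = TRUE))
  }
  saf / tot
}

#' Per-replicate NSAF matrix
#'
#' Applies [compute_nsaf()] to every replicate column of a spectral-count
#' table.
#'
#' @param x an [spc_table].
#' @return numeric matrix, loci x replicates, each column summing to 1.
#' @export
nsaf_matrix <- function(x) {
  stopifnot(inherits(x, "spc_table"))
  apply(x$counts, 2, compute_nsaf, mw = x$mw_kda)
}

#' Summed-replicate NSAF per species
#'
#' For each protein the spectral counts of a species' replicates are summed
#' and NSAF is computed from the sums; this per-species abundance is the usual
#' input to cross-layer correlation.
#'
#' @param x an [spc_table].
#' @param species a species label, or `NULL` for all species.
#' @return numeric vector (one species) or matrix loci x species.
#' @export
compute_nsaf_summed <- function(x, species = NULL) {
  stopifnot(inherits(x, "spc_table"))
  sp <- unique(x$species)
  if (is.null(species)) {
    out <- vapply(sp, function(s) compute_nsaf_summed(x, s),
                  numeric(nrow(x$counts)))
    rownames(out) <- rownames(x$counts)
    return(out)
  }
  if (!species %in% sp) stop_data("unknown species label: ", species)
  cols <- names(x$species)[x$species == species]
  compute_nsaf(rowSums(x$counts[, cols, drop = FALSE]), x$mw_kda)
}

#' Add a spectral fraction (pseudo-count)
#'
#' Adds a small constant to every spectral count. NSAF computed from
#' pseudo-counted data is approximately normally distributed, which justifies
#' t-tests in pairwise species comparisons; the fraction is used only on that
#' testing path, never for the summed abundance measure.
#'
#' @param x an [spc_table].
#' @param fraction positive pseudo-count added to every cell (default 0.5).
#' @return an [spc_table] with fractional counts.
#' @export
add_spectral_fraction <- function(x, fraction = 0.5) {
  stopifnot(inherits(x, "spc_table"))
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0) {
    stop_data("spectral fraction must be a positive scalar")
  }
  y <- x
  y$counts <- x$counts + fraction
  y
}
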