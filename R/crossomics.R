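#' Common locus set of two profiling layers
#'
#' Order-stable intersection of the transcript and protein locus universes,
#' the set on which cross-layer correlation and overlap statistics are
#' computed. An empty intersection is a warning, not an error.
#'
#' @param transcript_ids,protein_ids character vectors of locus identifiers
#'   sharing a namespace (AGI locus codes).
#' @return object of class `common_set`: list with `loci` (in
#'   `transcript_ids` order), `n_transcript`, `n_protein`.
#' @export
common_gene_set <- function(transcript_ids, protein_ids) {
  transcript_ids <- unique(transcript_ids)
  protein_ids <- unique(protein_ids)
  loci <- transcript_ids[transcript_ids %in% protein_ids]
  if (length(loci) == 0) warning("transcript and protein sets share no loci")
  structure(list(loci = loci,
                 n_transcript = length(transcript_ids),
                 n_protein = length(protein_ids)),
            class = "common_set")
}

#' @export
print.common_set <- function(x, ...) {
  cat(sprintf("Common locus set: %d loci (transcript universe %d, protein universe %d)\n",
              length(x$loci), x$n_transcript, x$n_protein))
  invisible(x)
}

#' Spearman correlation matrix across layers and species
#'
#' Computes all pairwise Spearman rank correlations among the per-species
#' transcript and protein abundance columns, restricted to a common locus
#' set. Rank correlation is used because neither log2 spectral abundance
#' factors nor log2 fluorescence intensities are normally distributed; ties
#' are handled by midranks. A constant column yields `NA` entries with a
#' warning.
#'
#' @param transcript_log2 matrix, loci x species, transcript abundance.
#' @param protein_log2 matrix, loci x species, protein abundance (log2 summed
#'   NSAF).
#' @param common a [common_gene_set()] result, or `NULL` to intersect the
#'   rownames.
#' @return a `correlation_matrix`: symmetric numeric matrix with labels
#'   `<species>_T`, `<species>_P` and attribute `n_loci`.
#' @export
correlation_matrix <- function(transcript_log2, protein_log2, common = NULL) {
  if (is.null(common)) {
    common <- common_gene_set(rownames(transcript_log2), rownames(protein_log2))
  }
  loci <- common$loci
  if (!all(loci %in% rownames(transcript_log2)) ||
      !all(loci %in% rownames(protein_log2))) {
    stop_data("common loci missing from an abundance matrix")
  }
  tm <- transcript_log2[loci, , drop = FALSE]
  pm <- protein_log2[loci, , drop = FALSE]
  colnames(tm) <- paste0(colnames(transcript_log2), "_T")
  colnames(pm) <- paste0(colnames(protein_log2), "_P")
  m <- cbind(tm, pm)
  const <- apply(m, 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    warning("constant column(s): ", paste(colnames(m)[const], collapse = ", "),
            "; correlations reported as NA")
  }
  suppressWarnings(rho <- stats::cor(m, method = "spearman"))
  rho[const, ] <- NA; rho[, const] <- NA
  diag(rho) <- 1
  structure(rho, n_loci = length(loci), class = c("correlation_matrix", "matrix"))
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("Spearman correlations over %d common loci\n", attr(x, "n_loci")))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Size-corrected overlap of regulated transcript and protein lists
#'
#' Restricts both regulated lists to the common locus set (correcting for the
#' different sizes of the transcript and protein universes) and reports the
#' intersection together with two confirmation percentages: the proportion of
#' regulated transcripts confirmed by protein profiling (`upper_pct` =
#' 100*k/a) and the proportion of regulated proteins confirmed by transcript
#' profiling (`lower_pct` = 100*k/b). Display values are rounded half-up to
#' whole percent; full precision is retained.
#'
#' @param t_list,p_list character vectors of regulated loci from the
#'   transcript and protein layers (may extend beyond the common set).
#' @param common a [common_gene_set()] result.
#' @param contrast optional contrast label carried through.
#' @return object of class `overlap_result`: list with `contrast`, `a`, `b`,
#'   `k`, `upper_pct`, `lower_pct` (full precision), `upper_pct_display`,
#'   `lower_pct_display`; percentage is `NA` when its denominator is 0.
#' @examples
#' cs <- common_gene_set(sprintf("g%03d", 1:200), sprintf("g%03d", 1:200))
#' overlap_analysis(sprintf("g%03d", 1:20), sprintf("g%03d", 11:40), cs)
#' @export
overlap_analysis <- function(t_list, p_list, common, contrast = "") {
  stopifnot(inherits(common, "common_set"))
  tc <- intersect(t_list, common$loci)
  pc <- intersect(p_list, common$loci)
  k <- length(intersect(tc, pc))
  a <- length(tc); b <- length(pc)
  structure(list(
    contrast = contrast, a = a, b = b, k = k,
    upper_pct = if (a > 0) 100 * k / a else NA_real_,
    lower_pct = if (b > 0) 100 * k / b else NA_real_,
    upper_pct_display = if (a > 0) round_half_up(100 * k / a) else NA_real_,
    lower_pct_display = if (b > 0) round_half_up(100 * k / b) else NA_real_,
    p_perm = NA_real_, n_perm = NA_integer_, seed = NA_integer_
  ), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Overlap %s: |T|=%d, |P|=%d, k=%d\n",
              if (nzchar(x$contrast)) x$contrast else "(unnamed)",
              x$a, x$b, x$k))
  cat(sprintf("  transcripts confirmed by proteins: %s%%\n",
              format(x$upper_pct_display)))
  cat(sprintf("  proteins confirmed by transcripts: %s%%\n",
              format(x$lower_pct_display)))
  if (!is.na(x$p_perm)) {
    cat(sprintf("  permutation p = %.4g (%d draws)%s\n", x$p_perm, x$n_perm,
                if (x$p_perm < 0.05) " *" else ""))
  }
  invisible(x)
}

#' Permutation null for gene-list overlap
#'
#' Significance of an observed overlap between two regulated-gene lists of
#' sizes `a` and `b` drawn from a universe of `universe_n` loci: both sets
#' are redrawn uniformly at random (without replacement, independently)
#' `n_perm` times and the one-sided tail probability of an overlap at least
#' as large as observed is estimated with the add-one correction
#' `p = (1 + #\{overlap >= k_obs\}) / (1 + n_perm)`, so p is never exactly 0.
#' The null distribution of the overlap is hypergeometric, which serves as a
#' closed-form cross-check.
#'
#' @param a,b set sizes (each <= `universe_n`).
#' @param k_obs observed intersection size (<= `min(a, b)`).
#' @param universe_n size of the common locus universe.
#' @param n_perm number of random draws (default 10000).
#' @param seed optional integer seed for reproducibility.
#' @return the permutation p-value in (0, 1].
#' @export
permutation_overlap_pvalue <- function(a, b, k_obs, universe_n,
                                       n_perm = 10000, seed = NULL) {
  if (a > universe_n || b > universe_n) stop_data("set size exceeds universe")
  if (k_obs > min(a, b) || k_obs < max(0, a + b - universe_n)) {
    stop_data("impossible observed overlap for the given sizes")
  }
  if (!is.null(seed)) set.seed(seed)
  if (a == 0 || b == 0) return(1)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    sa <- sample.int(universe_n, a)
    sb <- sample.int(universe_n, b)
    if (sum(sa %in% sb) >= k_obs) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_perm)
}

#' Annotate an overlap result with its permutation p-value
#'
#' @param x an [overlap_analysis()] result.
#' @param universe_n common-set size (defaults cannot be inferred; required).
#' @param n_perm,seed passed to [permutation_overlap_pvalue()].
#' @return the `overlap_result` with `p_perm`, `n_perm`, `seed` filled in.
#' @export
add_overlap_pvalue <- function(x, universe_n, n_perm = 10000, seed = NULL) {
  stopifnot(inherits(x, "overlap_result"))
  x$p_perm <- permutation_overlap_pvalue(x$a, x$b, x$k, universe_n,
                                         n_perm = n_perm, seed = seed)
  x$n_perm <- as.integer(n_perm)
  x$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  x
}
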