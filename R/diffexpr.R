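#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values controlling the FDR across a family of tests.
#' Input order is preserved; adjusted values are clipped at 1 and validated to
#' lie in \[0, 1\] on input.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return numeric vector of BH-adjusted p-values, same order as `p`.
#' @export
adjust_bh <- function(p) {
  if (!is.numeric(p)) stop_data("p-values must be numeric")
  if (any(!is.na(p) & (p < 0 | p > 1))) stop_data("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' The six study contrasts for a set of species
#'
#' Builds the standard contrast set for a multi-species comparison: each
#' species against the remaining species combined (group, one-vs-rest) and
#' all pairwise comparisons.
#'
#' @param species character vector of species labels (>= 2).
#' @return list of contrast specifications, each with elements `name`,
#'   `kind` (`"group"` or `"pairwise"`), `target`, `others`, and `weights`
#'   (named numeric vector over species).
#' @examples
#' study_contrasts(c("CH", "EX", "NZ"))
#' @export
study_contrasts <- function(species) {
  species <- unique(species)
  if (length(species) < 2) stop_config("need at least two species")
  grp <- lapply(species, function(s) {
    o <- setdiff(species, s)
    w <- stats::setNames(rep(-1 / length(o), length(species)), species)
    w[s] <- 1
    list(name = paste0(s, "_vs_", paste(o, collapse = "+")),
         kind = "group", target = s, others = o, weights = w)
  })
  prs <- utils::combn(species, 2, simplify = FALSE)
  pw <- lapply(prs, function(p) {
    w <- stats::setNames(rep(0, length(species)), species)
    w[p[1]] <- 1; w[p[2]] <- -1
    list(name = paste0(p[1], "_vs_", p[2]),
         kind = "pairwise", target = p[1], others = p[2], weights = w)
  })
  c(grp, pw)
}

#' Per-gene linear-model contrasts on log2 expression
#'
#' Fits an ordinary least-squares cell-means model per gene across arrays and
#' tests linear contrasts of the species means with two-sided t-tests,
#' adjusting p-values across genes within each contrast by Benjamini-
#' Hochberg. This is the plain-OLS analogue of the moderated linear model
#' typically used for two-channel arrays; no variance moderation is applied.
#'
#' @param mat numeric matrix, genes x arrays, log2 expression (or log-ratio)
#'   values; rownames are locus ids.
#' @param species character vector assigning each array (column) to a
#'   species.
#' @param contrasts list of contrasts from [study_contrasts()], or `NULL` for
#'   the full study set.
#' @param alpha significance level for up/down calls on adjusted p-values.
#' @return data.frame with columns `locus, contrast, log2fc, stat, p_raw,
#'   p_adj, call` (one row per gene per contrast). With zero residual
#'   degrees of freedom the estimates are returned but statistics are `NA`
#'   and all calls are `ns` (with a warning).
#' @export
fit_transcript_contrasts <- function(mat, species, contrasts = NULL, alpha = 0.05) {
  mat <- as.matrix(mat)
  if (length(species) != ncol(mat)) {
    stop_data("species must assign every array to a species")
  }
  lev <- unique(species)
  if (is.null(contrasts)) contrasts <- study_contrasts(lev)
  X <- stats::model.matrix(~ 0 + factor(species, levels = lev))
  colnames(X) <- lev
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop_data("rank-deficient design; confounded columns: ",
              paste(colnames(X)[-seq_len(qrX$rank)], collapse = ", "))
  }
  XtXi <- chol2inv(chol(crossprod(X)))
  B <- mat %*% X %*% XtXi                    # genes x species cell means
  res <- mat - B %*% t(X)
  df <- ncol(mat) - ncol(X)
  s2 <- if (df > 0) rowSums(res^2) / df else rep(NA_real_, nrow(mat))
  if (df <= 0) warning("no residual degrees of freedom; statistics set to NA")
  out <- lapply(contrasts, function(ct) {
    cw <- ct$weights[lev]
    est <- drop(B %*% cw)
    se2 <- s2 * drop(t(cw) %*% XtXi %*% cw)
    stat <- est / sqrt(se2)
    p <- if (df > 0) 2 * stats::pt(-abs(stat), df) else rep(NA_real_, length(est))
    padj <- if (df > 0) adjust_bh(p) else p
    data.frame(locus = rownames(mat), contrast = ct$name,
               log2fc = est, stat = stat, p_raw = p, p_adj = padj,
               call = de_call(est, padj, alpha),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# up/down/ns labelling shared by all tests
de_call <- function(log2fc, p_adj, alpha) {
  ifelse(!is.na(p_adj) & p_adj < alpha & log2fc > 0, "up",
         ifelse(!is.na(p_adj) & p_adj < alpha & log2fc < 0, "down", "ns"))
}

#' Wilcoxon rank-sum test of species-specific protein abundance
#'
#' Tests each locus for differential NSAF abundance between a target species
#' and the remaining species combined (one-vs-rest), using the two-sided
#' Wilcoxon rank-sum test: exact when both sides have at most 8 replicates
#' and no ties, otherwise the normal approximation with continuity and tie
#' correction. The log2 fold change is computed from pseudo-counted NSAF
#' means (so zero counts stay finite); p-values are BH-adjusted across loci.
#'
#' @param x an [spc_table].
#' @param target species label tested against the rest.
#' @param others species labels of the comparison group; defaults to all
#'   remaining species.
#' @param alpha significance level for calls.
#' @param fraction spectral fraction used for the fold-change means.
#' @return data.frame like [fit_transcript_contrasts()], one row per locus.
#' @export
protein_group_test <- function(x, target, others = NULL, alpha = 0.05,
                               fraction = 0.5) {
  stopifnot(inherits(x, "spc_table"))
  sp <- unique(x$species)
  if (!target %in% sp) stop_data("unknown species label: ", target)
  if (is.null(others)) others <- setdiff(sp, target)
  nsaf <- nsaf_matrix(x)
  nsaf_f <- nsaf_matrix(add_spectral_fraction(x, fraction))
  a_cols <- names(x$species)[x$species == target]
  b_cols <- names(x$species)[x$species %in% others]
  if (length(a_cols) < 2 || length(b_cols) < 2) {
    stop_data("need at least two replicates on each side")
  }
  p <- vapply(seq_len(nrow(nsaf)), function(i) {
    wilcoxon_p(nsaf[i, a_cols], nsaf[i, b_cols])
  }, numeric(1))
  lfc <- log2(rowMeans(nsaf_f[, a_cols, drop = FALSE]) /
              rowMeans(nsaf_f[, b_cols, drop = FALSE]))
  padj <- adjust_bh(p)
  data.frame(locus = rownames(x$counts),
             contrast = paste0(target, "_vs_", paste(others, collapse = "+")),
             log2fc = lfc, stat = NA_real_, p_raw = p, p_adj = padj,
             call = de_call(lfc, padj, alpha),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' The primitive behind [protein_group_test()]: exact when both groups have
#' at most 8 observations and the pooled sample is untied, otherwise the
#' normal approximation with continuity and tie correction. An all-identical
#' pooled sample returns 1 by convention.
#'
#' @param a,b numeric vectors of observations.
#' @return the two-sided p-value.
#' @examples
#' wilcoxon_p(c(1, 2, 3), c(4, 5, 6))  # most extreme 3-vs-3 split: 2/20
#' @export
wilcoxon_p <- function(a, b) {
  if (all(c(a, b) == c(a, b)[1])) return(1)
  exact <- length(a) <= 8 && length(b) <= 8 && !anyDuplicated(c(a, b))
  suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
  )
}

#' Pairwise t-test of protein abundance on pseudo-counted NSAF
#'
#' Two-sided two-sample t-test per locus between two species, computed on
#' NSAF from pseudo-counted spectral counts (which renders the values
#' approximately normal). Welch's unequal-variance form is the default; the
#' pooled-variance form is available for textbook comparability. P-values are
#' BH-adjusted across loci.
#'
#' @param x an [spc_table]; the spectral fraction is applied internally.
#' @param a,b species labels to compare (`a` minus `b` in the fold change).
#' @param alpha significance level for calls.
#' @param fraction spectral fraction (default 0.5).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return data.frame like [fit_transcript_contrasts()], one row per locus.
#' @export
protein_pairwise_test <- function(x, a, b, alpha = 0.05, fraction = 0.5,
                                  var_equal = FALSE) {
  stopifnot(inherits(x, "spc_table"))
  sp <- unique(x$species)
  if (!all(c(a, b) %in% sp)) stop_data("unknown species label")
  nsaf_f <- nsaf_matrix(add_spectral_fraction(x, fraction))
  a_cols <- names(x$species)[x$species == a]
  b_cols <- names(x$species)[x$species == b]
  if (length(a_cols) < 2 || length(b_cols) < 2) {
    stop_data("need at least two replicates on each side")
  }
  tp <- t(vapply(seq_len(nrow(nsaf_f)), function(i) {
    welch_t(nsaf_f[i, a_cols], nsaf_f[i, b_cols], var_equal)
  }, numeric(2)))
  lfc <- log2(rowMeans(nsaf_f[, a_cols, drop = FALSE]) /
              rowMeans(nsaf_f[, b_cols, drop = FALSE]))
  padj <- adjust_bh(tp[, 2])
  data.frame(locus = rownames(x$counts), contrast = paste0(a, "_vs_", b),
             log2fc = lfc, stat = tp[, 1], p_raw = tp[, 2], p_adj = padj,
             call = de_call(lfc, padj, alpha),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-sample t statistic and p-value
#'
#' The primitive behind [protein_pairwise_test()]: Welch's unequal-variance
#' t-test by default, or the pooled-variance form. Degenerate zero-variance
#' inputs follow fixed conventions: both sides constant and equal gives
#' `c(0, 1)`; constant but unequal gives `c(sign(diff) * Inf, 0)`.
#'
#' @param a,b numeric vectors of observations.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return numeric vector `c(statistic, p.value)`.
#' @export
welch_t <- function(a, b, var_equal = FALSE) {
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(c(0, 1))
    return(c(sign(mean(a) - mean(b)) * Inf, 0))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  c(unname(tt$statistic), tt$p.value)
}

#' Extract up- and down-regulated locus lists
#'
#' @param de a differential-expression data.frame (from any of the test
#'   functions), optionally covering several contrasts.
#' @param alpha significance level applied to `p_adj` (re-deriving the calls,
#'   so a different alpha than at fit time can be used).
#' @return named list per contrast, each with character vectors `up` and
#'   `down` (disjoint).
#' @export
call_regulated <- function(de, alpha = 0.05) {
  if (nrow(de) == 0) return(list())
  split_de <- split(de, de$contrast)
  lapply(split_de, function(d) {
    sig <- !is.na(d$p_adj) & d$p_adj < alpha
    list(up = d$locus[sig & d$log2fc > 0],
         down = d$locus[sig & d$log2fc < 0])
  })
}
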