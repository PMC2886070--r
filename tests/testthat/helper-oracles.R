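# Independent oracles and small fixture builders shared across tests.

# Benjamini-Hochberg step-up from the definition: sort, multiply by m/rank,
# cumulative minimum from the largest, clip at 1, restore input order.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Greedy Ward agglomeration by explicit error-sum-of-squares computation:
# at each step merge the pair of clusters whose union increases total
# within-cluster ESS least. Returns merge heights (Delta-ESS) and the member
# sets of each merge, for comparison against the Lance-Williams route.
brute_ward_oracle <- function(X) {
  n <- nrow(X)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(n - 1)
  merges <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    best <- NULL
    bestd <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        A <- clusters[[i]]; B <- clusters[[j]]
        cA <- colMeans(X[A, , drop = FALSE])
        cB <- colMeans(X[B, , drop = FALSE])
        d <- length(A) * length(B) / (length(A) + length(B)) * sum((cA - cB)^2)
        if (d < bestd) { bestd <- d; best <- c(i, j) }
      }
    }
    heights[step] <- bestd
    merges[[step]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, merges = merges)
}

# cluster membership sets implied by an hclust object after each merge
hclust_merge_sets <- function(h) {
  sets <- vector("list", nrow(h$merge))
  for (i in seq_len(nrow(h$merge))) {
    members <- function(v) {
      if (v < 0) -v else sets[[v]]
    }
    sets[[i]] <- sort(c(members(h$merge[i, 1]), members(h$merge[i, 2])))
  }
  sets
}

# small spectral-count table builder: counts is loci x replicates
make_spc <- function(counts, mw = NULL, npep = NULL, species) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("At1g%05d", 10 * seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0(species, "_r", stats::ave(seq_along(species),
                                                         species, FUN = seq_along))
  }
  if (is.null(mw)) mw <- rep(10, nrow(counts))
  if (is.null(npep)) npep <- rep(3L, nrow(counts))
  spc_table(counts, mw, npep, species)
}

# spectral-count matrix whose per-replicate NSAF (equal MW) equals the rows
# of `target` scaled to fractions, by adding a filler locus
nsaf_fixture <- function(target_nsaf, species) {
  stopifnot(all(target_nsaf > 0), all(target_nsaf < 1))
  filler <- 1 - colSums(target_nsaf)
  stopifnot(all(filler > 0))
  counts <- rbind(target_nsaf, filler) * 1000
  rownames(counts) <- c(sprintf("At1g%05d", 10 * seq_len(nrow(target_nsaf))),
                        "At9g99990")
  colnames(counts) <- paste0("s", seq_along(species))
  make_spc(counts, species = species)
}
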