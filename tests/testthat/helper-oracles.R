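# Independent brute-force oracles. Deliberately written in a different
# style from the package code (index bookkeeping, explicit loops, direct
# formulas) and never calling the routines they check.

# Iterative 3-SD rule: returns the indices of true peaks.
oracle_detect <- function(heights, k = 3) {
  true_idx <- integer(0)
  repeat {
    rem <- setdiff(seq_along(heights), true_idx)
    if (length(rem) == 0L) break
    s <- sqrt(sum(heights[rem]^2) / length(rem))
    newly <- rem[heights[rem] > k * s]
    if (length(newly) == 0L) break
    true_idx <- c(true_idx, newly)
  }
  sort(true_idx)
}

# Pairwise Euclidean distances by explicit double loop.
oracle_distances <- function(x) {
  # x: variables-by-samples matrix
  n <- ncol(x)
  d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sqrt(sum((x[, i] - x[, j])^2))
    }
  }
  d
}

# Complete-linkage agglomeration over a labelled distance matrix.
# Returns merge heights and the canonical partition after each merge.
oracle_complete_linkage <- function(d) {
  labels <- rownames(d)
  clusters <- as.list(labels)
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1L) {
    best <- list(h = Inf, i = NA, j = NA)
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq(i + 1L, length(clusters))) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best$h) best <- list(h = h, i = i, j = j)
      }
    }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
    heights <- c(heights, best$h)
    partitions <- c(partitions, list(canonical_partition(clusters)))
  }
  list(heights = heights, partitions = partitions)
}

canonical_partition <- function(clusters) {
  parts <- sort(vapply(clusters, function(cl) {
    paste(sort(cl), collapse = ",")
  }, character(1)))
  paste(parts, collapse = " | ")
}

# Partition sequence implied by an hclust tree, canonicalized.
hclust_partitions <- function(hc) {
  n <- length(hc$labels)
  lapply(seq_len(n - 1L), function(m) {
    grp <- stats::cutree(hc, k = n - m)
    canonical_partition(split(names(grp), grp))
  })
}

# Eigendecomposition of the sample covariance of samples-by-variables x.
oracle_pca_variances <- function(x) {
  xc <- sweep(x, 2L, colMeans(x))
  cv <- crossprod(xc) / (nrow(x) - 1L)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  ev[ev > 1e-12 * max(ev)]
}

# Balanced split-plot sums of squares from cell/marginal means.
oracle_split_plot_ss <- function(df, response) {
  y <- df[[response]]
  grand <- mean(y)
  sp <- unique(df$species); di <- unique(df$diet)
  a <- length(unique(df$animal_id[df$species == sp[1]]))
  nd <- length(di)
  sp_mean <- vapply(sp, function(s) mean(y[df$species == s]), numeric(1))
  di_mean <- vapply(di, function(d) mean(y[df$diet == d]), numeric(1))
  uid <- paste(df$species, df$animal_id)
  an_mean <- tapply(y, uid, mean)
  an_sp <- tapply(df$species, uid, `[`, 1L)
  ss_species <- a * nd * sum((sp_mean - grand)^2)
  ss_animal <- nd * sum((an_mean - sp_mean[an_sp])^2)
  ss_diet <- length(sp) * a * sum((di_mean - grand)^2)
  ss_int <- 0
  for (s in sp) {
    for (d in di) {
      cm <- mean(y[df$species == s & df$diet == d])
      ss_int <- ss_int +
        unname(a * (cm - sp_mean[s] - di_mean[d] + grand)^2)
    }
  }
  ss_total <- sum((y - grand)^2)
  c(species = ss_species, animal = ss_animal, diet = ss_diet,
    interaction = ss_int,
    residual = ss_total - ss_species - ss_animal - ss_diet - ss_int,
    total = ss_total)
}

random_simplex <- function(n) {
  x <- stats::rexp(n)
  x / sum(x)
}
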