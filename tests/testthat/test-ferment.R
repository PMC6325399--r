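ref_ph_cells <- function() {
  ref <- reference_fermentation()
  tapply(ref$pH, list(ref$species, ref$diet), mean)
}

test_that("summarize_means recovers cell means and a zero SEM on constants", {
  rec <- simulate_fermentation(mu = 4.2, seed = 1)
  sm <- summarize_means(rec)
  expect_equal(sm$cells$mean, rep(4.2, 6))
  expect_equal(sm$sem, 0)
})

test_that("noise-free simulation returns the planted pH cell means", {
  cm <- ref_ph_cells()
  rec <- simulate_fermentation(cell_means = cm, sigma_animal = 0,
                               sigma_e = 0, seed = 2, response = "pH")
  sm <- summarize_means(rec, "pH")
  for (i in seq_len(nrow(sm$cells))) {
    expect_equal(sm$cells$mean[i],
                 cm[sm$cells$species[i], sm$cells$diet[i]])
  }
  expect_equal(unname(sm$diet_means["HF"]), mean(c(6.39, 6.37, 6.25)))
  expect_equal(unname(sm$diet_means["HC"]), mean(c(5.56, 5.14, 5.90)))
})

test_that("two records per cell average to the midpoint", {
  rec <- data.frame(species = rep("Goat", 4), diet = rep(c("HF", "HC"),
                                                         each = 2),
                    value = c(1, 3, 10, 20))
  sm <- summarize_means(rec)
  expect_equal(sort(sm$cells$mean), c(2, 15))
  expect_true(is.na(sm$sem))  # no animal structure, no residual stratum
})

test_that("split-plot sums of squares match the cell-means oracle", {
  for (seed in 1:5) {
    rec <- simulate_fermentation(cell_means = ref_ph_cells(),
                                 sigma_animal = 0.3, sigma_e = 0.1,
                                 seed = seed, response = "pH")
    fit <- split_plot_anova(rec, "pH")
    ss <- oracle_split_plot_ss(rec, "pH")
    tab <- fit$table
    expect_equal(tab$sum_sq[tab$effect == "species"],
                 unname(ss["species"]), tolerance = 1e-8)
    expect_equal(tab$sum_sq[tab$effect == "animal(species)"],
                 unname(ss["animal"]), tolerance = 1e-8)
    expect_equal(tab$sum_sq[tab$effect == "diet"], unname(ss["diet"]),
                 tolerance = 1e-8)
    expect_equal(tab$sum_sq[tab$effect == "species:diet"],
                 unname(ss["interaction"]), tolerance = 1e-8)
    expect_equal(tab$sum_sq[tab$effect == "residual"],
                 unname(ss["residual"]), tolerance = 1e-8)
    expect_equal(sum(tab$sum_sq), unname(ss["total"]), tolerance = 1e-8)
    expect_equal(sum(tab$df), nrow(rec) - 1)
  }
})

test_that("whole-plot and sub-plot effects use their own error strata", {
  rec <- simulate_fermentation(cell_means = ref_ph_cells(),
                               sigma_animal = 0.3, sigma_e = 0.1,
                               seed = 11, response = "pH")
  fit <- split_plot_anova(rec, "pH")
  tab <- fit$table
  ms <- function(e) tab$mean_sq[tab$effect == e]
  expect_equal(tab$F[tab$effect == "species"],
               ms("species") / ms("animal(species)"))
  expect_equal(tab$F[tab$effect == "diet"], ms("diet") / ms("residual"))
  expect_equal(tab$error_stratum[tab$effect == "species"],
               "animal(species)")
})

test_that("unbalanced designs are rejected with guidance", {
  rec <- simulate_fermentation(seed = 1)
  expect_error(split_plot_anova(rec[-1, ]), "unsupported design")
  expect_error(split_plot_anova(rec[-1, ]), "mixed-model")
})

test_that("zero residual variance with a pure diet effect overflows F", {
  rec <- simulate_fermentation(diet_effect = c(HC = 2), sigma_animal = 0,
                               sigma_e = 0, seed = 1)
  fit <- split_plot_anova(rec)
  expect_true(is.infinite(fit$table$F[fit$table$effect == "diet"]))
  expect_equal(fit$table$p[fit$table$effect == "diet"], 0)
  expect_true(fit$overflow)
})

test_that("p-values are invariant to consistent relabeling", {
  rec <- simulate_fermentation(cell_means = ref_ph_cells(),
                               sigma_animal = 0.3, sigma_e = 0.1,
                               seed = 21, response = "pH")
  relab <- rec
  map <- c(Hanwoo = "sp_c", Holstein = "sp_a", Goat = "sp_b")
  relab$species <- unname(map[relab$species])
  relab$animal_id <- sub("^(Hanwoo|Holstein|Goat)", "x", relab$animal_id)
  dmap <- c(HF = "d2", HC = "d1")
  relab$diet <- unname(dmap[relab$diet])
  f1 <- split_plot_anova(rec, "pH")
  f2 <- split_plot_anova(relab, "pH")
  expect_equal(f1$table$p, f2$table$p, tolerance = 1e-12)
  expect_equal(f1$variance_components, f2$variance_components,
               tolerance = 1e-12)
})

test_that("variance components recover the planted variances at large n", {
  rec <- simulate_fermentation(n_animals = 200, sigma_animal = 0.5,
                               sigma_e = 0.2, seed = 31)
  fit <- split_plot_anova(rec)
  expect_equal(unname(fit$variance_components["animal"]), 0.25,
               tolerance = 0.1)
  expect_equal(unname(fit$variance_components["residual"]), 0.04,
               tolerance = 0.1)
})

test_that("Tukey comparisons collapse to known forms", {
  expect_error(tukey_pairwise(c(a = 1, b = 2), 1, 0, 4), "df_error")
  same <- tukey_pairwise(c(a = 3, b = 3), ms_error = 2, df_error = 10,
                         n_per_cell = 4)
  expect_equal(same$p_adj, 1)

  # k = 2: the range test collapses to the two-sample t-test on the
  # same error stratum
  means <- c(g1 = 1.0, g2 = 2.3)
  tk <- tukey_pairwise(means, ms_error = 0.8, df_error = 12,
                       n_per_cell = 5)
  tstat <- abs(diff(means)) / sqrt(2 * 0.8 / 5)
  p_t <- unname(2 * pt(tstat, df = 12, lower.tail = FALSE))
  expect_equal(tk$p_adj, p_t, tolerance = 1e-8)
})

test_that("Tukey adjusted p agrees with a permutation max-range reference", {
  rec <- simulate_fermentation(
    cell_means = matrix(c(0, 0.2, 0.35, 0.1, 0.25, 0.45), nrow = 3,
                        dimnames = list(c("Hanwoo", "Holstein", "Goat"),
                                        c("HF", "HC"))),
    sigma_animal = 0, sigma_e = 0.25, seed = 41)
  y <- rec$value
  cell <- paste(rec$species, rec$diet, sep = ":")
  cells <- sort(unique(cell))
  n_cell <- 4
  cm <- tapply(y, cell, mean)[cells]
  df_res <- length(y) - length(cells)
  ms_res <- sum((y - cm[cell])^2) / df_res
  tk <- tukey_pairwise(cm, ms_error = ms_res, df_error = df_res,
                       n_per_cell = n_cell)

  # reference: permute the (exchangeable) cell residuals 10,000 times
  # and form the null distribution of the maximum studentized range
  resid <- y - cm[cell]
  G <- outer(cells, cell, "==") + 0
  set.seed(1)
  qmax <- vapply(seq_len(10000), function(b) {
    rp <- sample(resid)
    m <- as.vector(G %*% rp) / n_cell
    ms <- sum((rp - m[match(cell, cells)])^2) / df_res
    (max(m) - min(m)) / sqrt(ms / n_cell)
  }, numeric(1))
  p_perm <- vapply(tk$q, function(q) mean(qmax >= q), numeric(1))
  expect_lt(max(abs(tk$p_adj - p_perm)), 0.05)
})

test_that("significance labels follow the reporting convention", {
  expect_equal(classify_significance(c(0.01, 0.07, 0.2)),
               c("significant", "trend", "ns"))
})
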