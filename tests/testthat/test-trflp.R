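test_that("size filter keeps the inclusive 27-520 bp window", {
  pt <- peak_table(c(26.9, 27.0, 300, 520.0, 520.1), rep(10, 5), "A")
  out <- filter_by_size(pt)
  expect_equal(out$size, c(27.0, 300, 520.0))

  expect_equal(nrow(filter_by_size(peak_table(sample_id = "A"))), 0L)
  inside <- peak_table(c(100, 200, 300), c(1, 2, 3), "A")
  expect_equal(filter_by_size(inside)$size, inside$size)
  expect_error(filter_by_size(pt, 520, 27), "strictly less")
})

test_that("iterative detection reproduces the hand-traced example", {
  # 20 peaks of height 5 plus one of 500: iteration 1 SD = sqrt((500^2 +
  # 20*25)/21) ~ 109.2, threshold ~ 327.6 declares the 500; iteration 2
  # over the fives has SD 5, threshold 15, declares none.
  pt <- peak_table(seq(30, length.out = 21, by = 2),
                   c(rep(5, 20), 500), "A")
  res <- detect_true_peaks(pt)
  expect_equal(res$true_peaks$height, 500)
  expect_equal(res$n_iterations, 2L)
  expect_equal(res$final_sd, 5)
  expect_true(res$converged)
  expect_equal(sqrt((500^2 + 20 * 25) / 21), 109.2, tolerance = 1e-3)
})

test_that("equal heights can never exceed their own threshold", {
  pt <- peak_table(seq(30, 70, 10), rep(8, 5), "A")
  res <- detect_true_peaks(pt)
  expect_equal(nrow(res$true_peaks), 0L)
  expect_equal(res$n_iterations, 1L)
})

test_that("empty input gives an empty set with zero iterations", {
  res <- detect_true_peaks(peak_table(sample_id = "A"))
  expect_equal(nrow(res$true_peaks), 0L)
  expect_equal(res$n_iterations, 0L)
  expect_true(is.na(res$final_sd))
})

test_that("two dominant peaks are caught, matching the brute-force loop", {
  pt <- peak_table(seq_len(32) + 30, c(400, 350, rep(2, 30)), "A")
  res <- detect_true_peaks(pt)
  expect_setequal(res$true_peaks$height, c(400, 350))
  expect_lte(res$n_iterations - 1L, 2L)
  expect_equal(which(pt$height %in% res$true_peaks$height),
               oracle_detect(pt$height))
})

test_that("detection is invariant to peak order and uniform rescaling", {
  set.seed(42)
  for (i in 1:25) {
    pt <- random_peak_table()
    base <- sort(detect_true_peaks(pt)$true_peaks$size)
    perm <- sample(nrow(pt))
    shuffled <- peak_table(pt$size[perm], pt$height[perm], "R")
    expect_equal(sort(detect_true_peaks(shuffled)$true_peaks$size), base)
    scaled <- peak_table(pt$size, pt$height * 17.3, "R")
    expect_equal(sort(detect_true_peaks(scaled)$true_peaks$size), base)
  }
})

test_that("raising k_sd never adds true peaks", {
  set.seed(7)
  for (i in 1:25) {
    pt <- random_peak_table()
    counts <- vapply(c(1, 2, 3, 4, 6), function(k) {
      nrow(detect_true_peaks(pt, k_sd = k)$true_peaks)
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("max_iter exhaustion is flagged as non-convergence", {
  # strictly geometric heights peel off one peak per iteration
  pt <- peak_table(seq(30, length.out = 12, by = 3), 10 * 4^(11:0), "A")
  res <- detect_true_peaks(pt, max_iter = 2)
  expect_false(res$converged)
  expect_equal(res$n_iterations, 2L)
})

test_that("binning chains pooled lengths and sums within-sample heights", {
  tps <- list(A = make_tps("A", 100.1, 50), B = make_tps("B", 100.4, 80))
  bm <- bin_fragments(tps, tolerance_bp = 0.5)
  expect_equal(nrow(bm$values), 1L)
  expect_equal(bm$bins$representative_length, 100.25)
  expect_equal(unname(bm$values[1, ]), c(50, 80))

  two <- bin_fragments(list(A = make_tps("A", c(100.0, 100.6), c(1, 2))),
                       tolerance_bp = 0.5)
  expect_equal(nrow(two$values), 2L)

  summed <- bin_fragments(list(A = make_tps("A", c(200.0, 200.3),
                                            c(10, 5))))
  expect_equal(nrow(summed$values), 1L)
  expect_equal(unname(summed$values[1, 1]), 15)
  expect_equal(summed$bins$representative_length, 200.15)
})

test_that("duplicate lengths across samples count once in the average", {
  tps <- list(A = make_tps("A", c(150.0, 150.4), c(5, 5)),
              B = make_tps("B", 150.0, 7))
  bm <- bin_fragments(tps)
  # members {150.0, 150.4}: the duplicated 150.0 is not double-counted
  expect_equal(bm$bins$representative_length, 150.2)
  expect_equal(bm$bins$n_members, 2L)
})

test_that("binning rejects a negative tolerance and handles empty sets", {
  expect_error(bin_fragments(list(A = make_tps("A", 100, 1)), -1),
               ">= 0")
  empty <- bin_fragments(list(A = make_tps("A", numeric(0), numeric(0))))
  expect_equal(nrow(empty$values), 0L)
  expect_equal(ncol(empty$values), 1L)
})

test_that("standardization yields per-sample relative abundances", {
  v <- matrix(c(50, 80, 70), ncol = 1, dimnames = list(NULL, "A"))
  out <- standardize(make_bm(v))
  expect_equal(unname(out$values[, 1]), c(0.25, 0.40, 0.35))
  expect_true(out$standardized)

  one <- standardize(make_bm(matrix(9, dimnames = list(NULL, "A"))))
  expect_equal(unname(one$values[1, 1]), 1)

  vz <- matrix(c(1, 2, 0, 0), ncol = 2,
               dimnames = list(NULL, c("A", "Z")))
  expect_message(zz <- standardize(make_bm(vz)), "no true peaks")
  expect_equal(unname(zz$values[, "Z"]), c(0, 0))
  expect_equal(zz$zero_samples, "Z")
  expect_error(standardize(zz), "already standardized")
})

test_that("binning conserves each sample's total true-peak height", {
  set.seed(13)
  cfg <- default_config()
  cm <- simulate_community(8, seed = 21)
  tps <- lapply(1:4, function(i) {
    pt <- simulate_electropherogram(cm, cfg$sim, seed = 100 + i,
                                    sample_id = paste0("S", i))
    detect_true_peaks(filter_by_size(pt))
  })
  names(tps) <- paste0("S", 1:4)
  bm <- bin_fragments(tps)
  for (id in names(tps)) {
    expect_equal(sum(bm$values[, id]), sum(tps[[id]]$true_peaks$height))
  }
  std <- standardize(bm)
  expect_equal(unname(colSums(std$values)), rep(1, 4), tolerance = 1e-9)
})
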