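test_that("skeleton extraction records totals and group sizes", {
  recs <- groups_to_records(list(c("A", "B"), "A", c("B", "C")))
  sk <- dataset_skeleton(recs)
  expect_equal(sk$totals, c(A = 2L, B = 2L, C = 1L))
  expect_equal(sort(sk$group_sizes), c(1L, 2L, 2L))
  expect_error(dataset_skeleton(groups_to_records(list(c("A", "A")))),
               "duplicate")
})

test_that("infeasible skeletons error before sampling", {
  sk <- skeleton_from(c(A = 3L), c(2L, 1L))
  expect_error(randomize_once(sk), "infeasible")
  sk2 <- skeleton_from(c(A = 2L, B = 1L), c(2L, 1L))
  expect_error(run_randomizations(sk2, 0), ">= 1")
})

test_that("a fully constrained skeleton returns its only valid assignment", {
  # totals {A:2, B:1}, sizes [2, 1]: the only valid outcome is {A,B} + {A}
  sk <- skeleton_from(c(A = 2L, B = 1L), c(2L, 1L))
  set.seed(10)
  for (i in 1:20) {
    r <- randomize_once(sk)
    members <- split(r$feature_name, r$barcode_group_id)
    expect_setequal(members[[which(lengths(members) == 2)]], c("A", "B"))
    expect_equal(members[[which(lengths(members) == 1)]], "A")
  }
  rr <- run_randomizations(sk, 1, seed = 11)
  expect_equal(rr$pair_sums$random_sum, 1)
  expect_equal(rr$pair_sums$feature_a, "A")
  expect_equal(rr$pair_sums$feature_b, "B")
})

test_that("symmetric single-token skeletons are equiprobable over seeds", {
  # {A:1, B:1} into two singleton groups: both assignments equally likely
  sk <- skeleton_from(c(A = 1L, B = 1L), c(1L, 1L))
  set.seed(12)
  n <- 10000
  a_first <- 0L
  for (i in seq_len(n)) {
    r <- randomize_once(sk)
    if (r$feature_name[r$barcode_group_id == 1] == "A") a_first <- a_first + 1L
  }
  chisq <- (a_first - n / 2)^2 / (n / 2) + ((n - a_first) - n / 2)^2 / (n / 2)
  expect_lt(chisq, qchisq(0.999, df = 1))
})

test_that("every randomization conserves the skeleton exactly", {
  set.seed(13)
  for (rep_i in 1:5) {
    nf <- sample(5:20, 1)
    ng <- sample(20:60, 1)
    recs <- generate_dataset(synthetic_config(
      n_features = nf, n_groups = ng, group_size_lambda = 1.4), seed = rep_i)
    sk <- dataset_skeleton(recs$groups)
    for (draw in 1:20) {
      r <- randomize_once(sk)
      expect_equal(sort(as.integer(table(r$barcode_group_id))),
                   sort(sk$group_sizes))
      got_totals <- table(factor(r$feature_name, levels = sk$features))
      expect_equal(as.integer(got_totals), as.integer(sk$totals))
      expect_equal(anyDuplicated(r[c("barcode_group_id", "feature_name")]),
                   0L)
    }
  }
})

test_that("C++ kernel and the pure-R reference sample the same distribution", {
  # compare per-(feature, group-size) occupancy frequencies on a small
  # skeleton between the compiled kernel and the independent R reference
  totals <- c(A = 2L, B = 1L, C = 1L)
  sizes <- c(2L, 1L, 1L)
  n <- 4000
  set.seed(14)
  occ_cpp <- matrix(0, 3, 3, dimnames = list(names(totals), NULL))
  sk <- skeleton_from(totals, sizes)
  for (i in seq_len(n)) {
    r <- randomize_once(sk)
    idx <- cbind(match(r$feature_name, names(totals)), r$barcode_group_id)
    occ_cpp[idx] <- occ_cpp[idx] + 1
  }
  occ_ref <- matrix(0, 3, 3, dimnames = list(names(totals), NULL))
  for (i in seq_len(n)) {
    g <- reference_randomize(totals, sizes)
    for (gi in seq_along(g)) {
      occ_ref[g[[gi]], gi] <- occ_ref[g[[gi]], gi] + 1
    }
  }
  # agreement within 4 binomial SEs cell-wise
  p_ref <- occ_ref / n
  se <- sqrt(pmax(p_ref * (1 - p_ref), 1e-6) / n) * sqrt(2)
  expect_true(all(abs(occ_cpp / n - p_ref) < 4 * se + 1e-9))
})

test_that("randomization shards merge by exact summation", {
  recs <- generate_dataset(synthetic_config(n_features = 12, n_groups = 60,
                                            group_size_lambda = 1.6),
                           seed = 15)
  sk <- dataset_skeleton(recs$groups)
  s1 <- run_randomizations(sk, 50, seed = 16)
  s2 <- run_randomizations(sk, 50, seed = 17)
  merged <- merge_randomizations(s1, s2)
  expect_equal(merged$n_randomizations, 100L)
  both <- dplyr::full_join(merged$pair_sums, s1$pair_sums,
                           by = c("feature_a", "feature_b"),
                           suffix = c("_m", "_1"))
  both <- dplyr::full_join(both, s2$pair_sums, by = c("feature_a",
                                                      "feature_b"))
  both[is.na(both)] <- 0
  expect_equal(both$random_sum_m, both$random_sum_1 + both$random_sum)
  other <- run_randomizations(dataset_skeleton(
    groups_to_records(list(c("X", "Y")))), 5)
  expect_error(merge_randomizations(s1, other), "different skeletons")
})

test_that("background of a fully determined skeleton is exactly zero", {
  # {A:2, B:2} into two groups of 2: every randomization is {A,B}+{A,B},
  # so x = 2, the mean random count is 2 and the log2 ratio is 0
  sk <- skeleton_from(c(A = 2L, B = 2L), c(2L, 2L))
  bg <- background_distribution(sk, 2, seed = 18)
  expect_equal(bg$x, 2L)
  expect_equal(bg$y, 0)
})

test_that("null background is centred near zero at informative counts", {
  recs <- generate_dataset(synthetic_config(
    n_features = 44, n_groups = 10000, group_size_lambda = 1.5,
    abundance_exponent = 0.3), seed = 19)
  sk <- dataset_skeleton(recs$groups)
  bg <- background_distribution(sk, 300, seed = 20)
  informative <- bg$y[bg$x >= 5]
  expect_gt(length(informative), 500)
  expect_lt(abs(mean(informative)), 0.15)
  frac_pos <- mean(informative > 0)
  expect_gt(frac_pos, 0.35)
  expect_lt(frac_pos, 0.65)
  # a pair absent from the randomized dataset is absent from the cloud
  expect_false(any(bg$x < 2))
})

test_that("local p values follow the windowed normal model", {
  # craft a background of exactly 500 points with known mean and sd
  set.seed(21)
  y <- qnorm(seq(0.001, 0.999, length.out = 500), mean = 0.5, sd = 0.25)
  bg <- tibble::tibble(feature_a = "x", feature_b = "y",
                       x = rep(10L, 500), y = y,
                       mean_random_count = 1)
  mu <- mean(y); sigma <- sd(y)
  obs <- tibble::tibble(feature_a = c("A", "A"), feature_b = c("B", "C"),
                        x = c(10L, 10L), y = c(mu, mu + 3 * sigma),
                        mean_random_count = c(2, 2))
  res <- local_significance(obs, bg)
  expect_equal(res$local_p[res$feature_b == "B"], 0.5)
  expect_equal(res$local_p[res$feature_b == "C"],
               pnorm(3, lower.tail = FALSE), tolerance = 1e-6)
  # upper-tail convention: ~0.00135 at +3 sd
  expect_equal(res$local_p[res$feature_b == "C"], 0.00135, tolerance = 0.01)
})

test_that("window selection is nearest-in-count with small-count ties first", {
  # background at x = 5 (y = 0) and x = 15 (y = 10); window of 2 around an
  # observation at x = 10 must take one of each (tie broken to x = 5 first
  # has no effect on the mean here, but the window contents do)
  bg <- tibble::tibble(feature_a = "f", feature_b = "g",
                       x = c(5L, 5L, 15L, 15L), y = c(0, 0, 10, 10),
                       mean_random_count = 1)
  cfg <- significance_config(window_size = 2L)
  obs <- tibble::tibble(feature_a = "A", feature_b = "B", x = 10L, y = 0,
                        mean_random_count = 1)
  res <- suppressWarnings(local_significance(obs, bg, cfg))
  # ties at |5-10| = |15-10|: smaller x first -> window = the two x=5 points
  # -> sd 0 -> degenerate path with y_obs <= mu -> p = 1
  expect_equal(res$local_p, 1)
})

test_that("BH correction is applied over the testable subset only", {
  recs <- generate_dataset(synthetic_config(
    n_features = 30, n_groups = 800, group_size_lambda = 1.6,
    abundance_exponent = 0.3), seed = 22)
  pt <- suppressWarnings(proximity_test(recs$groups, n_randomizations = 150,
                                        seed = 23))
  res <- tidy(pt)
  testable <- res$observed_count >= pt$config$min_observed_for_significance
  expect_true(all(is.na(res$q_value[!testable])))
  expect_equal(res$q_value[testable],
               p.adjust(res$local_p[testable], method = "BH"))
  expect_false(any(res$significant_corrected & !testable))
})

test_that("the proximity test is deterministic under a fixed seed", {
  recs <- generate_dataset(synthetic_config(
    n_features = 25, n_groups = 500, group_size_lambda = 1.5,
    abundance_exponent = 0.3), seed = 24)
  p1 <- suppressWarnings(proximity_test(recs$groups, 100, seed = 99))
  p2 <- suppressWarnings(proximity_test(recs$groups, 100, seed = 99))
  expect_equal(tidy(p1), tidy(p2))
  expect_equal(glance(p1), glance(p2))
})
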