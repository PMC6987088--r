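#' Extract the randomization skeleton of a co-barcoding dataset
#'
#' The skeleton is what every randomization must conserve exactly: the
#' number of proxy reads of each feature and the size of every barcode
#' group.
#'
#' @param records A data frame with `barcode_group_id` and `feature_name`
#'   columns (simulation-formatted records or proxy reads); each feature
#'   must be unique within a group.
#' @return A `proxseq_skeleton`: list with `features` (sorted), `totals`
#'   (named integer vector of per-feature proxy counts) and `group_sizes`
#'   (integer vector, one entry per barcode group).
#' @export
dataset_skeleton <- function(records) {
  stopifnot(all(c("barcode_group_id", "feature_name") %in% names(records)))
  if (anyDuplicated(records[c("barcode_group_id", "feature_name")])) {
    stop("duplicate (barcode_group_id, feature_name): collapse to proxy reads first")
  }
  features <- sort(unique(records$feature_name))
  totals <- table(factor(records$feature_name, levels = features))
  group_sizes <- as.integer(table(records$barcode_group_id))
  structure(list(features = features,
                 totals = setNames(as.integer(totals), features),
                 group_sizes = group_sizes),
            class = "proxseq_skeleton")
}

#' @export
print.proxseq_skeleton <- function(x, ...) {
  cat("Randomization skeleton: ", length(x$features), " features, ",
      length(x$group_sizes), " barcode groups, ",
      sum(x$group_sizes), " proxy reads\n", sep = "")
  invisible(x)
}

check_skeleton <- function(skeleton) {
  stopifnot(inherits(skeleton, "proxseq_skeleton"))
  n_groups <- length(skeleton$group_sizes)
  if (sum(skeleton$totals) != sum(skeleton$group_sizes)) {
    stop("skeleton inconsistent: feature totals and group sizes disagree")
  }
  too_big <- skeleton$totals > n_groups
  if (any(too_big)) {
    stop("infeasible skeleton: feature '",
         names(skeleton$totals)[too_big][1], "' occurs in ",
         skeleton$totals[too_big][1], " groups but only ", n_groups,
         " groups exist")
  }
  invisible(skeleton)
}

skeleton_tokens <- function(skeleton) {
  rep(seq_along(skeleton$features), skeleton$totals)
}

#' Draw one constrained randomization of a dataset
#'
#' Produces one random reassignment of features to barcode groups that
#' conserves the skeleton exactly: each group receives its observed number
#' of distinct features and each feature keeps its total proxy-read count.
#' The feature tokens are shuffled and dealt into groups visited in random
#' order; a token that would duplicate a feature within a group is carried
#' forward and offered first to the next group, so abundant features are
#' not under-represented by rejection.
#'
#' @param skeleton A [dataset_skeleton()].
#' @param seed Optional integer seed (`set.seed()` is called when given).
#' @param max_restarts Restart cap for stuck deals (default 1000).
#' @return A tibble `barcode_group_id`, `feature_name` (one row per proxy
#'   read); the number of restarts is attached as attribute `restarts`.
#' @export
randomize_once <- function(skeleton, seed = NULL, max_restarts = 1000L) {
  check_skeleton(skeleton)
  if (!is.null(seed)) set.seed(seed)
  m <- mc_assign_once(skeleton_tokens(skeleton), skeleton$group_sizes,
                      as.integer(max_restarts))
  out <- tibble::tibble(barcode_group_id = m[, 1],
                        feature_name = skeleton$features[m[, 2]])
  attr(out, "restarts") <- attr(m, "restarts")
  out
}

#' Accumulate pair counts over many randomizations
#'
#' Runs `n` independent constrained randomizations (see [randomize_once()])
#' and accumulates, for every unordered feature pair, the total number of
#' times the pair was co-barcoded across randomizations.
#'
#' @inheritParams randomize_once
#' @param n Number of randomizations (>= 1).
#' @return A `proxseq_randomization` object: list with `pair_sums` (tibble
#'   `feature_a`, `feature_b`, `random_sum`), `n_randomizations`, `restarts`
#'   and the `skeleton`.
#' @export
run_randomizations <- function(skeleton, n, seed = NULL,
                               max_restarts = 1000L) {
  check_skeleton(skeleton)
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  res <- mc_pair_sums(skeleton_tokens(skeleton), skeleton$group_sizes,
                      as.integer(n), as.integer(max_restarts))
  pair_sums <- tibble::tibble(
    feature_a = skeleton$features[res$i],
    feature_b = skeleton$features[res$j],
    random_sum = res$sum)
  pair_sums <- dplyr::arrange(canonicalize_pairs(pair_sums),
                              .data$feature_a, .data$feature_b)
  structure(list(pair_sums = pair_sums, n_randomizations = as.integer(n),
                 restarts = res$restarts, skeleton = skeleton),
            class = "proxseq_randomization")
}

#' @export
print.proxseq_randomization <- function(x, ...) {
  cat("Monte Carlo randomization sums: ", x$n_randomizations,
      " randomizations, ", nrow(x$pair_sums), " pairs ever co-barcoded\n",
      sep = "")
  invisible(x)
}

#' Merge randomization shards into one result
#'
#' Supports sharded execution: shards run with different seeds over the
#' same skeleton are merged by exact summation of pair counts and
#' randomization counts.
#'
#' @param ... `proxseq_randomization` objects over the identical skeleton.
#' @return A merged `proxseq_randomization`.
#' @export
merge_randomizations <- function(...) {
  shards <- list(...)
  stopifnot(length(shards) >= 1L,
            all(vapply(shards, inherits, logical(1), "proxseq_randomization")))
  ref <- shards[[1]]$skeleton
  for (s in shards[-1]) {
    same <- identical(s$skeleton$features, ref$features) &&
      identical(s$skeleton$totals, ref$totals) &&
      identical(sort(s$skeleton$group_sizes), sort(ref$group_sizes))
    if (!same) stop("shards were run on different skeletons")
  }
  pair_sums <- dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(lapply(shards, `[[`, "pair_sums")),
                    .data$feature_a, .data$feature_b),
    random_sum = sum(.data$random_sum), .groups = "drop")
  structure(list(pair_sums = pair_sums,
                 n_randomizations = sum(vapply(shards, `[[`, integer(1),
                                               "n_randomizations")),
                 restarts = sum(vapply(shards, function(s)
                   as.numeric(s$restarts %||% 0), numeric(1))),
                 skeleton = ref),
            class = "proxseq_randomization")
}

#' Significance configuration
#'
#' Tunables of the local-background significance procedure.
#'
#' @param window_size Number of surrounding background points forming the
#'   local distribution (default 500).
#' @param min_observed_for_inclusion Minimum observed co-barcoding count for
#'   a pair to enter the analysis (default 2).
#' @param min_observed_for_significance Minimum observed count for a pair to
#'   be eligible for significance and multiple-testing correction
#'   (default 3).
#' @param local_p_cutoff Local p value call threshold (default 0.01).
#' @param q_cutoff Benjamini-Hochberg q value call threshold (default 0.05).
#' @param zero_mean_floor Floor applied to mean randomized counts of 0 when
#'   forming ratios; `NULL` (default) uses 1 / number of randomizations.
#' @return A `significance_config` list.
#' @export
significance_config <- function(window_size = 500L,
                                min_observed_for_inclusion = 2L,
                                min_observed_for_significance = 3L,
                                local_p_cutoff = 0.01, q_cutoff = 0.05,
                                zero_mean_floor = NULL) {
  stopifnot(window_size >= 2, local_p_cutoff > 0, local_p_cutoff < 1,
            q_cutoff > 0, q_cutoff < 1)
  structure(list(window_size = as.integer(window_size),
                 min_observed_for_inclusion = as.integer(min_observed_for_inclusion),
                 min_observed_for_significance = as.integer(min_observed_for_significance),
                 local_p_cutoff = local_p_cutoff, q_cutoff = q_cutoff,
                 zero_mean_floor = zero_mean_floor),
            class = "significance_config")
}

# count-vs-log2-ratio points for a set of observed pair counts against the
# mean over randomizations
ratio_points <- function(observed_counts, randomization, cfg) {
  floor_val <- cfg$zero_mean_floor %||% (1 / randomization$n_randomizations)
  pts <- dplyr::left_join(canonicalize_pairs(observed_counts),
                          randomization$pair_sums,
                          by = c("feature_a", "feature_b"))
  pts$random_sum[is.na(pts$random_sum)] <- 0
  pts$mean_random_count <- pts$random_sum / randomization$n_randomizations
  pts$x <- pts$observed_count
  pts$y <- log2(pts$x / pmax(pts$mean_random_count, floor_val))
  pts[pts$x >= cfg$min_observed_for_inclusion,
      c("feature_a", "feature_b", "x", "y", "mean_random_count")]
}

#' Build the empirical background distribution
#'
#' One randomization of the observed dataset is itself randomized `n`
#' times; the cloud of (observed count, log2 observed/mean-randomized
#' ratio) points of that known-null dataset defines the expected ratio
#' spread at each co-barcoding count.
#'
#' @inheritParams run_randomizations
#' @param cfg A [significance_config()].
#' @return A tibble of background points `feature_a`, `feature_b`, `x`
#'   (count in the randomized dataset), `y` (log2 ratio), restricted to
#'   pairs with `x >=` `min_observed_for_inclusion`; the number of
#'   randomizations is attached as attribute `n_randomizations`.
#' @export
background_distribution <- function(skeleton, n, cfg = significance_config(),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r1 <- randomize_once(skeleton)
  r1_counts <- pairwise_counts(r1)
  rand <- run_randomizations(skeleton, n)
  out <- ratio_points(r1_counts, rand, cfg)
  attr(out, "n_randomizations") <- as.integer(n)
  out
}

#' Local-background significance for observed RNA pairs
#'
#' Each observed pair, located at (observed count `x`, log2 observed/random
#' ratio `y`), is compared against its local background: the `window_size`
#' background points nearest in `x` (ties broken towards smaller counts).
#' The window's `y` values are modelled as a normal distribution and the
#' pair's local p value is the upper-tail probability of its own `y`.
#' Pairs with at least `min_observed_for_significance` observations undergo
#' Benjamini-Hochberg correction.
#'
#' @param observed A tibble of observed points with columns `feature_a`,
#'   `feature_b`, `x`, `y`, `mean_random_count` (see
#'   [background_distribution()] for the construction; observed data use
#'   the same count-vs-ratio transformation).
#' @param background The background point cloud from
#'   [background_distribution()].
#' @param cfg A [significance_config()].
#' @return A tibble: `feature_a`, `feature_b`, `observed_count`,
#'   `mean_random_count`, `ratio`, `log2_ratio`, `local_p`, `q_value`
#'   (`NA` below the significance count threshold), `significant_local`
#'   and `significant_corrected`.
#' @export
local_significance <- function(observed, background,
                               cfg = significance_config()) {
  if (nrow(observed) == 0L || nrow(background) == 0L) {
    if (nrow(background) == 0L && nrow(observed) > 0L) {
      stop("background distribution is empty")
    }
    return(tibble::tibble(feature_a = character(), feature_b = character(),
                          observed_count = numeric(),
                          mean_random_count = numeric(), ratio = numeric(),
                          log2_ratio = numeric(), local_p = numeric(),
                          q_value = numeric(), significant_local = logical(),
                          significant_corrected = logical()))
  }
  w <- cfg$window_size
  if (nrow(background) < w) {
    warning("background smaller than window (", nrow(background), " < ", w,
            "): using the entire background")
    w <- nrow(background)
  }
  bg_x <- background$x
  bg_y <- background$y
  ord_bg <- order(bg_x)
  bg_x <- bg_x[ord_bg]; bg_y <- bg_y[ord_bg]
  floor_p <- cfg$zero_mean_floor %||%
    (1 / max(attr(background, "n_randomizations") %||% 1e5, 1))
  stats_for <- function(x_obs, y_obs) {
    sel <- order(abs(bg_x - x_obs), bg_x)[seq_len(w)]
    mu <- mean(bg_y[sel])
    sigma <- sd(bg_y[sel])
    if (!is.finite(sigma) || sigma == 0) {
      warning("zero background spread in local window; degenerate p value")
      return(if (y_obs <= mu) 1 else floor_p)
    }
    pnorm(y_obs, mean = mu, sd = sigma, lower.tail = FALSE)
  }
  p <- vapply(seq_len(nrow(observed)),
              function(i) stats_for(observed$x[i], observed$y[i]),
              numeric(1))
  out <- tibble::tibble(
    feature_a = observed$feature_a, feature_b = observed$feature_b,
    observed_count = observed$x,
    mean_random_count = observed$mean_random_count,
    ratio = observed$x / pmax(observed$mean_random_count,
                              .Machine$double.eps),
    log2_ratio = observed$y,
    local_p = p,
    q_value = NA_real_)
  testable <- out$observed_count >= cfg$min_observed_for_significance
  out$q_value[testable] <- p.adjust(out$local_p[testable], method = "BH")
  out$significant_local <- testable & out$local_p <= cfg$local_p_cutoff
  out$significant_corrected <- testable & !is.na(out$q_value) &
    out$q_value <= cfg$q_cutoff
  dplyr::arrange(out, .data$q_value, dplyr::desc(.data$observed_count))
}

#' Full Monte Carlo proximity test
#'
#' End-to-end significance analysis of a co-barcoded dataset: extracts the
#' skeleton, builds the empirical background (one randomization of the
#' data, itself randomized `n_randomizations` times), randomizes the
#' observed data `n_randomizations` times, and scores every observed pair
#' against its local background with Benjamini-Hochberg correction.
#'
#' @inheritParams dataset_skeleton
#' @param n_randomizations Randomizations for both the background and the
#'   observed comparison (default 1000; the reference analysis of a full
#'   dataset uses 100000).
#' @param cfg A [significance_config()].
#' @param seed Optional integer seed for full reproducibility.
#' @return A `proxseq_proximity` object; use [tidy()][generics::tidy] for
#'   the per-pair table, [glance()][generics::glance] for a one-row
#'   summary, and [autoplot()][ggplot2::autoplot] for the count-ratio
#'   plot.
#' @export
proximity_test <- function(records, n_randomizations = 1000L,
                           cfg = significance_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  skeleton <- dataset_skeleton(records)
  observed_counts <- pairwise_counts(records)
  background <- background_distribution(skeleton, n_randomizations, cfg)
  rand <- run_randomizations(skeleton, n_randomizations)
  observed <- ratio_points(observed_counts, rand, cfg)
  results <- local_significance(observed, background, cfg)
  structure(list(results = results, background = background,
                 skeleton = skeleton, config = cfg,
                 n_randomizations = as.integer(n_randomizations)),
            class = "proxseq_proximity")
}

#' @export
print.proxseq_proximity <- function(x, ...) {
  cat("Proximity RNA-seq Monte Carlo test\n")
  cat("  randomizations:", x$n_randomizations, "\n")
  cat("  pairs analysed:", nrow(x$results), "\n")
  cat("  significant (local p <= ", x$config$local_p_cutoff, "): ",
      sum(x$results$significant_local), "\n", sep = "")
  cat("  significant (q <= ", x$config$q_cutoff, "): ",
      sum(x$results$significant_corrected), "\n", sep = "")
  invisible(x)
}
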