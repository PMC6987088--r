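#' Deduplicate reads within barcode groups
#'
#' Reads in the same barcode group with identical mapped coordinates
#' (chromosome, midpoint, strand) are PCR duplicates and collapse to one;
#' identical coordinates in different groups are kept.
#'
#' @param assignments Feature assignments carrying a `barcode_group_id`
#'   column (typically [assign_features()] output joined with the
#'   read-to-group map).
#' @return The deduplicated assignment tibble.
#' @export
deduplicate_reads <- function(assignments) {
  stopifnot("barcode_group_id" %in% names(assignments))
  dplyr::distinct(tibble::as_tibble(assignments),
                  .data$barcode_group_id, .data$chromosome, .data$midpoint,
                  .data$strand, .keep_all = TRUE)
}

#' Remove implausibly large barcode groups
#'
#' Fits the Poisson group-size model ([fit_group_size_threshold()]) to the
#' deduplicated member counts and removes barcode groups larger than the
#' largest size expected at the tail cutoff.
#'
#' @inheritParams deduplicate_reads
#' @param cutoff Poisson upper-tail probability cutoff (default 0.001).
#' @return The filtered tibble; the fitted model is attached as attribute
#'   `group_size_model`.
#' @export
apply_group_size_cap <- function(assignments, cutoff = 0.001) {
  stopifnot("barcode_group_id" %in% names(assignments))
  assignments <- tibble::as_tibble(assignments)
  if (nrow(assignments) == 0L) return(assignments)
  sizes <- dplyr::count(assignments, .data$barcode_group_id)
  model <- fit_group_size_threshold(sizes$n, cutoff)
  keep <- sizes$barcode_group_id[sizes$n <= model$max_allowed_size]
  out <- assignments[assignments$barcode_group_id %in% keep, ]
  attr(out, "group_size_model") <- model
  out
}

#' Collapse assignments into proxy reads
#'
#' A transcript is counted once per barcode group regardless of how many of
#' its reads carry that barcode (one RNA molecule may be reverse-transcribed
#' several times, and copies of one transcript in a particle cannot be
#' distinguished): each distinct (barcode group, feature) observation is one
#' proxy read.
#'
#' @param assignments Deduplicated assignments with `barcode_group_id` and
#'   `feature_name` columns; rows with `NA` feature are dropped.
#' @return A tibble of proxy reads, one row per (group, feature), retaining
#'   the first row's coordinate columns where present.
#' @export
make_proxy_reads <- function(assignments) {
  stopifnot(all(c("barcode_group_id", "feature_name") %in% names(assignments)))
  keep <- !is.na(assignments$feature_name)
  dplyr::distinct(tibble::as_tibble(assignments)[keep, ],
                  .data$barcode_group_id, .data$feature_name,
                  .keep_all = TRUE)
}

#' Restrict proxy reads to predefined transcripts
#'
#' @param proxies Proxy reads from [make_proxy_reads()].
#' @param allowed_features Character vector of feature names to keep;
#'   `NULL` keeps everything, an empty vector keeps nothing.
#' @return Filtered proxy reads.
#' @export
restrict_features <- function(proxies, allowed_features = NULL) {
  if (is.null(allowed_features)) return(proxies)
  proxies[proxies$feature_name %in% allowed_features, ]
}

#' Count pairwise co-barcoding between features
#'
#' Each barcode group of k features contributes one count to each of its
#' k(k-1)/2 unordered feature pairs; counts are summed over groups. These
#' co-barcoding counts are the observable for RNA-RNA proximity.
#'
#' @param proxies Proxy reads (`barcode_group_id`, `feature_name`), unique
#'   per (group, feature).
#' @return A tibble `feature_a`, `feature_b` (canonical lexicographic
#'   order), `observed_count`, sorted by descending count.
#' @export
pairwise_counts <- function(proxies) {
  empty <- tibble::tibble(feature_a = character(), feature_b = character(),
                          observed_count = integer())
  if (nrow(proxies) == 0L) return(empty)
  groups <- split(proxies$feature_name, proxies$barcode_group_id)
  groups <- groups[lengths(groups) >= 2L]
  if (length(groups) == 0L) return(empty)
  pairs <- purrr::map(groups, function(f) {
    f <- sort(f)
    m <- combn(f, 2L)
    tibble::tibble(feature_a = m[1, ], feature_b = m[2, ])
  })
  out <- dplyr::count(dplyr::bind_rows(pairs), .data$feature_a,
                      .data$feature_b, name = "observed_count")
  dplyr::arrange(out, dplyr::desc(.data$observed_count), .data$feature_a,
                 .data$feature_b)
}

#' Summarize a pipeline run
#'
#' Collates per-stage tallies into the standard run summary: read counts
#' and percentages through primer matching, barcode filtering, grouping,
#' mapping, deduplication and proxy-read collapse, the barcode-group size
#' histogram, and the percentage of proxy reads that are co-barcoded
#' (proxy reads in groups of size >= 2 over all proxy reads).
#'
#' @param tallies A named list of stage tallies as produced by [run_map()]:
#'   `n_reads`, `n_fixed_seq`, `n_filter_pass`, `n_unique_barcodes`,
#'   `n_barcode_groups`, `n_reads_allocated`, `n_unique_mapped`,
#'   `n_repeat_multimapped`, `n_discarded_multimapped`, `n_unmapped`,
#'   `n_for_dedup`, `n_after_dedup_cap`, `n_within_annotation`,
#'   `n_proxy_reads`, plus `proxy_group_sizes` (integer vector: the size of
#'   the barcode group each proxy read belongs to).
#' @return A tibble with columns `metric` and `value`.
#' @export
summarize_run <- function(tallies) {
  t <- tallies
  pct <- function(a, b) if (is.null(a) || is.null(b) || !length(b) || b == 0)
    NA_real_ else round(100 * a / b, 2)
  gs <- t$proxy_group_sizes %||% integer()
  hist_k <- vapply(1:5, function(k) sum(gs == k), numeric(1))
  hist_6p <- sum(gs >= 6)
  n_groups_with_proxies <- length(gs)
  proxy_sizes <- t$proxy_sizes %||% integer()  # per proxy read, its group size
  pct_cobarcoded <- if (length(proxy_sizes))
    round(100 * mean(proxy_sizes >= 2), 2) else NA_real_
  tibble::tibble(
    metric = c("Sequencing reads", "Matching Fixed_Seq", "%Matching Fixed_Seq",
               "LC & Adapter Pass", "%LC & Adapter Pass", "Unique barcodes",
               "Barcode groups", "Reads allocated to barcode groups",
               "Uniquely mapped", "Multi-mapped on RNA repeats",
               "Multi-mapped (discarded)", "Unmapped", "%Mapped",
               "Reads for further use",
               "%PCR deduplication, barcode group size limit",
               "%Within annotation", "%Proxy reads", "Proxy reads",
               "Barcode groups with proxy reads",
               paste("Reads in barcode group", 1:5),
               "Reads in barcode group 6+", "%Proxy reads co-barcoded"),
    value = c(t$n_reads, t$n_fixed_seq, pct(t$n_fixed_seq, t$n_reads),
              t$n_filter_pass, pct(t$n_filter_pass, t$n_fixed_seq),
              t$n_unique_barcodes, t$n_barcode_groups, t$n_reads_allocated,
              t$n_unique_mapped, t$n_repeat_multimapped,
              t$n_discarded_multimapped, t$n_unmapped,
              pct(t$n_unique_mapped + t$n_repeat_multimapped,
                  t$n_reads_allocated),
              t$n_for_dedup, pct(t$n_after_dedup_cap, t$n_for_dedup),
              pct(t$n_within_annotation, t$n_after_dedup_cap),
              pct(t$n_proxy_reads, t$n_within_annotation), t$n_proxy_reads,
              n_groups_with_proxies, hist_k, hist_6p, pct_cobarcoded)
  )
}
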