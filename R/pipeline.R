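#' Run the read-processing stage of the pipeline
#'
#' Orchestrates the mapping/QC half of the analysis: primer validation,
#' barcode extraction and filtering, barcode grouping, joining with
#' externally produced alignments, annotation assignment, PCR
#' deduplication, Poisson group-size capping, proxy-read collapse, and the
#' simulation-formatted output. Alignment itself is external: produce the
#' SAM with any splice-aware aligner run on the trimmed cDNA, and pass it
#' in via `sam`.
#'
#' @param fastq Path to the FASTQ file, or a reads tibble from
#'   [read_fastq()].
#' @param sam Path to the SAM file with cDNA alignments (read ids must
#'   match the FASTQ), or an alignments tibble from
#'   [read_sam_alignments()].
#' @param genes Gene annotation rows (tibble or path readable by
#'   [read_feature_list()]).
#' @param repeats Repeat annotation rows (tibble or path), or `NULL`.
#' @param layout A [read_layout()].
#' @param adapters Adapter screen sequences (default [default_adapters()]).
#' @param link_edit_distance Barcode-group linking distance (default 2).
#' @param size_cutoff Poisson group-size tail cutoff (default 0.001).
#' @param allowed_features Optional restriction to predefined transcripts.
#' @param output_dir Optional directory; when given, the
#'   simulation-formatted file, resolved annotation and summary table are
#'   written there.
#' @return A list: `sim_records`, `proxies`, `assignments` (post-dedup/cap),
#'   `barcode_groups` (read to group map), `annotation`, `summary`
#'   ([summarize_run()] tibble) and `tallies`.
#' @export
run_map <- function(fastq, sam, genes, repeats = NULL,
                    layout = read_layout(), adapters = default_adapters(),
                    link_edit_distance = 2L, size_cutoff = 0.001,
                    allowed_features = NULL, output_dir = NULL) {
  reads <- if (is.character(fastq)) read_fastq(fastq) else
    tibble::as_tibble(fastq)
  if (is.character(genes)) genes <- read_feature_list(genes)
  if (is.character(repeats)) repeats <- read_feature_list(repeats,
                                                          repeats = TRUE)
  t <- list(n_reads = nrow(reads))

  chk <- check_fixed_sequence(reads, layout)
  passed <- reads[chk$pass, ]
  t$n_fixed_seq <- nrow(passed)

  barcode <- extract_trimmed_barcode(passed, layout)
  keep <- low_complexity_filter(barcode) &
    adapter_similarity_filter(barcode, adapters, layout)
  passed <- passed[keep, ]
  barcode <- barcode[keep]
  t$n_filter_pass <- nrow(passed)
  t$n_unique_barcodes <- length(unique(barcode))

  bc_groups <- group_barcodes(barcode, link_edit_distance)
  read_groups <- dplyr::left_join(
    tibble::tibble(read_id = passed$read_id, barcode = barcode),
    bc_groups, by = "barcode")
  t$n_barcode_groups <- max(c(bc_groups$group_id, 0L))
  t$n_reads_allocated <- nrow(read_groups)

  aln <- if (is.character(sam)) read_sam_alignments(sam) else
    tibble::as_tibble(sam)
  aln <- aln[aln$read_id %in% read_groups$read_id, ]

  annotation <- build_annotation(genes, repeats)
  assign <- assign_features(aln, annotation)
  assign <- dplyr::inner_join(assign,
                              read_groups[c("read_id", "group_id")],
                              by = "read_id")
  names(assign)[names(assign) == "group_id"] <- "barcode_group_id"

  t$n_unique_mapped <- sum(assign$status %in% c("unique", "unassigned"))
  t$n_repeat_multimapped <- sum(assign$status == "repeat_multimap")
  t$n_discarded_multimapped <- sum(assign$status == "discarded_multimap")
  t$n_unmapped <- t$n_reads_allocated - dplyr::n_distinct(aln$read_id)

  usable <- assign[assign$status %in%
                     c("unique", "unassigned", "repeat_multimap"), ]
  t$n_for_dedup <- nrow(usable)
  deduped <- deduplicate_reads(usable)
  capped <- apply_group_size_cap(deduped, size_cutoff)
  t$n_after_dedup_cap <- nrow(capped)
  annotated <- capped[!is.na(capped$feature_name), ]
  t$n_within_annotation <- nrow(annotated)

  proxies <- make_proxy_reads(annotated)
  proxies <- restrict_features(proxies, allowed_features)
  t$n_proxy_reads <- nrow(proxies)
  proxy_sizes_by_group <- dplyr::count(proxies, .data$barcode_group_id)
  t$proxy_group_sizes <- proxy_sizes_by_group$n
  t$proxy_sizes <- dplyr::left_join(proxies, proxy_sizes_by_group,
                                    by = "barcode_group_id")$n

  feature_coords <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(annotation), .data$feature_name),
    chromosome = .data$chromosome[1], start = min(.data$start),
    end = max(.data$end), strand = .data$strand[1], .groups = "drop")
  sim_records <- as_simulation_records(dplyr::left_join(
    proxies[c("barcode_group_id", "feature_name")], feature_coords,
    by = "feature_name"))

  summary <- summarize_run(t)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_simulation_formatted(
      sim_records, file.path(output_dir, "simulation_formatted.txt.gz"))
    write_annotation_table(annotation,
                           file.path(output_dir, "annotation.txt.gz"))
    write_tsv_gz(summary, file.path(output_dir, "summary_results.txt"))
    # intermediate interactions file: group ids + read midpoint coordinates
    write_tsv_gz(capped[c("barcode_group_id", "read_id", "chromosome",
                          "midpoint", "strand", "feature_name", "status")],
                 file.path(output_dir, "interactions.txt.gz"))
  }
  list(sim_records = sim_records, proxies = proxies, assignments = capped,
       barcode_groups = read_groups, annotation = annotation,
       summary = summary, tallies = t)
}

#' Run Monte Carlo simulations over a co-barcoded dataset
#'
#' Without `random`, the observed dataset is randomized `n` times and its
#' pair counts are compared with the accumulated random counts. With
#' `random = TRUE`, one randomization of the dataset is generated first and
#' then treated as the observed data (the background branch used by
#' [run_correction()] as the control).
#'
#' @param records Simulation-formatted records (tibble or file path).
#' @param n Number of randomizations.
#' @param random Generate and analyse a randomized dataset instead of the
#'   observed one.
#' @param seed Optional integer seed.
#' @param path Optional output path for the collated results table.
#' @return A tibble `feature_a`, `feature_b`, `observed_count`,
#'   `random_sum`, `mean_random_count`, `n_randomizations`, with attribute
#'   `random` marking the background branch.
#' @export
run_simulations <- function(records, n, random = FALSE, seed = NULL,
                            path = NULL) {
  if (n < 1) stop("number of simulations must be >= 1")
  if (is.character(records)) records <- read_simulation_formatted(records)
  if (!is.null(seed)) set.seed(seed)
  skeleton <- dataset_skeleton(records)
  if (random) records <- randomize_once(skeleton)
  obs <- pairwise_counts(records)
  rand <- run_randomizations(skeleton, n)
  out <- dplyr::full_join(obs, rand$pair_sums, by = c("feature_a",
                                                      "feature_b"))
  out$observed_count[is.na(out$observed_count)] <- 0L
  out$random_sum[is.na(out$random_sum)] <- 0
  out$mean_random_count <- out$random_sum / n
  out$n_randomizations <- as.integer(n)
  out <- dplyr::arrange(out, dplyr::desc(.data$observed_count),
                        .data$feature_a, .data$feature_b)
  attr(out, "random") <- random
  if (!is.null(path)) {
    tagged <- out
    tagged$dataset <- if (random) "background" else "observed"
    write_tsv_gz(tagged, path)
  }
  out
}

#' Read collated simulation results written by [run_simulations()]
#'
#' @param path Path to the results table.
#' @return The results tibble; attribute `random` is restored from the
#'   `dataset` column.
#' @export
read_simulation_results <- function(path) {
  out <- read_tsv_gz(path, col_types = c(
    feature_a = "character", feature_b = "character",
    observed_count = "integer", random_sum = "double",
    mean_random_count = "double", n_randomizations = "integer"))
  random <- "dataset" %in% names(out) && any(out$dataset == "background")
  out$dataset <- NULL
  attr(out, "random") <- random
  out
}

#' Local-background multiple-testing correction of simulation results
#'
#' Compares randomizations of the observed dataset (`results`) against
#' randomizations of one random dataset (`control`, the background): each
#' observed pair is scored against the local background distribution and
#' Benjamini-Hochberg corrected (see [local_significance()]).
#'
#' @param control Background simulation results ([run_simulations()] with
#'   `random = TRUE`; tibble or path).
#' @param results Observed simulation results (tibble or path).
#' @param cfg A [significance_config()].
#' @param path Optional output path for the q-value table (written with
#'   [write_qval_table()]).
#' @return The significance tibble from [local_significance()].
#' @export
run_correction <- function(control, results, cfg = significance_config(),
                           path = NULL) {
  if (is.character(control)) control <- read_simulation_results(control)
  if (is.character(results)) results <- read_simulation_results(results)
  feats_c <- unique(c(control$feature_a, control$feature_b))
  feats_r <- unique(c(results$feature_a, results$feature_b))
  if (!setequal(feats_c, feats_r)) {
    warning("control and results cover different feature universes; ",
            "intersecting")
    common <- intersect(feats_c, feats_r)
    control <- control[control$feature_a %in% common &
                         control$feature_b %in% common, ]
    results <- results[results$feature_a %in% common &
                         results$feature_b %in% common, ]
  }
  to_points <- function(tab) {
    n <- tab$n_randomizations[1] %||% 1L
    floor_val <- cfg$zero_mean_floor %||% (1 / n)
    pts <- tab[tab$observed_count >= cfg$min_observed_for_inclusion, ]
    x <- pts$observed_count
    tibble::tibble(feature_a = pts$feature_a, feature_b = pts$feature_b,
                   x = x,
                   y = log2(x / pmax(pts$mean_random_count, floor_val)),
                   mean_random_count = pts$mean_random_count)
  }
  background <- to_points(control)
  attr(background, "n_randomizations") <- control$n_randomizations[1]
  observed <- to_points(results)
  sig <- local_significance(observed, background, cfg)
  if (!is.null(path)) {
    write_qval_table(tibble::tibble(
      feature_a = sig$feature_a, feature_b = sig$feature_b,
      observed_count = sig$observed_count,
      mean_random_count = sig$mean_random_count,
      p_value = sig$local_p, q_value = sig$q_value), path)
  }
  sig
}

#' Compute and optionally write the valency table for a dataset
#'
#' @param records Simulation-formatted records (tibble or path).
#' @param path Optional output path ([write_valency_table()] format).
#' @return The long valency tibble from [valency_distribution()].
#' @export
run_valency <- function(records, path = NULL) {
  if (is.character(records)) records <- read_simulation_formatted(records)
  out <- valency_distribution(records)
  if (!is.null(path)) write_valency_table(out, path)
  out
}
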