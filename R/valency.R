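#' Per-feature valency distribution
#'
#' Valency is an estimate of local RNA density or connectivity: valency 1
#' counts the barcode groups in which a transcript was detected alone,
#' valency 2 those where it shared the barcode with one other transcript,
#' and so on. The group size is the number of distinct features (proxy
#' reads) in the group after all filtering.
#'
#' @param records Simulation-formatted records or proxy reads
#'   (`barcode_group_id`, `feature_name`; unique per group).
#' @return A long tibble `feature_name`, `group_size`, `count` where
#'   `count` is the number of groups of that size containing the feature.
#'   Summed over sizes, a feature's counts equal its proxy-read total.
#' @export
valency_distribution <- function(records) {
  stopifnot(all(c("barcode_group_id", "feature_name") %in% names(records)))
  if (anyDuplicated(records[c("barcode_group_id", "feature_name")])) {
    stop("duplicate (barcode_group_id, feature_name): collapse to proxy reads first")
  }
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L) {
    return(tibble::tibble(feature_name = character(), group_size = integer(),
                          count = integer()))
  }
  sizes <- dplyr::count(records, .data$barcode_group_id, name = "group_size")
  long <- dplyr::left_join(records, sizes, by = "barcode_group_id")
  out <- dplyr::count(long, .data$feature_name, .data$group_size,
                      name = "count")
  dplyr::arrange(out, .data$feature_name, .data$group_size)
}

#' Classify transcripts into valency classes
#'
#' Transcripts with more than `min_sum` proxy reads across valencies 1-3
#' qualify. For each qualifying transcript the counts at valency 1, 2 and 3
#' are divided by their sum; each of the three fraction distributions is
#' then z-scored across qualifying transcripts. A transcript is high
#' valency when its valency-1 z-score is below 0 and the mean of its
#' valency-2 and valency-3 z-scores is above 0; low valency in the mirror
#' case; otherwise middle. Non-qualifying transcripts are unassigned.
#'
#' @param valency A long valency table from [valency_distribution()].
#' @param min_sum Qualification threshold: the valency 1-3 sum must be
#'   strictly greater than this (default 10).
#' @return A tibble `feature_name`, `v1`, `v2`, `v3` (counts), `f1`-`f3`
#'   (fractions), `z1`-`z3` (z-scores, `NA` for unassigned), `class` in
#'   `high`, `low`, `middle`, `unassigned`.
#' @export
classify_valency <- function(valency, min_sum = 10L) {
  stopifnot(nrow(valency) > 0L)
  counts <- tidyr::pivot_wider(
    dplyr::filter(valency, .data$group_size <= 3L),
    id_cols = "feature_name", names_from = "group_size",
    values_from = "count", names_prefix = "v", values_fill = 0L)
  for (col in c("v1", "v2", "v3")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  all_features <- unique(valency$feature_name)
  counts <- dplyr::right_join(counts[c("feature_name", "v1", "v2", "v3")],
                              tibble::tibble(feature_name = all_features),
                              by = "feature_name")
  counts[is.na(counts)] <- 0L
  total <- counts$v1 + counts$v2 + counts$v3
  qualifying <- total > min_sum
  if (sum(qualifying) < 2L) {
    stop("fewer than 2 transcripts qualify (valency 1-3 sum > ", min_sum,
         "); z-scores undefined")
  }
  out <- counts
  out$f1 <- out$f2 <- out$f3 <- NA_real_
  out$f1[qualifying] <- counts$v1[qualifying] / total[qualifying]
  out$f2[qualifying] <- counts$v2[qualifying] / total[qualifying]
  out$f3[qualifying] <- counts$v3[qualifying] / total[qualifying]
  zscore <- function(f) {
    s <- sd(f[qualifying])
    if (!is.finite(s) || s == 0) {
      stop("degenerate valency fractions: zero spread across qualifying transcripts")
    }
    (f - mean(f[qualifying])) / s
  }
  out$z1 <- zscore(out$f1)
  out$z2 <- zscore(out$f2)
  out$z3 <- zscore(out$f3)
  z23 <- (out$z2 + out$z3) / 2
  out$class <- dplyr::case_when(
    !qualifying ~ "unassigned",
    out$z1 < 0 & z23 > 0 ~ "high",
    out$z1 > 0 & z23 < 0 ~ "low",
    TRUE ~ "middle")
  out$z1[!qualifying] <- NA_real_
  out$z2[!qualifying] <- NA_real_
  out$z3[!qualifying] <- NA_real_
  dplyr::arrange(tibble::as_tibble(out), .data$feature_name)
}

#' Consensus valency classes across libraries
#'
#' A transcript keeps the high (resp. low) class only when it was classed
#' high (resp. low) in every input library; all other transcripts are
#' dropped.
#'
#' @param classifications A list of [classify_valency()] tables (one per
#'   library/replicate).
#' @return A tibble `feature_name`, `class` (high or low only) plus the
#'   mean across libraries of each z-score (`z1`, `z2`, `z3`).
#' @export
consensus_classes <- function(classifications) {
  stopifnot(length(classifications) >= 1L)
  combined <- dplyr::bind_rows(classifications, .id = "library")
  per_feature <- dplyr::summarise(
    dplyr::group_by(combined, .data$feature_name),
    n_lib = dplyr::n(),
    all_high = all(.data$class == "high"),
    all_low = all(.data$class == "low"),
    z1 = mean(.data$z1), z2 = mean(.data$z2), z3 = mean(.data$z3),
    .groups = "drop")
  n_lib_total <- length(classifications)
  keep <- per_feature$n_lib == n_lib_total &
    (per_feature$all_high | per_feature$all_low)
  out <- per_feature[keep, ]
  out$class <- ifelse(out$all_high, "high", "low")
  dplyr::arrange(out[c("feature_name", "class", "z1", "z2", "z3")],
                 .data$feature_name)
}

#' Export a proximity network as edge and node attribute tables
#'
#' Pairwise proximities at or below `p_cutoff` become edges weighted by
#' `-log10(p)` capped at 10; valency classifications become node attributes
#' (the mean of the valency 1-3 z-scores and the class).
#'
#' @param proximity A per-pair significance table ([local_significance()]
#'   output or [tidy()][generics::tidy] of a [proximity_test()]).
#' @param classification A [classify_valency()] or [consensus_classes()]
#'   table; may be `NULL`.
#' @param p_cutoff Edge inclusion threshold on the local p value
#'   (default 0.1).
#' @param edge_path,node_path Optional output paths (tab-delimited, `.gz`
#'   supported).
#' @param weight_cap Cap on the `-log10(p)` edge weight (default 10).
#' @return A list with tibbles `edges` (`feature_a`, `feature_b`,
#'   `weight`) and `nodes` (`feature_name`, `mean_z`, `class`).
#' @export
export_network <- function(proximity, classification = NULL, p_cutoff = 0.1,
                           edge_path = NULL, node_path = NULL,
                           weight_cap = 10) {
  keep <- proximity$local_p <= p_cutoff
  edges <- tibble::tibble(
    feature_a = proximity$feature_a[keep],
    feature_b = proximity$feature_b[keep],
    weight = pmin(-log10(pmax(proximity$local_p[keep],
                              .Machine$double.xmin)), weight_cap))
  nodes <- if (is.null(classification)) {
    tibble::tibble(feature_name = sort(unique(c(edges$feature_a,
                                                edges$feature_b))),
                   mean_z = NA_real_, class = "unassigned")
  } else {
    tibble::tibble(
      feature_name = classification$feature_name,
      mean_z = rowMeans(cbind(classification$z1, classification$z2,
                              classification$z3)),
      class = classification$class)
  }
  if (!is.null(edge_path)) write_tsv_gz(edges, edge_path)
  if (!is.null(node_path)) write_tsv_gz(nodes, node_path)
  list(edges = edges, nodes = nodes)
}
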