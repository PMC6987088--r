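#' Build a conflict-resolved transcriptome annotation
#'
#' Resolves overlapping gene and repeat annotations into a disjoint set of
#' labelled intervals using the priority rules of the pipeline:
#'
#' 1. Repeat regions take priority over genes and claim their coordinates on
#'    both strands; repeat elements of one class (e.g. all tRNAs) are
#'    collapsed into one feature named after the class. Bases claimed by two
#'    or more different repeat classes are ambiguous and removed (they still
#'    block genes).
#' 2. The forward and reverse strands are then processed independently for
#'    genes. Where a gene is wholly contained within another, the inner
#'    feature wins its interval and the outer keeps its flanks; where two
#'    genes overlap partially, the shared region is ambiguous and removed
#'    from both. Identical intervals carrying two names are ambiguous.
#'    The rules apply transitively: at every base the winning gene is the
#'    one whose full interval is contained in all other genes covering that
#'    base.
#'
#' The result is deterministic and independent of input row order.
#'
#' @param genes Annotation rows for genes/transcripts (see
#'   [annotation_rows()]); `is_repeat` must be `FALSE`.
#' @param repeats Annotation rows for repeat elements with `repeat_class`
#'   set; may be `NULL` or empty.
#' @return A tibble of disjoint intervals (`chromosome`, `start`, `end`,
#'   `strand`, `feature_name`, `is_repeat`) with class `proxseq_annotation`.
#'   Repeat intervals carry strand `"."`. Attribute `ambiguous_removed`
#'   records the removed ambiguous regions.
#' @export
build_annotation <- function(genes, repeats = NULL) {
  genes <- annotation_rows(genes)
  if (any(genes$is_repeat)) stop("repeat rows supplied in `genes`")
  if (is.null(repeats) || nrow(tibble::as_tibble(repeats)) == 0L) {
    repeats <- annotation_rows(tibble::tibble(
      chromosome = character(), start = integer(), end = integer(),
      strand = character(), feature_name = character(),
      is_repeat = logical(), repeat_class = character()))
  } else {
    repeats <- annotation_rows(repeats)
    if (!all(repeats$is_repeat)) stop("non-repeat rows supplied in `repeats`")
  }
  check_consistent_genes(genes)
  genes <- dplyr::distinct(genes)

  # --- repeat layer: strand-agnostic, classes collapsed -------------------
  repeats$feature_name <- repeats$repeat_class
  rep_out <- list(); rep_ambig <- list()
  rep_union <- list()  # full claimed region per chromosome (blocks genes)
  for (chr in unique(repeats$chromosome)) {
    r <- repeats[repeats$chromosome == chr, ]
    pieces <- disjoin_intervals(r$start, r$end)
    cover <- covering_sets(pieces, r$start, r$end)
    classes <- lapply(cover, function(i) unique(r$feature_name[i]))
    one <- lengths(classes) == 1L
    if (any(one)) {
      rep_out[[chr]] <- tibble::tibble(
        chromosome = chr, start = pieces$start[one], end = pieces$end[one],
        strand = ".", feature_name = unlist(classes[one]), is_repeat = TRUE)
    }
    if (any(!one)) {
      rep_ambig[[chr]] <- tibble::tibble(
        chromosome = chr, start = pieces$start[!one], end = pieces$end[!one],
        strand = ".", reason = "repeat_class_conflict")
    }
    rep_union[[chr]] <- merge_touching(pieces$start, pieces$end)
  }

  # --- gene layer: per strand, repeat region subtracted -------------------
  gene_out <- list(); gene_ambig <- list()
  keys <- unique(genes[c("chromosome", "strand")])
  for (k in seq_len(nrow(keys))) {
    chr <- keys$chromosome[k]; std <- keys$strand[k]
    g <- genes[genes$chromosome == chr & genes$strand == std, ]
    pieces <- disjoin_intervals(g$start, g$end)
    cover <- covering_sets(pieces, g$start, g$end)
    winner <- vapply(cover, function(i) containment_winner(g$start[i], g$end[i], i),
                     integer(1))
    amb <- winner == 0L
    if (any(amb)) {
      gene_ambig[[paste(chr, std)]] <- tibble::tibble(
        chromosome = chr, start = pieces$start[amb], end = pieces$end[amb],
        strand = std, reason = "gene_overlap")
    }
    ps <- pieces$start[!amb]; pe <- pieces$end[!amb]
    nm <- g$feature_name[winner[!amb]]
    blocked <- rep_union[[chr]]
    if (!is.null(blocked) && length(ps)) {
      cut <- subtract_intervals(ps, pe, nm, blocked$start, blocked$end)
      ps <- cut$start; pe <- cut$end; nm <- cut$label
    }
    if (length(ps)) {
      gene_out[[paste(chr, std)]] <- tibble::tibble(
        chromosome = chr, start = ps, end = pe, strand = std,
        feature_name = nm, is_repeat = FALSE)
    }
  }

  out <- dplyr::bind_rows(c(rep_out, gene_out))
  if (nrow(out) == 0L) {
    out <- tibble::tibble(chromosome = character(), start = integer(),
                          end = integer(), strand = character(),
                          feature_name = character(), is_repeat = logical())
  } else {
    out <- merge_adjacent_labels(out)
    out <- out[order(out$chromosome, out$start, out$strand), ]
  }
  attr(out, "ambiguous_removed") <- dplyr::bind_rows(c(rep_ambig, gene_ambig))
  class(out) <- c("proxseq_annotation", class(out))
  out
}

check_consistent_genes <- function(genes) {
  per_name <- dplyr::summarise(
    dplyr::group_by(genes, .data$feature_name),
    n = dplyr::n_distinct(.data$chromosome, .data$start, .data$end, .data$strand),
    .groups = "drop")
  bad <- per_name$feature_name[per_name$n > 1L]
  if (length(bad)) {
    stop("gene '", bad[1], "' listed with inconsistent coordinates")
  }
}

# disjoint pieces spanned by a set of intervals (1-based inclusive)
disjoin_intervals <- function(start, end) {
  if (length(start) == 0L) return(list(start = integer(), end = integer()))
  bp <- sort(unique(c(start, end + 1L)))
  ps <- bp[-length(bp)]
  pe <- bp[-1L] - 1L
  covered <- vapply(ps, function(p) any(start <= p & end >= p), logical(1))
  list(start = ps[covered], end = pe[covered])
}

# which input intervals cover each piece (pieces never straddle boundaries)
covering_sets <- function(pieces, start, end) {
  lapply(pieces$start, function(p) which(start <= p & end >= p))
}

# index of the gene whose full interval is contained in all others covering
# a piece; 0 when ambiguous (partial overlap or identical-interval tie)
containment_winner <- function(starts, ends, idx) {
  if (length(idx) == 1L) return(idx)
  contained_in_all <- which(vapply(seq_along(idx), function(i) {
    all(starts[i] >= starts & ends[i] <= ends)
  }, logical(1)))
  if (length(contained_in_all) != 1L) return(0L)
  idx[contained_in_all]
}

# union of intervals, merging overlapping/touching runs
merge_touching <- function(start, end) {
  if (length(start) == 0L) return(NULL)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  out_s <- start[1]; out_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= out_e[length(out_e)] + 1L) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], end[i])
    } else {
      out_s <- c(out_s, start[i]); out_e <- c(out_e, end[i])
    }
  }
  list(start = out_s, end = out_e)
}

# remove blocked regions from labelled intervals, splitting where needed
subtract_intervals <- function(start, end, label, b_start, b_end) {
  out_s <- integer(); out_e <- integer(); out_l <- character()
  for (i in seq_along(start)) {
    segs_s <- start[i]; segs_e <- end[i]
    for (j in seq_along(b_start)) {
      new_s <- integer(); new_e <- integer()
      for (k in seq_along(segs_s)) {
        if (b_end[j] < segs_s[k] || b_start[j] > segs_e[k]) {
          new_s <- c(new_s, segs_s[k]); new_e <- c(new_e, segs_e[k])
        } else {
          if (b_start[j] > segs_s[k]) {
            new_s <- c(new_s, segs_s[k]); new_e <- c(new_e, b_start[j] - 1L)
          }
          if (b_end[j] < segs_e[k]) {
            new_s <- c(new_s, b_end[j] + 1L); new_e <- c(new_e, segs_e[k])
          }
        }
      }
      segs_s <- new_s; segs_e <- new_e
    }
    out_s <- c(out_s, segs_s); out_e <- c(out_e, segs_e)
    out_l <- c(out_l, rep(label[i], length(segs_s)))
  }
  list(start = out_s, end = out_e, label = out_l)
}

# merge contiguous pieces carrying the same feature label
merge_adjacent_labels <- function(out) {
  out <- out[order(out$chromosome, out$strand, out$feature_name, out$start), ]
  same_run <- with(out, c(FALSE,
    chromosome[-1] == chromosome[-nrow(out)] &
    strand[-1] == strand[-nrow(out)] &
    feature_name[-1] == feature_name[-nrow(out)] &
    start[-1] == end[-nrow(out)] + 1L))
  run_id <- cumsum(!same_run)
  dplyr::summarise(dplyr::group_by(out, run_id = run_id),
                   chromosome = .data$chromosome[1], start = min(.data$start),
                   end = max(.data$end), strand = .data$strand[1],
                   feature_name = .data$feature_name[1],
                   is_repeat = .data$is_repeat[1], .groups = "drop")[-1]
}

#' Assign mapped reads to annotation features
#'
#' Reads are assigned by the midpoint of their alignment,
#' `floor((start + end) / 2)`. Uniquely mapping reads take the feature whose
#' interval contains the midpoint on the read's strand (repeat intervals
#' match on either strand); antisense hits to a gene are unassigned.
#' Multi-mapping reads are retained only when every alignment's midpoint
#' falls in repeat intervals of one single collapsed class; all other
#' multi-mappers are discarded.
#'
#' @param alignments Alignment tibble from [read_sam_alignments()]
#'   (columns `read_id`, `chromosome`, `start`, `end`, `strand`, `unique`).
#' @param annotation A resolved annotation from [build_annotation()].
#' @return A tibble with one row per read: `read_id`, `feature_name` (`NA`
#'   when unassigned/discarded), `chromosome`, `midpoint`, `strand`, and
#'   `status` in `unique`, `repeat_multimap`, `discarded_multimap`,
#'   `unassigned`.
#' @export
assign_features <- function(alignments, annotation) {
  aln <- tibble::as_tibble(alignments)
  if (nrow(aln) == 0L) {
    return(tibble::tibble(read_id = character(), feature_name = character(),
                          chromosome = character(), midpoint = integer(),
                          strand = character(), status = character()))
  }
  aln$midpoint <- (aln$start + aln$end) %/% 2L
  aln <- aln[order(aln$read_id, aln$chromosome, aln$midpoint, aln$strand), ]

  ann <- tibble::as_tibble(annotation)
  rep_hit <- interval_lookup(ann[ann$is_repeat, ], aln$chromosome, aln$midpoint)
  gene_hit <- interval_lookup(ann[!ann$is_repeat, ], aln$chromosome,
                              aln$midpoint, aln$strand)
  aln$rep_feature <- rep_hit
  aln$any_feature <- dplyr::coalesce(rep_hit, gene_hit)

  per_read <- dplyr::summarise(
    dplyr::group_by(aln, .data$read_id),
    n_aln = dplyr::n(),
    feature_name = if (dplyr::n() == 1L) .data$any_feature[1] else {
      rf <- .data$rep_feature
      if (!anyNA(rf) && dplyr::n_distinct(rf) == 1L) rf[1] else NA_character_
    },
    chromosome = .data$chromosome[1],
    midpoint = .data$midpoint[1],
    strand = .data$strand[1],
    .groups = "drop")
  per_read$status <- dplyr::case_when(
    per_read$n_aln == 1L & !is.na(per_read$feature_name) ~ "unique",
    per_read$n_aln == 1L ~ "unassigned",
    !is.na(per_read$feature_name) ~ "repeat_multimap",
    TRUE ~ "discarded_multimap")
  per_read[c("read_id", "feature_name", "chromosome", "midpoint", "strand",
             "status")]
}

# midpoint lookup in disjoint intervals; strand = NULL means strand-agnostic
interval_lookup <- function(ann, chrom, pos, strand = NULL) {
  res <- rep(NA_character_, length(chrom))
  if (nrow(ann) == 0L) return(res)
  key <- if (is.null(strand)) chrom else paste(chrom, strand)
  ann_key <- if (is.null(strand)) ann$chromosome else
    paste(ann$chromosome, ann$strand)
  for (k in unique(ann_key)) {
    a <- ann[ann_key == k, ]
    a <- a[order(a$start), ]
    sel <- which(key == k)
    if (!length(sel)) next
    idx <- findInterval(pos[sel], a$start)
    ok <- idx >= 1L & idx <= nrow(a)
    ok[ok] <- pos[sel][ok] <= a$end[idx[ok]]
    res[sel[ok]] <- a$feature_name[idx[ok]]
  }
  res
}
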