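#' Read and write the simulation-formatted co-barcoding file
#'
#' The simulation-formatted file is the pipeline's hand-off between read
#' processing and the Monte Carlo machinery: one line per proxy read, i.e.
#' per (barcode group, feature) observation, with the feature's genomic
#' coordinates. Within a barcode group every feature appears at most once.
#'
#' Dialect: tab-delimited UTF-8 with a header line, columns
#' `barcode_group_id`, `feature_name`, `chromosome`, `start`, `end`,
#' `strand`; gzip-compressed when the filename ends in `.gz`.
#'
#' @param records A data frame with the six columns above (coordinate
#'   columns may be omitted on write, in which case placeholders are used).
#' @param path File path; `.gz` triggers gzip.
#' @return `read_simulation_formatted()` returns the records tibble;
#'   `write_simulation_formatted()` returns `path` invisibly.
#' @export
write_simulation_formatted <- function(records, path) {
  records <- as_simulation_records(records)
  dup <- duplicated(records[c("barcode_group_id", "feature_name")])
  if (any(dup)) {
    stop("duplicate (barcode_group_id, feature_name) record: group ",
         records$barcode_group_id[dup][1], ", feature '",
         records$feature_name[dup][1], "'")
  }
  write_tsv_gz(records, path)
}

#' @rdname write_simulation_formatted
#' @export
read_simulation_formatted <- function(path) {
  out <- read_tsv_gz(path, col_types = c(
    barcode_group_id = "integer", feature_name = "character",
    chromosome = "character", start = "integer", end = "integer",
    strand = "character"
  ))
  as_simulation_records(out)
}

as_simulation_records <- function(records) {
  stopifnot(all(c("barcode_group_id", "feature_name") %in% names(records)))
  defaults <- list(chromosome = ".", start = 0L, end = 0L, strand = ".")
  for (col in names(defaults)) {
    if (!col %in% names(records)) records[[col]] <- defaults[[col]]
  }
  tibble::tibble(
    barcode_group_id = as.integer(records$barcode_group_id),
    feature_name = as.character(records$feature_name),
    chromosome = as.character(records$chromosome),
    start = as.integer(records$start),
    end = as.integer(records$end),
    strand = as.character(records$strand)
  )
}

#' Write the per-pair significance (qval) table
#'
#' Writes one line per unordered feature pair with its observed co-barcoding
#' count, the mean count over Monte Carlo randomizations, the local
#' background p value and the Benjamini-Hochberg q value. Pairs are
#' canonicalized so that `feature_a < feature_b` lexicographically and rows
#' are sorted by q ascending, then observed count descending (pairs without
#' a q value sort last).
#'
#' @param table A data frame with columns `feature_a`, `feature_b`,
#'   `observed_count`, `mean_random_count`, `p_value`, `q_value`.
#' @inheritParams write_simulation_formatted
#' @return `path`, invisibly.
#' @export
write_qval_table <- function(table, path) {
  cols <- c("feature_a", "feature_b", "observed_count", "mean_random_count",
            "p_value", "q_value")
  stopifnot(all(cols %in% names(table)))
  table <- canonicalize_pairs(tibble::as_tibble(table)[cols])
  ord <- order(table$q_value, -table$observed_count, table$feature_a,
               table$feature_b, na.last = TRUE)
  write_tsv_gz(table[ord, ], path)
}

#' @rdname write_qval_table
#' @export
read_qval_table <- function(path) {
  read_tsv_gz(path, col_types = c(
    feature_a = "character", feature_b = "character",
    observed_count = "double", mean_random_count = "double",
    p_value = "double", q_value = "double"
  ))
}

# put each pair into (min, max) lexicographic order
canonicalize_pairs <- function(table) {
  swap <- table$feature_a > table$feature_b
  if (any(swap)) {
    tmp <- table$feature_a[swap]
    table$feature_a[swap] <- table$feature_b[swap]
    table$feature_b[swap] <- tmp
  }
  table
}

#' Read a gene or repeat feature list
#'
#' Feature lists are tab-delimited files with columns `chromosome`, `start`,
#' `end`, `strand`, `feature_name` and, for repeat lists, `repeat_class`.
#' Repeat elements present at multiple genomic locations share a
#' `repeat_class` (e.g. all tRNA copies are the single feature "tRNA").
#'
#' @param path Path to the list (`.gz` supported).
#' @param repeats If `TRUE` the rows are repeat elements: `repeat_class` is
#'   required (defaulting to `feature_name` when absent) and `is_repeat` is
#'   set.
#' @return A tibble of annotation rows: `chromosome`, `start`, `end`,
#'   `strand`, `feature_name`, `is_repeat`, `repeat_class`.
#' @export
read_feature_list <- function(path, repeats = FALSE) {
  out <- read_tsv_gz(path, col_types = NULL)
  names(out)[1:5] <- c("chromosome", "start", "end", "strand", "feature_name")
  out$start <- as.integer(out$start)
  out$end <- as.integer(out$end)
  if (repeats) {
    if (!"repeat_class" %in% names(out)) out$repeat_class <- out$feature_name
    out$is_repeat <- TRUE
  } else {
    out$is_repeat <- FALSE
    out$repeat_class <- NA_character_
  }
  annotation_rows(out)
}

#' Construct validated annotation rows
#'
#' @param rows A data frame with columns `chromosome`, `start`, `end`,
#'   `strand`, `feature_name` and optionally `is_repeat`, `repeat_class`.
#' @return A tibble of validated annotation rows.
#' @export
annotation_rows <- function(rows) {
  rows <- tibble::as_tibble(rows)
  stopifnot(all(c("chromosome", "start", "end", "strand", "feature_name")
                %in% names(rows)))
  if (!"is_repeat" %in% names(rows)) rows$is_repeat <- FALSE
  if (!"repeat_class" %in% names(rows)) rows$repeat_class <- NA_character_
  rows$start <- as.integer(rows$start)
  rows$end <- as.integer(rows$end)
  if (any(rows$start > rows$end)) stop("annotation row with start > end")
  if (!all(rows$strand %in% c("+", "-"))) {
    stop("annotation strand must be '+' or '-'")
  }
  if (any(rows$is_repeat & (is.na(rows$repeat_class) | rows$repeat_class == ""))) {
    stop("repeat rows must carry a repeat_class")
  }
  rows[c("chromosome", "start", "end", "strand", "feature_name",
         "is_repeat", "repeat_class")]
}

#' Write / read a resolved annotation
#'
#' One interval per line, sorted by chromosome then start; round-trips
#' losslessly. Repeat intervals carry strand "." (they claim both strands).
#'
#' @param annotation A resolved annotation, see [build_annotation()].
#' @inheritParams write_simulation_formatted
#' @return `path` invisibly / the annotation tibble.
#' @export
write_annotation_table <- function(annotation, path) {
  ann <- tibble::as_tibble(annotation)
  ann <- ann[order(ann$chromosome, ann$start, ann$strand), ]
  write_tsv_gz(ann, path)
}

#' @rdname write_annotation_table
#' @export
read_annotation_table <- function(path) {
  out <- read_tsv_gz(path, col_types = c(
    chromosome = "character", start = "integer", end = "integer",
    strand = "character", feature_name = "character", is_repeat = "logical"
  ))
  class(out) <- c("proxseq_annotation", class(out))
  out
}

#' Write / read a valency feature distribution table
#'
#' One line per feature: the feature name followed by the number of times it
#' was observed in barcode groups of size 1, 2, ... (columns `valency_1`,
#' `valency_2`, ...).
#'
#' @param valency A long valency table from [valency_distribution()]
#'   (columns `feature_name`, `group_size`, `count`).
#' @inheritParams write_simulation_formatted
#' @return `path` invisibly; the reader returns the long tibble.
#' @export
write_valency_table <- function(valency, path) {
  stopifnot(all(c("feature_name", "group_size", "count") %in% names(valency)))
  max_k <- max(valency$group_size, 1L)
  wide <- tidyr::pivot_wider(
    dplyr::mutate(valency, group_size = factor(.data$group_size,
                                               levels = seq_len(max_k))),
    names_from = "group_size", values_from = "count",
    names_prefix = "valency_", values_fill = 0L, names_expand = TRUE
  )
  wide <- wide[order(wide$feature_name), ]
  write_tsv_gz(wide, path)
}

#' @rdname write_valency_table
#' @export
read_valency_table <- function(path) {
  wide <- read_tsv_gz(path, col_types = NULL)
  long <- tidyr::pivot_longer(wide, dplyr::starts_with("valency_"),
                              names_to = "group_size", names_prefix = "valency_",
                              values_to = "count")
  long$group_size <- as.integer(long$group_size)
  long <- long[long$count > 0, ]
  dplyr::arrange(tibble::as_tibble(long), .data$feature_name, .data$group_size)
}

# tab-delimited IO --------------------------------------------------------

write_tsv_gz <- function(x, path) {
  df <- as.data.frame(x)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv_gz <- function(path, col_types = NULL) {
  stopifnot(file.exists(path))
  lines <- read_text_lines(path)
  if (length(lines) <= 1L) {
    if (length(lines) == 0L && !is.null(col_types)) {
      # headerless empty file: synthesize empty columns
      out <- tibble::as_tibble(lapply(col_types, function(t) empty_col(t)))
      return(out)
    }
    header <- if (length(lines)) strsplit(lines[1], "\t", fixed = TRUE)[[1]]
              else names(col_types)
    if (!is.null(col_types)) {
      missing <- setdiff(names(col_types), header)
      if (length(missing)) {
        stop("missing column '", missing[1], "' in ", path)
      }
    }
    out <- tibble::as_tibble(setNames(
      lapply(seq_along(header), function(i) {
        t <- if (!is.null(col_types) && header[i] %in% names(col_types))
          col_types[[header[i]]] else "character"
        empty_col(t)
      }), header))
    return(out)
  }
  df <- utils::read.delim(text = lines, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  out <- tibble::as_tibble(df)
  if (!is.null(col_types)) {
    for (col in names(col_types)) {
      if (!col %in% names(out)) stop("missing column '", col, "' in ", path)
      out[[col]] <- switch(col_types[[col]],
        integer = as.integer(out[[col]]),
        double = as.numeric(out[[col]]),
        logical = as.logical(out[[col]]),
        character = as.character(out[[col]])
      )
    }
  }
  out
}

empty_col <- function(type) {
  switch(type %||% "character",
         integer = integer(), double = numeric(),
         logical = logical(), character = character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
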