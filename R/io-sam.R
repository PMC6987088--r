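#' Read aligned cDNA coordinates from a SAM file
#'
#' Parses the mandatory SAM columns and merges all alignment lines of one
#' read into a single per-read alignment set. Only start/end/strand are
#' extracted (the end is `POS + sequence length - 1`; CIGAR-aware split-read
#' arithmetic is out of scope). Unmapped reads (FLAG 0x4) are suppressed
#' from the output but counted.
#'
#' @param path Path to a SAM file (`.gz` supported). Header lines (`@...`)
#'   are skipped.
#' @param collapse_multimaps If `TRUE` (default), secondary/supplementary
#'   alignment lines (FLAG 0x100/0x800) are merged into the read's alignment
#'   set; if `FALSE` they are dropped and only primary alignments are kept.
#' @return A tibble with one row per retained alignment: `read_id`,
#'   `chromosome`, `start`, `end`, `strand`, plus per-read `n_alignments`
#'   and `unique` (exactly one alignment). The number of unmapped reads is
#'   attached as attribute `n_unmapped`.
#' @export
read_sam_alignments <- function(path, collapse_multimaps = TRUE) {
  stopifnot(file.exists(path))
  lines <- read_text_lines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    out <- tibble::tibble(read_id = character(), chromosome = character(),
                          start = integer(), end = integer(),
                          strand = character(), n_alignments = integer(),
                          unique = logical())
    attr(out, "n_unmapped") <- 0L
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    stop("SAM alignment line ", which(nf < 11L)[1],
         " has fewer than the 11 mandatory columns")
  }
  get <- function(i) vapply(fields, `[[`, "", i)
  read_id <- get(1L)
  flag <- as.integer(get(2L))
  if (anyNA(flag)) stop("non-numeric FLAG field in SAM input")
  chromosome <- get(3L)
  pos <- as.integer(get(4L))
  seqs <- get(10L)
  width <- pmax(nchar(seqs), 1L)
  width[seqs == "*"] <- 1L

  unmapped <- bitwAnd(flag, 4L) != 0L
  secondary <- bitwAnd(flag, 256L) != 0L | bitwAnd(flag, 2048L) != 0L
  n_unmapped <- length(unique(read_id[unmapped]))

  keep <- !unmapped
  if (!collapse_multimaps) keep <- keep & !secondary
  out <- tibble::tibble(
    read_id = read_id[keep],
    chromosome = chromosome[keep],
    start = pos[keep],
    end = pos[keep] + width[keep] - 1L,
    strand = ifelse(bitwAnd(flag[keep], 16L) != 0L, "-", "+")
  )
  out <- dplyr::mutate(dplyr::group_by(out, .data$read_id),
                       n_alignments = dplyr::n(),
                       unique = dplyr::n() == 1L)
  out <- dplyr::ungroup(out)
  attr(out, "n_unmapped") <- n_unmapped
  out
}
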