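#' Read single-end reads from a FASTQ file
#'
#' Reads a (optionally gzip-compressed) FASTQ file of 4-line records into a
#' tibble, one row per read. Sequenced Proximity RNA-seq fragments carry the
#' construct layout barcode / fixed PCR primer / random pentadecamer / cDNA;
#' this reader is layout-agnostic and returns the raw records.
#'
#' @param path Path to a FASTQ file. Files ending in `.gz` are decompressed
#'   transparently.
#' @return A tibble with columns `read_id`, `sequence` and `quality`, in file
#'   order.
#' @seealso [write_fastq()]
#' @export
read_fastq <- function(path) {
  stopifnot(file.exists(path))
  lines <- read_text_lines(path)
  n <- length(lines)
  if (n == 0L) {
    return(tibble::tibble(read_id = character(), sequence = character(),
                          quality = character()))
  }
  if (n %% 4L != 0L) {
    stop("truncated FASTQ record starting at line ", 4L * (n %/% 4L) + 1L,
         " of '", path, "' (", n %% 4L, " trailing line(s))")
  }
  idx <- seq(1L, n, by = 4L)
  header <- lines[idx]
  sequence <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  quality <- lines[idx + 3L]
  bad_hdr <- which(!startsWith(header, "@"))
  if (length(bad_hdr)) {
    stop("malformed FASTQ header at line ", (bad_hdr[1] - 1L) * 4L + 1L,
         ": expected '@'")
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus)) {
    stop("malformed FASTQ separator at line ", (bad_plus[1] - 1L) * 4L + 3L,
         ": expected '+'")
  }
  bad_len <- which(nchar(sequence) != nchar(quality))
  if (length(bad_len)) {
    stop("sequence/quality length mismatch at line ",
         (bad_len[1] - 1L) * 4L + 2L, " of '", path, "'")
  }
  tibble::tibble(
    read_id = sub("^@", "", sub("\\s.*$", "", header)),
    sequence = toupper(sequence),
    quality = quality
  )
}

#' Write reads to a FASTQ file
#'
#' @param reads A data frame with columns `read_id`, `sequence`, `quality`.
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "quality") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    stop("sequence/quality length mismatch in records to write")
  }
  lines <- as.vector(rbind(paste0("@", reads$read_id),
                           reads$sequence, "+", reads$quality))
  write_text_lines(lines, path)
  invisible(path)
}

# gz-transparent line IO -------------------------------------------------

read_text_lines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

write_text_lines <- function(lines, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
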