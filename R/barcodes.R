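#' Describe the layout of a sequenced library fragment
#'
#' A sequenced Proximity RNA-seq fragment is laid out as a 26-base random
#' bead barcode, the fixed PCR primer used for on-bead barcode
#' amplification, a random pentadecamer that primed reverse transcription,
#' and the cDNA of which the first 50 high-quality bases are used. Barcodes
#' are trimmed by 3 bases at either end (sequences are typically offset by
#' about one base), leaving a 20-base working barcode.
#'
#' @param barcode_len Length of the random bead barcode (default 26).
#' @param trim_each_end Bases trimmed from each barcode end (default 3).
#' @param primer_seq The fixed PCR primer expected after the barcode
#'   (default: the on-bead amplification primer, 20 nt).
#' @param random_primer_len Length of the random RT primer (default 15).
#' @param cdna_len Number of cDNA bases used downstream (default 50).
#' @param edit_rate_denominator Edit budget for approximate primer/adapter
#'   matching is `floor(length / edit_rate_denominator)`; the default 10
#'   allows one insertion, deletion or substitution per 10 primer bases.
#' @return A `read_layout` list.
#' @export
read_layout <- function(barcode_len = 26L, trim_each_end = 3L,
                        primer_seq = "CCTATCCCCTGTGTGCCTTG",
                        random_primer_len = 15L, cdna_len = 50L,
                        edit_rate_denominator = 10L) {
  stopifnot(barcode_len > 0, trim_each_end >= 0,
            barcode_len > 2 * trim_each_end, nchar(primer_seq) > 0,
            random_primer_len > 0, cdna_len > 0, edit_rate_denominator > 0)
  structure(list(barcode_len = as.integer(barcode_len),
                 trim_each_end = as.integer(trim_each_end),
                 primer_seq = toupper(primer_seq),
                 random_primer_len = as.integer(random_primer_len),
                 cdna_len = as.integer(cdna_len),
                 edit_rate_denominator = as.integer(edit_rate_denominator)),
            class = "read_layout")
}

#' Check reads for the fixed primer sequence
#'
#' Tests whether the fixed PCR primer occurs directly after the barcode,
#' allowing one insertion, deletion or substitution per
#' `edit_rate_denominator` primer bases (total edits counted together).
#' The primer may start within plus/minus the edit budget of its canonical
#' position so that small indels inside the barcode do not reject the read.
#'
#' @param reads A data frame with columns `read_id` and `sequence` (e.g.
#'   from [read_fastq()]), or a character vector of sequences.
#' @param layout A [read_layout()].
#' @return A tibble with one row per read: `read_id`, `pass`, `reason`
#'   (`NA`, `"too_short"` or `"no_primer"`), `primer_end` (1-based position
#'   of the last primer base, `NA` on failure) and `edits` (edit distance of
#'   the accepted match).
#' @export
check_fixed_sequence <- function(reads, layout = read_layout()) {
  if (is.character(reads)) {
    reads <- tibble::tibble(read_id = as.character(seq_along(reads)),
                            sequence = reads)
  }
  seqs <- toupper(reads$sequence)
  primer <- layout$primer_seq
  lp <- nchar(primer)
  budget <- lp %/% layout$edit_rate_denominator
  min_len <- layout$barcode_len + lp + layout$random_primer_len +
    layout$cdna_len - budget
  n <- length(seqs)

  pass <- logical(n)
  reason <- rep(NA_character_, n)
  primer_end <- rep(NA_integer_, n)
  edits <- rep(NA_integer_, n)

  too_short <- nchar(seqs) < min_len
  reason[too_short] <- "too_short"
  eligible <- which(!too_short)
  if (length(eligible)) {
    sub_seqs <- mask_n(seqs[eligible])
    p <- mask_n(primer, sentinel = "!")
    best_d <- rep(Inf, length(eligible))
    best_key <- rep(Inf, length(eligible))
    best_end <- rep(NA_integer_, length(eligible))
    canonical_start <- layout$barcode_len + 1L
    for (ds in -budget:budget) {
      s <- canonical_start + ds
      if (s < 1L) next
      for (dl in -budget:budget) {
        L <- lp + dl
        if (L < 1L) next
        frag <- substr(sub_seqs, s, s + L - 1L)
        long_enough <- nchar(frag) == L
        if (!any(long_enough)) next
        d <- as.integer(adist(p, frag))
        # deterministic preference: fewest edits, then least start/length shift
        key <- d * 100L + abs(ds) * 10L + abs(dl)
        upd <- long_enough & d <= budget & key < best_key
        best_key[upd] <- key[upd]
        best_d[upd] <- d[upd]
        best_end[upd] <- s + L - 1L
      }
    }
    ok <- is.finite(best_d)
    pass[eligible] <- ok
    reason[eligible][!ok] <- "no_primer"
    pe <- rep(NA_integer_, length(eligible)); pe[ok] <- best_end[ok]
    ed <- rep(NA_integer_, length(eligible)); ed[ok] <- as.integer(best_d[ok])
    primer_end[eligible] <- pe
    edits[eligible] <- ed
  }
  tibble::tibble(read_id = reads$read_id, pass = pass, reason = reason,
                 primer_end = primer_end, edits = edits)
}

#' Extract the trimmed working barcode from a read
#'
#' Returns the 26-base barcode trimmed by `trim_each_end` bases at either
#' end (20 bases under the default layout).
#'
#' @param reads A data frame with a `sequence` column, or a character
#'   vector of read sequences, for reads that passed
#'   [check_fixed_sequence()].
#' @inheritParams check_fixed_sequence
#' @return A character vector of trimmed barcodes.
#' @export
extract_trimmed_barcode <- function(reads, layout = read_layout()) {
  seqs <- if (is.character(reads)) reads else reads$sequence
  substr(toupper(seqs), layout$trim_each_end + 1L,
         layout$barcode_len - layout$trim_each_end)
}

#' Discard low-complexity barcodes
#'
#' A barcode is discarded when any single nucleotide symbol (N included)
#' occurs 13 or more times in the 20-base trimmed barcode; such barcodes
#' collect reads from many beads into one artifactual group.
#'
#' @param barcodes Character vector of trimmed barcodes (equal length).
#' @param max_mononucleotide Discard threshold: discard when the most
#'   frequent symbol occurs at least this many times (default 13).
#' @return Logical vector: `TRUE` = keep, `FALSE` = discard.
#' @export
low_complexity_filter <- function(barcodes, max_mononucleotide = 13L) {
  len <- unique(nchar(barcodes))
  if (length(len) > 1L) stop("barcodes must all have the same length")
  vapply(strsplit(toupper(barcodes), ""), function(b) {
    max(tabulate(factor(b))) < max_mononucleotide
  }, logical(1))
}

#' Discard barcodes resembling adapter sequences
#'
#' A barcode is discarded when any adapter (or its reverse complement)
#' matches a stretch of the barcode with edit distance at most
#' `floor(matchlen / edit_rate_denominator)`, where `matchlen` is the
#' shorter of adapter and barcode length. For adapters longer than the
#' barcode, the barcode is searched within the adapter instead.
#'
#' @param barcodes Character vector of trimmed barcodes.
#' @param adapters Character vector of adapter/primer sequences
#'   (default [default_adapters()]). An empty vector keeps everything.
#' @inheritParams check_fixed_sequence
#' @return Logical vector: `TRUE` = keep, `FALSE` = discard.
#' @export
adapter_similarity_filter <- function(barcodes, adapters = default_adapters(),
                                      layout = read_layout()) {
  if (length(adapters) == 0L || length(barcodes) == 0L) {
    return(rep(TRUE, length(barcodes)))
  }
  denom <- layout$edit_rate_denominator
  bc <- mask_n(toupper(barcodes))
  keep <- rep(TRUE, length(barcodes))
  probes <- unique(c(toupper(adapters), revcomp(toupper(adapters))))
  for (a in probes) {
    a_masked <- mask_n(a, sentinel = "!")
    matchlen <- min(nchar(a), nchar(barcodes[1]))
    budget <- matchlen %/% denom
    d <- if (nchar(a) <= nchar(barcodes[1])) {
      as.integer(adist(a_masked, bc, partial = TRUE))
    } else {
      as.integer(adist(bc, a_masked, partial = TRUE))
    }
    keep <- keep & d > budget
  }
  keep
}

#' Default adapter screen sequences
#'
#' The Illumina-side library primers: the RP1 sequencing primer, the
#' poly(C) cDNA adapter, and the indexed PCR primer's common 3' part.
#'
#' @return Character vector of adapter sequences.
#' @export
default_adapters <- function() {
  c(rp1 = "AATGATACGGCGACCACCGAGATCTACACGTTCAGAGTTCTACAGTCCGA",
    polyc = "GCCTTGGCACCCGAGAATTCCACCCCCCCCCCCC",
    index_common = "GTGACTGGAGTTCCTTGGCACCCGAGAATTCCA")
}

#' Reverse-complement nucleotide sequences
#'
#' @param x Character vector of sequences (A/C/G/T/N).
#' @return Reverse complements.
#' @export
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

#' Collapse near-identical barcodes into barcode groups
#'
#' Sequencing errors split reads from one bead across near-identical barcode
#' variants. Two barcodes are linked when their edit distance is at most
#' `link_edit_distance`; barcode groups are the connected components
#' (transitive closure) of this link relation, emulating the multi-mapping
#' of barcodes against a virtual scaffold of all unique barcodes. N bases
#' mismatch everything, including other Ns.
#'
#' @param barcodes Character vector of trimmed barcodes, one entry per read
#'   (duplicates allowed).
#' @param link_edit_distance Maximum edit distance that links two barcodes
#'   (default 2).
#' @return A tibble with one row per unique barcode: `barcode`, `group_id`
#'   (dense integer, ordered by first appearance). Join on `barcode` to
#'   propagate group ids to reads.
#' @export
group_barcodes <- function(barcodes, link_edit_distance = 2L) {
  ub <- unique(barcodes)
  n <- length(ub)
  if (n == 0L) {
    return(tibble::tibble(barcode = character(), group_id = integer()))
  }
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  masked <- mask_n(ub)
  chunk <- 512L
  starts <- seq(1L, n, by = chunk)
  for (bi in starts) {
    ii <- bi:min(bi + chunk - 1L, n)
    for (bj in starts[starts >= bi]) {
      jj <- bj:min(bj + chunk - 1L, n)
      d <- adist(masked[ii], masked[jj])
      hit <- which(d <= link_edit_distance, arr.ind = TRUE)
      for (h in seq_len(nrow(hit))) {
        i <- ii[hit[h, 1]]; j <- jj[hit[h, 2]]
        if (i < j) union2(i, j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  tibble::tibble(barcode = ub,
                 group_id = as.integer(factor(roots, levels = unique(roots))))
}

# map N to a sentinel so N never matches anything (not even another N
# on the opposite side of a comparison)
mask_n <- function(x, sentinel = "#") chartr("N", sentinel, x)

#' Annotate read headers with their barcode group id
#'
#' Mirrors the intermediate FASTQ convention of tagging each retained read
#' with its barcode group, appended to the read id after a delimiter, so
#' downstream tools can carry the grouping through external alignment.
#'
#' @param reads A reads tibble (`read_id`, `sequence`, `quality`).
#' @param read_groups A tibble mapping `read_id` to `group_id` (see
#'   [group_barcodes()]); unmatched reads are dropped.
#' @param delimiter Separator between the original id and the group id
#'   (default `"#"`).
#' @return The annotated reads tibble (new `read_id`s; original id kept in
#'   `original_read_id`).
#' @export
annotate_reads_with_group <- function(reads, read_groups, delimiter = "#") {
  joined <- dplyr::inner_join(tibble::as_tibble(reads),
                              read_groups[c("read_id", "group_id")],
                              by = "read_id")
  joined$original_read_id <- joined$read_id
  joined$read_id <- paste0(joined$original_read_id, delimiter,
                           joined$group_id)
  joined[c("read_id", "sequence", "quality", "original_read_id")]
}

#' Fit the Poisson barcode-group size threshold
#'
#' Barcode group sizes are modelled as a Poisson distribution (many small
#' groups, few very large ones). Groups so large that they would occur with
#' upper-tail probability below `cutoff` are flagged for removal: the
#' threshold is the largest size `s` with `P(X >= s) >= cutoff`.
#'
#' @param group_sizes Integer vector of barcode group sizes (>= 1).
#' @param cutoff Tail probability cutoff (default 0.001).
#' @return A `group_size_model` list with `lambda_hat` (sample mean),
#'   `tail_probability_cutoff` and `max_allowed_size`.
#' @export
fit_group_size_threshold <- function(group_sizes, cutoff = 0.001) {
  if (length(group_sizes) == 0L) stop("no group sizes supplied")
  stopifnot(all(group_sizes >= 1), cutoff > 0, cutoff <= 1)
  lambda <- mean(group_sizes)
  s <- 1L
  # P(X >= s) = ppois(s - 1, lambda, lower.tail = FALSE)
  while (ppois(s - 1L, lambda, lower.tail = FALSE) >= cutoff) s <- s + 1L
  max_allowed <- s - 1L
  if (max_allowed < 1L) {
    stop("degenerate configuration: cutoff ", cutoff,
         " removes all group sizes (max_allowed_size = 0)")
  }
  structure(list(lambda_hat = lambda, tail_probability_cutoff = cutoff,
                 max_allowed_size = max_allowed),
            class = "group_size_model")
}

#' @export
print.group_size_model <- function(x, ...) {
  cat("Poisson barcode-group size model\n",
      "  lambda_hat: ", format(x$lambda_hat), "\n",
      "  tail cutoff: ", format(x$tail_probability_cutoff), "\n",
      "  max allowed group size: ", x$max_allowed_size, "\n", sep = "")
  invisible(x)
}

#' Poisson bead-barcoding fractions
#'
#' Bead barcoding in droplets follows a Poisson distribution: if a fraction
#' `f` of beads carries any barcode, the loading rate is
#' `lambda = -ln(1 - f)` and the fraction of barcoded beads carrying copies
#' of a single barcode is `lambda * exp(-lambda) / (1 - exp(-lambda))`. At
#' 50% barcoded beads this gives approximately 70% single-barcode and 30%
#' multi-barcode beads.
#'
#' @param fraction_beads_barcoded Fraction of beads carrying at least one
#'   barcode, strictly between 0 and 1.
#' @return A one-row tibble: `lambda`, `fraction_single`,
#'   `fraction_multiple` (conditional on being barcoded; they sum to 1).
#' @export
barcoded_bead_fractions <- function(fraction_beads_barcoded) {
  f <- fraction_beads_barcoded
  if (!is.numeric(f) || length(f) != 1L || f <= 0 || f >= 1) {
    stop("fraction_beads_barcoded must be a single value in (0, 1)")
  }
  lambda <- -log(1 - f)
  single <- lambda * exp(-lambda) / (1 - exp(-lambda))
  tibble::tibble(lambda = lambda, fraction_single = single,
                 fraction_multiple = 1 - single)
}
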