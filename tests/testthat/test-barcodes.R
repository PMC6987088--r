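layout <- read_layout()
make_read <- function(primer = layout$primer_seq, barcode = NULL,
                      barcode_len = 26L) {
  if (is.null(barcode)) barcode <- strrep("AC", barcode_len / 2)
  paste0(barcode, primer, strrep("G", 15), strrep("T", 50))
}

test_that("primer detection matches the dynamic-programming edit oracle", {
  # exact primer directly after the 26-base barcode
  res <- check_fixed_sequence(make_read(), layout)
  expect_true(res$pass)
  expect_equal(res$primer_end, 26L + nchar(layout$primer_seq))

  # 2 substitutions (budget floor(20/10) = 2) pass, 3 fail
  p2 <- layout$primer_seq
  substr(p2, 1, 1) <- "A"; substr(p2, 5, 5) <- "A"
  p3 <- p2
  substr(p3, 9, 9) <- "T"
  expect_equal(edit_distance_dp(layout$primer_seq, p2), 2L)
  expect_equal(edit_distance_dp(layout$primer_seq, p3), 3L)
  res <- check_fixed_sequence(c(make_read(p2), make_read(p3)), layout)
  expect_equal(res$pass, c(TRUE, FALSE))
  expect_equal(res$edits[1], 2L)
  expect_equal(res$reason[2], "no_primer")

  # one base inserted in the barcode shifts the matched end by one
  shifted <- make_read(barcode = paste0(strrep("AC", 13), "G"),
                       barcode_len = 27L)
  res <- check_fixed_sequence(shifted, layout)
  expect_true(res$pass)
  expect_equal(res$primer_end, 26L + nchar(layout$primer_seq) + 1L)

  # a read below the minimal layout fails with the too_short reason
  res <- check_fixed_sequence("ACGTACGT", layout)
  expect_false(res$pass)
  expect_equal(res$reason, "too_short")
})

test_that("barcode trimming removes 3 bases at either end", {
  core <- strrep("GT", 10)
  expect_equal(extract_trimmed_barcode(paste0("AAA", core, "CCC"), layout),
               core)
  lay0 <- read_layout(barcode_len = 20L, trim_each_end = 0L)
  expect_equal(extract_trimmed_barcode(core, lay0), core)
  # reads differing only in the trimmed bases give identical barcodes
  expect_equal(extract_trimmed_barcode(paste0("TTT", core, "GGG"), layout),
               extract_trimmed_barcode(paste0("AAA", core, "CCC"), layout))
})

test_that("low-complexity filter discards 13+ of one nucleotide in 20", {
  expect_false(low_complexity_filter(paste0(strrep("G", 13), "ACTACTA")))
  expect_true(low_complexity_filter(paste0(strrep("G", 12), "ACTACTAC")))
  expect_true(low_complexity_filter(strrep("ACGT", 5)))
  # N counts as a nucleotide symbol
  expect_false(low_complexity_filter(paste0(strrep("N", 13), "ACTACTA")))
  expect_error(low_complexity_filter(c("ACGT", "ACGTACGT")), "same length")
})

test_that("adapter filter discards near-adapter barcodes and keeps others", {
  adapters <- default_adapters()
  # 20 exact bases of an adapter
  bc_adapter <- substr(adapters[["rp1"]], 1, 20)
  expect_false(adapter_similarity_filter(bc_adapter, adapters, layout))
  # reverse complement is screened too
  expect_false(adapter_similarity_filter(revcomp(bc_adapter), adapters,
                                         layout))
  # random barcodes at edit distance >= 5 from every adapter window survive
  set.seed(42)
  repeat {
    bc <- random_dna(1, 20)
    windows <- unlist(lapply(c(adapters, revcomp(adapters)), function(a) {
      starts <- seq_len(max(nchar(a) - 20 + 1, 1))
      substring(a, starts, pmin(starts + 19, nchar(a)))
    }))
    if (min(vapply(windows, edit_distance_dp, integer(1), a = bc)) >= 5)
      break
  }
  expect_true(adapter_similarity_filter(bc, adapters, layout))
  # vacuous adapter list keeps everything
  expect_true(all(adapter_similarity_filter(c(bc, bc_adapter), character(0),
                                            layout)))
})

test_that("filters commute", {
  set.seed(43)
  bcs <- c(random_dna(50, 20), strrep("G", 20),
           substr(default_adapters()[["rp1"]], 1, 20))
  s1 <- bcs[low_complexity_filter(bcs)]
  s1 <- s1[adapter_similarity_filter(s1)]
  s2 <- bcs[adapter_similarity_filter(bcs)]
  s2 <- s2[low_complexity_filter(s2)]
  expect_equal(s1, s2)
  expect_lt(length(s1), length(bcs))  # the planted offenders were removed
})

test_that("barcode grouping equals brute-force connected components", {
  b1 <- strrep("A", 20)
  b2 <- paste0(strrep("A", 18), "CC")     # d(b1, b2) = 2
  b3 <- paste0(strrep("A", 16), "CCCC")   # d(b2, b3) = 2, d(b1, b3) = 4
  far <- strrep("GT", 10)
  grp <- group_barcodes(c(b1, b1, b2, b3, far))
  expect_equal(dplyr::n_distinct(grp$group_id), 2L)
  expect_equal(grp$group_id[grp$barcode == b1], grp$group_id[grp$barcode == b3])

  set.seed(44)
  # random 20-mers plus planted 1-2-edit variants to create real clusters
  base <- random_dna(60, 20)
  variants <- vapply(sample(base, 60, replace = TRUE), function(b) {
    v <- strsplit(b, "")[[1]]
    for (i in sample(20, sample(1:2, 1))) v[i] <- sample(c("A","C","G","T"), 1)
    paste(v, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  pool <- c(base, variants)
  got <- group_barcodes(pool)
  want <- oracle_group_barcodes(pool)
  # same partition: identical co-membership for every barcode pair
  got_sets <- split(got$barcode, got$group_id)
  key <- function(sets) sort(vapply(sets, function(s)
    paste(sort(s), collapse = "|"), character(1)))
  expect_equal(key(got_sets), key(want))
  # partition property: every unique barcode in exactly one group
  expect_setequal(got$barcode, unique(pool))
  expect_equal(anyDuplicated(got$barcode), 0L)
})

test_that("barcodes with small errors join their bead, distant ones do not", {
  set.seed(45)
  beads <- random_dna(40, 20)
  mutate_k <- function(b, k) {
    v <- strsplit(b, "")[[1]]
    pos <- sample(20, k)
    for (i in pos) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
    paste(v, collapse = "")
  }
  within <- vapply(beads, mutate_k, character(1), k = 2)
  grp <- group_barcodes(c(beads, within))
  ids <- setNames(grp$group_id, grp$barcode)
  expect_true(all(ids[beads] == ids[within]))
  # > 2 x link distance: fresh random barcodes almost surely stay separate
  far <- random_dna(40, 20)
  grp2 <- group_barcodes(c(beads, far))
  ids2 <- setNames(grp2$group_id, grp2$barcode)
  expect_equal(dplyr::n_distinct(ids2), length(unique(c(beads, far))))
})

test_that("Poisson group-size threshold follows the tail rule", {
  # mean 1: P(X >= 6) = 5.9e-4 < 1e-3 <= P(X >= 5) = 3.7e-3
  m <- fit_group_size_threshold(rep(1L, 500), cutoff = 0.001)
  expect_equal(m$lambda_hat, 1)
  expect_equal(m$max_allowed_size, 5L)
  expect_lt(ppois(m$max_allowed_size, m$lambda_hat, lower.tail = FALSE),
            0.001)
  expect_gte(ppois(m$max_allowed_size - 1L, m$lambda_hat,
                   lower.tail = FALSE), 0.001)
  # degenerate cutoff flags a configuration error
  expect_error(fit_group_size_threshold(c(1L, 2L), cutoff = 1),
               "degenerate")
  expect_error(fit_group_size_threshold(integer()), "no group sizes")
})

test_that("bead-loading fractions follow the truncated Poisson closed form", {
  f <- barcoded_bead_fractions(0.5)
  expect_equal(f$lambda, log(2))
  expect_equal(f$fraction_single, log(2) * exp(-log(2)) / (1 - exp(-log(2))))
  expect_equal(f$fraction_single + f$fraction_multiple, 1)
  # rare-loading limit: almost all barcoded beads carry a single barcode
  expect_gt(barcoded_bead_fractions(1e-6)$fraction_single, 0.999)
  lam <- log(10)
  expect_equal(barcoded_bead_fractions(0.9)$fraction_single,
               lam * exp(-lam) / 0.9)
  expect_error(barcoded_bead_fractions(1.2), "in \\(0, 1\\)")
})

test_that("group-annotated read headers carry the group id", {
  reads <- tibble::tibble(read_id = c("r1", "r2", "r3"),
                          sequence = "ACGT", quality = "IIII")
  groups <- tibble::tibble(read_id = c("r1", "r3"), group_id = c(4L, 9L))
  out <- annotate_reads_with_group(reads, groups)
  expect_equal(out$read_id, c("r1#4", "r3#9"))
  expect_equal(out$original_read_id, c("r1", "r3"))
})
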