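gene_row <- function(name, start, end, strand = "+", chrom = "c") {
  annotation_rows(tibble::tibble(chromosome = chrom, start = start,
                                 end = end, strand = strand,
                                 feature_name = name))
}
repeat_row <- function(class, start, end, strand = "+", chrom = "c") {
  annotation_rows(tibble::tibble(chromosome = chrom, start = start,
                                 end = end, strand = strand,
                                 feature_name = class, is_repeat = TRUE,
                                 repeat_class = class))
}

test_that("repeats take priority over genes on both strands", {
  ann <- build_annotation(gene_row("G1", 1, 1000),
                          repeat_row("5S", 400, 450))
  df <- as.data.frame(ann)[c("start", "end", "strand", "feature_name")]
  expect_equal(df$start, c(1, 400, 451))
  expect_equal(df$end, c(399, 450, 1000))
  expect_equal(df$feature_name, c("G1", "5S", "G1"))
  expect_equal(df$strand[2], ".")
  # a gene on the other strand is cut at the same coordinates
  ann2 <- build_annotation(gene_row("G2", 1, 1000, strand = "-"),
                           repeat_row("5S", 400, 450))
  expect_equal(sum(ann2$feature_name == "G2"), 2L)
})

test_that("partial gene overlap removes the shared region from both", {
  ann <- build_annotation(dplyr::bind_rows(gene_row("G1", 1, 1000),
                                           gene_row("G2", 500, 1500)))
  df <- as.data.frame(ann)
  expect_equal(df$feature_name, c("G1", "G2"))
  expect_equal(df$start, c(1, 1001))
  expect_equal(df$end, c(499, 1500))
  removed <- attr(ann, "ambiguous_removed")
  expect_equal(removed$start, 500)
  expect_equal(removed$end, 1000)
})

test_that("a wholly contained feature wins its interval", {
  ann <- build_annotation(dplyr::bind_rows(gene_row("G", 1, 1000),
                                           gene_row("S", 200, 300)))
  df <- as.data.frame(ann)
  expect_equal(df$feature_name, c("G", "S", "G"))
  expect_equal(df$start, c(1, 200, 301))
  expect_equal(df$end, c(199, 300, 1000))
  # identical intervals with two names are ambiguous
  ann2 <- build_annotation(dplyr::bind_rows(gene_row("A", 10, 20),
                                            gene_row("B", 10, 20)))
  expect_equal(nrow(ann2), 0L)
  # inconsistent duplicate gene definition errors
  expect_error(build_annotation(dplyr::bind_rows(gene_row("A", 10, 20),
                                                 gene_row("A", 15, 25))),
               "inconsistent")
})

test_that("resolution agrees per-base with the brute-force priority labeler", {
  set.seed(7)
  for (rep_i in 1:25) {
    toy <- random_toy_annotation(n_genes = sample(2:8, 1),
                                 n_repeats = sample(0:4, 1))
    ann <- build_annotation(toy$genes, toy$repeats)
    got <- annotation_to_bases(ann, 500L)
    want <- oracle_label_bases(
      toy$genes,
      toy$repeats %||% tibble::tibble(start = integer(), end = integer(),
                                      repeat_class = character()),
      500L)
    expect_identical(got, want)
    # disjointness within chromosome+strand
    for (std in c("+", "-", ".")) {
      sub <- ann[ann$strand %in% c(std, "."), ]
      if (nrow(sub) > 1) {
        sub <- sub[order(sub$start), ]
        expect_true(all(sub$start[-1] > sub$end[-nrow(sub)]))
      }
    }
  }
})

test_that("read assignment uses midpoints, strands and repeat classes", {
  ann <- build_annotation(
    dplyr::bind_rows(gene_row("G1", 1, 1000), gene_row("G2", 2001, 3000)),
    dplyr::bind_rows(repeat_row("tRNA", 5000, 5100),
                     repeat_row("tRNA", 6000, 6100),
                     repeat_row("U2", 7000, 7100)))
  mk_aln <- function(read_id, start, strand = "+", n = 1) {
    tibble::tibble(read_id = read_id, chromosome = "c", start = start,
                   end = start + 49L, strand = strand,
                   n_alignments = n, unique = n == 1)
  }
  aln <- dplyr::bind_rows(
    mk_aln("u1", 100),                      # unique, sense -> G1
    mk_aln("u2", 100, strand = "-"),        # antisense -> unassigned
    mk_aln("u3", 1500),                     # outside any feature
    mk_aln("rep", c(5010, 6010), n = 2),    # both midpoints in tRNA copies
    mk_aln("mix", c(5010, 7010), n = 2),    # tRNA + U2 -> discarded
    mk_aln("gmix", c(100, 2500), n = 2))    # gene multimap -> discarded
  got <- assign_features(aln, ann)
  res <- setNames(got$status, got$read_id)
  expect_equal(res[["u1"]], "unique")
  expect_equal(got$feature_name[got$read_id == "u1"], "G1")
  expect_equal(res[["u2"]], "unassigned")
  expect_equal(res[["u3"]], "unassigned")
  expect_equal(res[["rep"]], "repeat_multimap")
  expect_equal(got$feature_name[got$read_id == "rep"], "tRNA")
  expect_equal(res[["mix"]], "discarded_multimap")
  expect_equal(res[["gmix"]], "discarded_multimap")
  # midpoint definition: floor((start + end) / 2)
  expect_equal(got$midpoint[got$read_id == "u1"], (100L + 149L) %/% 2L)
  # alignment listing order does not matter
  got_rev <- assign_features(aln[rev(seq_len(nrow(aln))), ], ann)
  expect_equal(dplyr::arrange(got, .data$read_id),
               dplyr::arrange(got_rev, .data$read_id))
})

test_that("annotation export round-trips through the reader", {
  toy <- random_toy_annotation(5, 2)
  ann <- build_annotation(toy$genes, toy$repeats)
  path <- withr::local_tempfile(fileext = ".txt.gz")
  write_annotation_table(ann, path)
  back <- read_annotation_table(path)
  expect_equal(nrow(back), nrow(ann))
  expect_setequal(back$feature_name, ann$feature_name)
})
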