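#' Configuration for synthetic Proximity RNA-seq data
#'
#' Describes a synthetic droplet co-barcoding experiment: beads loaded with
#' RNA-containing particles according to a (zero-truncated) Poisson
#' distribution, Zipf-like transcript abundances, optional planted proximal
#' pairs whose co-occurrence is boosted above chance, sequencing errors in
#' barcodes, and an optional non-clonal control mode in which a bead
#' carries many different barcodes so that genuine co-barcoding is
#' destroyed.
#'
#' @param n_features Number of distinct transcripts (default 200).
#' @param abundance_exponent Zipf exponent: abundance of the rank-r
#'   transcript is proportional to `r^-abundance_exponent` (default 1).
#' @param n_groups Number of beads / barcode groups (default 5000).
#' @param group_size_lambda Poisson rate of distinct transcripts per bead;
#'   sizes are drawn zero-truncated (an empty bead is unobservable;
#'   default 1.5).
#' @param planted_pairs A data frame `feature_a`, `feature_b`, `boost`
#'   (boost >= 1) of proximal pairs, or `NULL`. After the first member of a
#'   pair enters a group, the partner is injected into the same group with
#'   probability `min(1, boost * base_rate)`, where the base rate is the
#'   partner's abundance weight.
#' @param barcode_substitution_rate Per-base probability of a substitution
#'   error in each read's copy of the bead barcode (default 0).
#' @param clonal_beads `TRUE` (default) for normal clonally barcoded beads;
#'   `FALSE` emulates the randomly barcoded control library (every read
#'   draws a fresh barcode).
#' @param reads_per_proxy Number of identical (PCR duplicate) reads emitted
#'   per proxy read when rendering reads (default 1).
#' @param layout A [read_layout()] used when rendering full reads.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_features = 200L, abundance_exponent = 1,
                             n_groups = 5000L, group_size_lambda = 1.5,
                             planted_pairs = NULL,
                             barcode_substitution_rate = 0,
                             clonal_beads = TRUE, reads_per_proxy = 1L,
                             layout = read_layout()) {
  stopifnot(n_features >= 1, n_groups >= 0, group_size_lambda > 0,
            barcode_substitution_rate >= 0, barcode_substitution_rate < 1,
            reads_per_proxy >= 1)
  features <- sprintf("FEAT%04d", seq_len(n_features))
  if (!is.null(planted_pairs)) {
    planted_pairs <- tibble::as_tibble(planted_pairs)
    stopifnot(all(c("feature_a", "feature_b", "boost") %in%
                    names(planted_pairs)),
              all(planted_pairs$boost >= 1),
              all(c(planted_pairs$feature_a, planted_pairs$feature_b) %in%
                    features))
  }
  structure(list(n_features = as.integer(n_features),
                 abundance_exponent = abundance_exponent,
                 n_groups = as.integer(n_groups),
                 group_size_lambda = group_size_lambda,
                 planted_pairs = planted_pairs,
                 barcode_substitution_rate = barcode_substitution_rate,
                 clonal_beads = isTRUE(clonal_beads),
                 reads_per_proxy = as.integer(reads_per_proxy),
                 layout = layout, features = features),
            class = "synthetic_config")
}

# zero-truncated Poisson draws (a bead with zero transcripts is unobservable)
rztpois <- function(n, lambda) {
  if (n == 0L) return(integer())
  u <- runif(n, min = dpois(0, lambda), max = 1)
  stats::qpois(u, lambda)
}

#' Generate a synthetic co-barcoding dataset with ground truth
#'
#' Draws barcode-group sizes from a zero-truncated Poisson, fills each
#' group by abundance-weighted sampling without within-group replacement,
#' co-samples planted pairs with boosted probability, and derives the
#' simulation-formatted records over a toy gene annotation. Full reads
#' (FASTQ plus matching alignments) can be rendered with
#' [render_synthetic_reads()]. Fully deterministic given a seed.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Optional integer seed.
#' @return A list of class `proxseq_synthetic`:
#'   `groups` (truth memberships: `barcode_group_id`, `feature_name`),
#'   `sim_records` (simulation-formatted tibble with coordinates),
#'   `annotation` (toy gene rows, one non-overlapping gene per feature),
#'   `beads` (`barcode_group_id`, `barcode` of 26 nt),
#'   `truth` (list: `planted_pairs`, abundance `weights`),
#'   and `cfg`.
#' @export
generate_dataset <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!is.null(seed)) set.seed(seed)
  nf <- cfg$n_features
  w <- (seq_len(nf))^(-cfg$abundance_exponent)
  w <- w / sum(w)
  sizes <- rztpois(cfg$n_groups, cfg$group_size_lambda)
  if (any(sizes > nf)) {
    stop("infeasible config: a group of size ", max(sizes), " was drawn but ",
         "only ", nf, " features exist")
  }
  partner_of <- list()
  boost_of <- list()
  if (!is.null(cfg$planted_pairs)) {
    for (i in seq_len(nrow(cfg$planted_pairs))) {
      a <- cfg$planted_pairs$feature_a[i]; b <- cfg$planted_pairs$feature_b[i]
      partner_of[[a]] <- c(partner_of[[a]], b)
      partner_of[[b]] <- c(partner_of[[b]], a)
      boost_of[[paste(a, b)]] <- cfg$planted_pairs$boost[i]
      boost_of[[paste(b, a)]] <- cfg$planted_pairs$boost[i]
    }
  }
  feature_idx <- setNames(seq_len(nf), cfg$features)
  group_members <- vector("list", cfg$n_groups)
  for (g in seq_len(cfg$n_groups)) {
    k <- sizes[g]
    members <- character(0)
    pending <- character(0)
    while (length(members) < k) {
      cand <- NA_character_
      while (length(pending)) {
        p <- pending[1]; pending <- pending[-1]
        if (!p %in% members) { cand <- p; break }
      }
      if (is.na(cand)) {
        avail <- setdiff(cfg$features, members)
        wa <- w[feature_idx[avail]]
        cand <- avail[sample.int(length(avail), 1L, prob = wa)]
      }
      members <- c(members, cand)
      partners <- setdiff(partner_of[[cand]] %||% character(0), members)
      for (p in partners) {
        boost <- boost_of[[paste(cand, p)]]
        if (runif(1) < min(1, boost * w[feature_idx[p]])) {
          pending <- c(pending, p)
        }
      }
    }
    group_members[[g]] <- members
  }
  groups <- tibble::tibble(
    barcode_group_id = rep(seq_len(cfg$n_groups), lengths(group_members)),
    feature_name = unlist(group_members) %||% character(0))
  annotation <- synthetic_annotation(cfg)
  sim_records <- dplyr::left_join(
    groups, annotation[c("feature_name", "chromosome", "start", "end",
                         "strand")],
    by = "feature_name")
  beads <- tibble::tibble(
    barcode_group_id = seq_len(cfg$n_groups),
    barcode = random_sequences(cfg$n_groups, cfg$layout$barcode_len))
  structure(list(groups = groups, sim_records = sim_records,
                 annotation = annotation, beads = beads,
                 truth = list(planted_pairs = cfg$planted_pairs, weights = w),
                 cfg = cfg),
            class = "proxseq_synthetic")
}

#' @rdname generate_dataset
#' @details `null_dataset()` is [generate_dataset()] with any planted pairs
#'   removed; it provides the no-proximity null used for type-I-error
#'   checks.
#' @export
null_dataset <- function(cfg, seed = NULL) {
  cfg$planted_pairs <- NULL
  generate_dataset(cfg, seed = seed)
}

# one non-overlapping toy gene per feature: 800 bp genes spaced 1 kb apart,
# alternating strand, all on one toy chromosome
synthetic_annotation <- function(cfg) {
  nf <- cfg$n_features
  annotation_rows(tibble::tibble(
    chromosome = "chrS",
    start = (seq_len(nf) - 1L) * 1000L + 101L,
    end = (seq_len(nf) - 1L) * 1000L + 900L,
    strand = rep(c("+", "-"), length.out = nf),
    feature_name = cfg$features,
    is_repeat = FALSE, repeat_class = NA_character_))
}

random_sequences <- function(n, len) {
  if (n == 0L) return(character())
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

substitute_bases <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    b <- strsplit(s, "")[[1]]
    hit <- which(runif(length(b)) < rate)
    for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1L)
    paste(b, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Render full synthetic reads and alignments
#'
#' Turns a synthetic dataset into sequencing reads following the library
#' layout (bead barcode with optional substitution errors, fixed PCR
#' primer, random pentadecamer, 50 nt of cDNA) plus the matching
#' alignment records, as a splice-aware aligner would report them.
#'
#' @param dataset A [generate_dataset()] result.
#' @param fastq_path,sam_path Optional output paths; when given, a FASTQ
#'   file and a SAM file are written.
#' @return A list with `reads` (FASTQ tibble: `read_id`, `sequence`,
#'   `quality`), `alignments` (tibble `read_id`, `chromosome`, `start`,
#'   `end`, `strand`) and `truth` (read-level truth: `read_id`,
#'   `barcode_group_id`, `feature_name`).
#' @export
render_synthetic_reads <- function(dataset, fastq_path = NULL,
                                   sam_path = NULL) {
  stopifnot(inherits(dataset, "proxseq_synthetic"))
  cfg <- dataset$cfg
  layout <- cfg$layout
  recs <- dataset$sim_records
  recs <- recs[rep(seq_len(nrow(recs)), each = cfg$reads_per_proxy), ]
  n <- nrow(recs)
  if (n == 0L) {
    reads <- tibble::tibble(read_id = character(), sequence = character(),
                            quality = character())
    aln <- tibble::tibble(read_id = character(), chromosome = character(),
                          start = integer(), end = integer(),
                          strand = character())
    truth <- tibble::tibble(read_id = character(),
                            barcode_group_id = integer(),
                            feature_name = character())
  } else {
    read_id <- sprintf("read%06d", seq_len(n))
    bead_bc <- dataset$beads$barcode[recs$barcode_group_id]
    barcode <- if (cfg$clonal_beads) {
      substitute_bases(bead_bc, cfg$barcode_substitution_rate)
    } else {
      random_sequences(n, layout$barcode_len)
    }
    # one aligned position per proxy read (duplicate copies share it)
    gene_len <- recs$end - recs$start + 1L
    offset_max <- pmax(gene_len - layout$cdna_len, 0L)
    prox_idx <- rep(seq_len(n %/% cfg$reads_per_proxy),
                    each = cfg$reads_per_proxy)
    off_per_proxy <- floor(runif(max(prox_idx)) *
                             (offset_max[!duplicated(prox_idx)] + 1L))
    start <- recs$start + as.integer(off_per_proxy[prox_idx])
    end <- start + layout$cdna_len - 1L
    cdna <- random_sequences(n, layout$cdna_len)
    sequence <- paste0(barcode, layout$primer_seq,
                       random_sequences(n, layout$random_primer_len), cdna)
    reads <- tibble::tibble(read_id = read_id, sequence = sequence,
                            quality = strrep("I", nchar(sequence)))
    aln <- tibble::tibble(read_id = read_id, chromosome = recs$chromosome,
                          start = start, end = end, strand = recs$strand)
    truth <- tibble::tibble(read_id = read_id,
                            barcode_group_id = recs$barcode_group_id,
                            feature_name = recs$feature_name)
  }
  if (!is.null(fastq_path)) write_fastq(reads, fastq_path)
  if (!is.null(sam_path)) {
    write_sam(aln, reads, sam_path,
              chrom_lengths = c(chrS = max(c(dataset$annotation$end, 1L)) +
                                  1000L))
  }
  list(reads = reads, alignments = aln, truth = truth)
}

#' Write a synthetic dataset and its ground truth to files
#'
#' Emits the simulation-formatted records, the toy gene list, the
#' bead-to-barcode truth table, the true group memberships and the
#' generating configuration (key: value lines, matching the pipeline
#' config style) into a directory.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "proxseq_synthetic"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_simulation_formatted(dataset$sim_records,
                             file.path(dir, "simulation_formatted.txt.gz"))
  write_tsv_gz(dataset$annotation[c("chromosome", "start", "end", "strand",
                                    "feature_name")],
               file.path(dir, "gene_list.txt.gz"))
  write_tsv_gz(dataset$beads, file.path(dir, "truth_beads.txt.gz"))
  write_tsv_gz(dataset$groups, file.path(dir, "truth_groups.txt.gz"))
  cfg <- dataset$cfg
  planted <- if (is.null(cfg$planted_pairs)) "none" else
    paste(sprintf("%s-%s:%g", cfg$planted_pairs$feature_a,
                  cfg$planted_pairs$feature_b, cfg$planted_pairs$boost),
          collapse = ",")
  write_text_lines(c(
    paste0("n_features: ", cfg$n_features),
    paste0("abundance_exponent: ", cfg$abundance_exponent),
    paste0("n_groups: ", cfg$n_groups),
    paste0("group_size_lambda: ", cfg$group_size_lambda),
    paste0("planted_pairs: ", planted),
    paste0("barcode_substitution_rate: ", cfg$barcode_substitution_rate),
    paste0("clonal_beads: ", cfg$clonal_beads)),
    file.path(dir, "config.txt"))
  invisible(dir)
}

# minimal SAM writer for synthetic alignments (primary alignments only)
write_sam <- function(alignments, reads, path, chrom_lengths) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                      as.integer(chrom_lengths)))
  if (nrow(alignments) == 0L) {
    write_text_lines(header, path)
    return(invisible(path))
  }
  cdna_len <- alignments$end - alignments$start + 1L
  flag <- ifelse(alignments$strand == "-", 16L, 0L)
  seqs <- strrep("A", cdna_len)
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                  alignments$read_id, flag, alignments$chromosome,
                  alignments$start, cdna_len, seqs, strrep("I", cdna_len))
  write_text_lines(c(header, body), path)
  invisible(path)
}
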