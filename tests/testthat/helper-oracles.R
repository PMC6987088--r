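# Independent oracles used across the suite. These stay deliberately naive
# (per-base loops, full DP tables, exhaustive enumeration) so they share no
# code path with the implementation they check.

# textbook dynamic-programming edit distance (insert/delete/substitute = 1);
# N mismatches everything, including N
edit_distance_dp <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      match <- x[i] == y[j] && x[i] != "N"
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (!match))
    }
  }
  d[n + 1, m + 1]
}

# brute-force barcode grouping: connected components (igraph) of the
# edit-distance graph
oracle_group_barcodes <- function(barcodes, link_edit_distance = 2L) {
  ub <- unique(barcodes)
  n <- length(ub)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        adj[i, j] <- adj[j, i] <-
          edit_distance_dp(ub[i], ub[j]) <= link_edit_distance
      }
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  split(ub, comp)
}

# per-base brute-force annotation labeler implementing the priority rules
# directly: repeat (single class, both strands) > unique inner-contained
# gene > sole gene > ambiguous/none. Returns for every base and strand the
# winning label ("" = unlabelled).
oracle_label_bases <- function(genes, repeats, max_pos) {
  labels <- list("+" = rep("", max_pos), "-" = rep("", max_pos))
  for (pos in seq_len(max_pos)) {
    rcov <- which(repeats$start <= pos & repeats$end >= pos)
    rclasses <- unique(repeats$repeat_class[rcov])
    if (length(rclasses) == 1L) {
      labels[["+"]][pos] <- rclasses
      labels[["-"]][pos] <- rclasses
      next
    }
    if (length(rclasses) > 1L) next  # ambiguous repeat region: removed
    for (std in c("+", "-")) {
      gcov <- which(genes$start <= pos & genes$end >= pos &
                      genes$strand == std)
      if (length(gcov) == 1L) {
        labels[[std]][pos] <- genes$feature_name[gcov]
      } else if (length(gcov) > 1L) {
        inner <- gcov[vapply(gcov, function(i) {
          all(genes$start[i] >= genes$start[gcov] &
                genes$end[i] <= genes$end[gcov])
        }, logical(1))]
        if (length(inner) == 1L) labels[[std]][pos] <- genes$feature_name[inner]
      }
    }
  }
  labels
}

# expand a resolved annotation to the same per-base representation
annotation_to_bases <- function(ann, max_pos) {
  labels <- list("+" = rep("", max_pos), "-" = rep("", max_pos))
  for (i in seq_len(nrow(ann))) {
    span <- ann$start[i]:min(ann$end[i], max_pos)
    if (ann$strand[i] == ".") {
      labels[["+"]][span] <- ann$feature_name[i]
      labels[["-"]][span] <- ann$feature_name[i]
    } else {
      labels[[ann$strand[i]]][span] <- ann$feature_name[i]
    }
  }
  labels
}

# random toy annotation on one chromosome
random_toy_annotation <- function(n_genes, n_repeats, max_pos = 500L) {
  mk <- function(n, prefix) {
    if (n == 0L) return(NULL)
    start <- sample.int(max_pos - 20L, n, replace = TRUE)
    len <- sample.int(120L, n, replace = TRUE)
    tibble::tibble(chromosome = "c", start = start,
                   end = pmin(start + len, max_pos),
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   feature_name = paste0(prefix, seq_len(n)))
  }
  genes <- mk(n_genes, "G")
  repeats <- mk(n_repeats, "R")
  if (!is.null(repeats)) {
    repeats$is_repeat <- TRUE
    repeats$repeat_class <- sample(c("5S", "U2", "tRNA"), n_repeats,
                                   replace = TRUE)
    repeats$feature_name <- paste0(repeats$repeat_class, "_",
                                   seq_len(n_repeats))
  }
  list(genes = annotation_rows(genes),
       repeats = if (is.null(repeats)) NULL else annotation_rows(repeats))
}

# pure-R reference implementation of the constrained randomizer (same
# algorithm, written independently of the C++ kernel)
reference_randomize <- function(totals, sizes, max_restarts = 1000L) {
  feats <- names(totals)
  for (restart in 0:max_restarts) {
    tokens <- sample(rep(seq_along(feats), totals))
    order_g <- sample(seq_along(sizes))
    carry <- integer(0)
    ptr <- 1L
    groups <- vector("list", length(sizes))
    ok <- TRUE
    for (g in order_g) {
      k <- sizes[g]; cur <- integer(0); rej <- integer(0)
      while (length(cur) < k) {
        if (length(carry)) {
          cand <- carry[1]; carry <- carry[-1]
        } else if (ptr <= length(tokens)) {
          cand <- tokens[ptr]; ptr <- ptr + 1L
        } else {
          ok <- FALSE; break
        }
        if (cand %in% cur) rej <- c(rej, cand) else cur <- c(cur, cand)
      }
      if (!ok) break
      carry <- c(rej, carry)
      groups[[g]] <- feats[cur]
    }
    if (ok && length(carry) == 0L) return(groups)
  }
  stop("reference randomizer: restart cap")
}

# exhaustive enumeration of all valid assignments (0/1 feature-by-group
# matrices with the skeleton's margins); returns the list of matrices
enumerate_assignments <- function(totals, sizes) {
  nf <- length(totals); ng <- length(sizes)
  res <- list()
  rec <- function(f, cap, mat) {
    if (f > nf) {
      if (all(cap == 0L)) res[[length(res) + 1L]] <<- mat
      return(invisible())
    }
    for (s in combn(ng, totals[f], simplify = FALSE)) {
      if (all(cap[s] > 0L)) {
        cap2 <- cap; cap2[s] <- cap2[s] - 1L
        m2 <- mat; m2[f, s] <- 1L
        rec(f + 1L, cap2, m2)
      }
    }
  }
  rec(1L, as.integer(sizes), matrix(0L, nf, ng))
  res
}

# random feasible small skeleton (features <= 6, groups <= 5)
random_small_skeleton <- function() {
  repeat {
    ng <- sample(2:5, 1)
    sizes <- pmin(1L + rpois(ng, 0.8), 4L)
    nf <- sample(3:6, 1)
    tot <- as.integer(table(factor(
      sample(nf, sum(sizes), replace = TRUE, prob = nf:1), levels = 1:nf)))
    tot <- tot[tot > 0]
    if (length(tot) < 2 || any(tot > ng)) next
    names(tot) <- paste0("F", seq_along(tot))
    if (length(enumerate_assignments(tot, sizes)) > 0) {
      return(list(totals = tot, sizes = sizes))
    }
  }
}

# tibble of proxy reads from a list of member vectors
groups_to_records <- function(members) {
  tibble::tibble(
    barcode_group_id = rep(seq_along(members), lengths(members)),
    feature_name = unlist(members))
}

skeleton_from <- function(totals, sizes) {
  structure(list(features = names(totals),
                 totals = setNames(as.integer(totals), names(totals)),
                 group_sizes = as.integer(sizes)),
            class = "proxseq_skeleton")
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
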