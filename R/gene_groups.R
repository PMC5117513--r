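#' Gene group of a cluster
#'
#' The motifs in a cluster determine its gene group: the distinct genes
#' whose sequences contribute at least one motif (positive-scoring hit)
#' with its 3' base inside the cluster's columns.
#'
#' @param cluster one cluster row from [find_clusters()] (needs `start`,
#'   `end`, `cluster_key`), or any list with those fields.
#' @param column_scores the [scan_block()] result the cluster came from.
#' @param block the scanned [promoter_block()].
#' @return A `gene_group` object: list with `cluster_key`, `genes`
#'   (sorted unique gene ids), `size`.
#' @export
cluster_gene_group <- function(cluster, column_scores, block) {
  hits <- column_scores$hits
  in_seg <- hits$col3p >= cluster$start - 1L & hits$col3p <= cluster$end - 1L
  genes <- sort(unique(block$gene_ids[hits$seq_index[in_seg]]))
  structure(list(cluster_key = cluster$cluster_key %||%
                   cluster_key(column_scores$tf_name,
                               col_to_coord(cluster$start - 1L, block),
                               col_to_coord(cluster$end - 1L, block),
                               column_scores$strand),
                 genes = genes, size = length(genes)),
            class = "gene_group")
}

#' @export
print.gene_group <- function(x, ...) {
  cat(sprintf("<gene_group> %s: %d gene(s)\n", x$cluster_key, x$size))
  invisible(x)
}

#' Fisher exact test of a gene-group intersection
#'
#' Tests whether two cluster gene-groups overlap more (right tail) or less
#' (left tail) than expected by chance within the dataset's own gene
#' universe. With `N = |universe|`, `|A|`, `|B|` fixed, the intersection
#' size is hypergeometric; the tails are exact sums,
#' `p_right = P(X >= a)` and `p_left = P(X <= a)`.
#'
#' The universe must be the dataset's own gene complement, not a global
#' gene catalogue: promoter databases are biased samples of genes, and
#' enrichment is only meaningful against the genes that could have
#' appeared.
#'
#' @param groupA,groupB character vectors of gene ids (or `gene_group`
#'   objects); both must be subsets of `universe`.
#' @param universe character vector: every gene in the dataset.
#' @return A one-row tibble: `a` (intersection), `b` (A only), `c` (B
#'   only), `d` (neither), `p_right`, `p_left`.
#' @export
fisher_intersection <- function(groupA, groupB, universe) {
  if (inherits(groupA, "gene_group")) groupA <- groupA$genes
  if (inherits(groupB, "gene_group")) groupB <- groupB$genes
  universe <- unique(universe)
  groupA <- unique(groupA); groupB <- unique(groupB)
  if (!all(groupA %in% universe) || !all(groupB %in% universe)) {
    abort("gene groups must be subsets of the universe")
  }
  N <- length(universe)
  if (N < 2L) abort("universe must contain at least 2 genes")
  a <- length(intersect(groupA, groupB))
  mA <- length(groupA); mB <- length(groupB)
  tibble(a = a, b = mA - a, c = mB - a, d = N - mA - mB + a,
         p_right = phyper(a - 1L, mA, N - mA, mB, lower.tail = FALSE),
         p_left = phyper(a, mA, N - mA, mB))
}

#' Test all pairwise gene-group intersections
#'
#' Runs [fisher_intersection()] on every unordered pair of cluster gene
#' groups (a cluster is never intersected with itself) and flags pairs
#' significant after Bonferroni correction.
#'
#' @param clusters a [find_clusters()]-style tibble with `cluster_key` and
#'   a `genes` list-column (e.g. the pipeline's significant clusters).
#' @param universe character vector of all genes in the dataset.
#' @param alpha family-wise significance level (default 0.05).
#' @param m_tests number of tests for the Bonferroni threshold; defaults to
#'   the number of pairs. Use `2 * pair_count(k)` to correct both tails.
#' @return A tibble with one row per unordered pair: `key_a`, `key_b`,
#'   contingency `a,b,c,d`, `p_right`, `p_left`, `significant` (right tail
#'   at the Bonferroni threshold) and the `threshold` used.
#' @export
intersect_gene_groups <- function(clusters, universe, alpha = 0.05,
                                  m_tests = NULL) {
  k <- nrow(clusters)
  if (k < 2L) {
    return(tibble(key_a = character(0), key_b = character(0),
                  a = integer(0), b = integer(0), c = integer(0),
                  d = integer(0), p_right = numeric(0), p_left = numeric(0),
                  significant = logical(0), threshold = numeric(0)))
  }
  pairs <- utils::combn(k, 2L)
  m <- m_tests %||% pair_count(k)
  thr <- bonferroni_threshold(alpha, m)
  out <- lapply(seq_len(ncol(pairs)), function(i) {
    ia <- pairs[1L, i]; ib <- pairs[2L, i]
    ft <- fisher_intersection(clusters$genes[[ia]], clusters$genes[[ib]],
                              universe)
    ft$key_a <- clusters$cluster_key[ia]
    ft$key_b <- clusters$cluster_key[ib]
    ft
  })
  out <- dplyr::bind_rows(out)
  out$significant <- out$p_right <= thr
  out$threshold <- thr
  out[, c("key_a", "key_b", "a", "b", "c", "d", "p_right", "p_left",
          "significant", "threshold")]
}

#' Multiple-testing arithmetic
#'
#' Small exact helpers used throughout the pipeline's reporting:
#' `bonferroni_threshold(alpha, m)` is `alpha / m`;
#' `pair_count(k)` is the number of unordered pairs `k (k - 1) / 2`;
#' `expected_false_positives(m, pi)` is `m * pi`, the expected number of
#' uniformly distributed p-values at or below `pi` among `m` tests.
#'
#' @param alpha significance level in (0, 1).
#' @param m_tests number of tests (`>= 1`).
#' @param k_groups number of gene groups.
#' @param pi_threshold p-value threshold in (0, 1).
#' @return A single number.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 53 * 2)   # 4.72e-4 to 3 s.f.
#' pair_count(43)                       # 903
#' expected_false_positives(212, 0.2)   # 42.4
bonferroni_threshold <- function(alpha, m_tests) {
  stopifnot(alpha > 0, alpha < 1, m_tests >= 1)
  alpha / m_tests
}

#' @rdname bonferroni_threshold
#' @export
pair_count <- function(k_groups) {
  stopifnot(k_groups >= 0)
  k_groups * (k_groups - 1) / 2
}

#' @rdname bonferroni_threshold
#' @export
expected_false_positives <- function(m_tests, pi_threshold) {
  stopifnot(pi_threshold >= 0, pi_threshold < 1)
  m_tests * pi_threshold
}

#' Export cluster gene lists
#'
#' Writes one plain-text file per cluster gene group (one gene id per
#' line, unique, lexicographically sorted), for use with external
#' gene-ontology enrichment tools.
#'
#' @param clusters a tibble with `cluster_key` and a `genes` list-column,
#'   or a list of `gene_group` objects.
#' @param destination directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_gene_lists <- function(clusters, destination) {
  if (!dir.exists(destination)) dir.create(destination, recursive = TRUE)
  if (is.data.frame(clusters)) {
    keys <- clusters$cluster_key
    groups <- clusters$genes
  } else {
    keys <- vapply(clusters, `[[`, "", "cluster_key")
    groups <- lapply(clusters, `[[`, "genes")
  }
  if (length(keys) == 0L) abort("no gene groups to export")
  paths <- character(length(keys))
  for (i in seq_along(keys)) {
    fname <- paste0(gsub("[^A-Za-z0-9_+-]", "_", keys[i]), ".txt")
    paths[i] <- file.path(destination, fname)
    genes <- sort(unique(groups[[i]]))
    if (length(genes) == 0L) {
      warn(sprintf("gene group '%s' is empty", keys[i]))
    }
    writeLines(genes, paths[i])
  }
  invisible(paths)
}
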