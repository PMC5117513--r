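#' Pipeline configuration
#'
#' Bundles every tunable parameter of the cluster pipeline so a run can be
#' reproduced bit-exactly from its manifest.
#'
#' @param rho normalized gap penalty (default 1.4; must be > 1).
#' @param K Karlin prefactor (default 1).
#' @param pseudocount Dirichlet pseudocount for count matrices (0.5).
#' @param column_sum_policy `"positive_sum"` or `"clamped_total"`.
#' @param strands strands to scan (default both).
#' @param cluster_alpha family-wise level for cluster significance (0.05);
#'   the per-cluster threshold is Bonferroni-corrected over
#'   `#matrices * #strands` tests.
#' @param intersection_alpha family-wise level for intersection tests.
#' @param intersection_mode `"pairs"` (threshold `alpha / C(k,2)`) or
#'   `"two_sided_pairs"` (`alpha / (2 * C(k,2))`, correcting both tails).
#' @param bg_block_size,bg_pad_left,bg_pad_right,bg_pseudocount,bg_order
#'   background-model settings (see [fit_background()]).
#' @param bg_mode background conditioning mode (`"context2"` or `"left"`).
#' @param seed seed recorded in the manifest and used for any permutation
#'   p-values.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(rho = 1.4, K = 1, pseudocount = 0.5,
                            column_sum_policy = "positive_sum",
                            strands = c("+", "-"),
                            cluster_alpha = 0.05,
                            intersection_alpha = 0.05,
                            intersection_mode = c("pairs", "two_sided_pairs"),
                            bg_block_size = 23L, bg_pad_left = 24L,
                            bg_pad_right = 3L, bg_pseudocount = 0.5,
                            bg_order = 3L, bg_mode = "context2",
                            seed = 1L) {
  if (rho <= 1) abort("rho must exceed 1 (logarithmic regime)")
  stopifnot(cluster_alpha > 0, cluster_alpha < 1,
            intersection_alpha > 0, intersection_alpha < 1,
            all(strands %in% c("+", "-")))
  structure(list(rho = rho, K = K, pseudocount = pseudocount,
                 column_sum_policy = column_sum_policy,
                 strands = strands, cluster_alpha = cluster_alpha,
                 intersection_alpha = intersection_alpha,
                 intersection_mode = match.arg(intersection_mode),
                 bg_block_size = bg_block_size, bg_pad_left = bg_pad_left,
                 bg_pad_right = bg_pad_right,
                 bg_pseudocount = bg_pseudocount, bg_order = bg_order,
                 bg_mode = bg_mode, seed = seed),
            class = "pipeline_config")
}

#' Run the full positional-cluster pipeline
#'
#' For every count matrix and strand: fit the background once per block,
#' scan, detect maximal segments, assign Karlin-Altschul p-values, and
#' retain clusters at the Bonferroni-corrected threshold
#' `cluster_alpha / (#matrices * #strands)`. Significant clusters yield
#' gene groups, whose unordered pairs are tested both-tailed for
#' intersection enrichment against the block's own gene universe.
#'
#' @param block a [promoter_block()].
#' @param matrices list of [count_matrix()] objects (e.g. [read_jaspar()]).
#' @param config a [pipeline_config()].
#' @param bg optionally, a pre-fitted [fit_background()] model.
#' @return A `pipeline_result`: list with `clusters` (all maximal
#'   segments), `significant` (those at the threshold), `intersections`,
#'   `universe`, `manifest` (parameters + per-stage tallies), and the
#'   fitted `bg`.
#' @export
run_pipeline <- function(block, matrices, config = pipeline_config(),
                         bg = NULL) {
  block <- with_encoding(block)
  if (inherits(matrices, "count_matrix")) matrices <- list(matrices)
  matrices <- matrices[order(vapply(matrices, `[[`, "", "tf_name"))]
  bg <- bg %||% fit_background(block, block_size = config$bg_block_size,
                               window_pad_left = config$bg_pad_left,
                               window_pad_right = config$bg_pad_right,
                               pseudocount = config$bg_pseudocount,
                               order = config$bg_order)
  m_tests <- length(matrices) * length(config$strands)
  cluster_thr <- bonferroni_threshold(config$cluster_alpha, m_tests)

  all_clusters <- list()
  n_hits <- 0L
  for (cm in matrices) {
    pssm <- counts_to_pssm(cm, config$pseudocount)
    for (strand in config$strands) {
      cs <- scan_block(block, pssm, bg, strand = strand,
                       column_sum_policy = config$column_sum_policy,
                       mode = config$bg_mode)
      n_hits <- n_hits + nrow(cs$hits)
      cl <- find_clusters(cs, block, rho = config$rho, K = config$K)
      if (nrow(cl)) all_clusters[[length(all_clusters) + 1L]] <- cl
    }
  }
  clusters <- dplyr::bind_rows(all_clusters)
  if (nrow(clusters)) {
    clusters <- clusters[order(clusters$tf_name, clusters$p_value), ]
  }
  significant <- clusters[clusters$p_value <= cluster_thr, , drop = FALSE]
  universe <- sort(unique(block$gene_ids))
  k <- nrow(significant)
  m_pairs <- switch(config$intersection_mode,
                    pairs = pair_count(k),
                    two_sided_pairs = 2 * pair_count(k))
  intersections <- if (k >= 2L) {
    intersect_gene_groups(significant, universe,
                          alpha = config$intersection_alpha,
                          m_tests = max(1, m_pairs))
  } else {
    inform("fewer than 2 significant clusters: no intersections to test")
    intersect_gene_groups(significant[0, ], universe)
  }
  manifest <- list(
    config = unclass(config),
    n_sequences = length(block$sequences), n_genes = block$n_genes,
    L = block$L, tss_col = block$tss_col,
    n_matrices = length(matrices),
    tf_names = vapply(matrices, `[[`, "", "tf_name"),
    n_hits = n_hits, cluster_threshold = cluster_thr,
    n_clusters = nrow(clusters), n_significant = k,
    n_pairs_tested = pair_count(k),
    intersection_threshold = if (k >= 2L)
      bonferroni_threshold(config$intersection_alpha, max(1, m_pairs))
    else NA_real_,
    n_enriched = sum(intersections$significant))
  structure(list(clusters = clusters, significant = significant,
                 intersections = intersections, universe = universe,
                 manifest = manifest, bg = bg),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<pipeline_result> %d seqs / %d genes; %d matrices x %d strand(s)\n  %d hits -> %d clusters, %d significant at p <= %.3g\n  %d pair(s) tested, %d enriched at p <= %.3g\n",
    m$n_sequences, m$n_genes, m$n_matrices, length(m$config$strands),
    m$n_hits, m$n_clusters, m$n_significant, m$cluster_threshold,
    m$n_pairs_tested, m$n_enriched,
    ifelse(is.na(m$intersection_threshold), NA, m$intersection_threshold)))
  invisible(x)
}

#' @method tidy pipeline_result
#' @export
tidy.pipeline_result <- function(x, ...) {
  dplyr::select(x$clusters, -dplyr::any_of("genes"))
}

#' @method glance pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) {
  m <- x$manifest
  tibble(n_sequences = m$n_sequences, n_genes = m$n_genes,
         n_hits = m$n_hits, n_clusters = m$n_clusters,
         n_significant = m$n_significant,
         cluster_threshold = m$cluster_threshold,
         n_pairs_tested = m$n_pairs_tested, n_enriched = m$n_enriched)
}

#' Write the pipeline's tables as TSV
#'
#' Writes `clusters.tsv` (TF, strand, cluster p, From, To, spread,
#' percent multiple motifs, hit and gene counts) and
#' `intersections.tsv` (long format: pair keys, contingency, both tails,
#' significance) into a directory.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_pipeline_tables <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cl <- dplyr::select(result$clusters, dplyr::any_of(c(
    "tf_name", "strand", "p_value", "From", "To", "spread",
    "pct_multiple_motifs", "n_hits", "n_genes", "cluster_key")))
  p1 <- file.path(dir, "clusters.tsv")
  p2 <- file.path(dir, "intersections.tsv")
  readr::write_tsv(cl, p1)
  readr::write_tsv(result$intersections, p2)
  paths <- c(p1, p2)
  if (nrow(result$intersections) >= 1L) {
    im <- render_intersection_matrix(result)
    pm <- as.data.frame(im$p)
    pm <- cbind(cluster = rownames(im$p), pm)
    p3 <- file.path(dir, "intersection_matrix.tsv")
    readr::write_tsv(pm, p3)
    paths <- c(paths, p3)
  }
  invisible(paths)
}

#' Tune the normalized gap penalty
#'
#' Scans once per matrix/strand and re-segments under each candidate
#' `rho`, reporting the median spread of significant clusters and their
#' count. Spreads shrink as `rho` grows; the recommendation is the
#' smallest `rho` whose median spread is at most `target_spread` (10 bp by
#' default, i.e. within about +/-5 bp of a preferred position).
#'
#' @param block a [promoter_block()].
#' @param matrices list of [count_matrix()] objects.
#' @param rho_grid candidate values, all > 1.
#' @param target_spread largest acceptable median spread (bp).
#' @param config base [pipeline_config()] (its `rho` is overridden).
#' @return A tibble (`rho`, `median_spread`, `n_significant`,
#'   `recommended`); attribute `recommended_rho` holds the chosen value
#'   (NA if no grid point meets the target).
#' @export
tune_rho <- function(block, matrices, rho_grid = c(1.2, 1.4, 1.6),
                     target_spread = 10, config = pipeline_config()) {
  if (any(rho_grid <= 1)) abort("every rho in the grid must exceed 1")
  rho_grid <- sort(rho_grid)
  block <- with_encoding(block)
  if (inherits(matrices, "count_matrix")) matrices <- list(matrices)
  bg <- fit_background(block, block_size = config$bg_block_size,
                       window_pad_left = config$bg_pad_left,
                       window_pad_right = config$bg_pad_right,
                       pseudocount = config$bg_pseudocount,
                       order = config$bg_order)
  m_tests <- length(matrices) * length(config$strands)
  thr <- bonferroni_threshold(config$cluster_alpha, m_tests)
  scans <- list()
  for (cm in matrices) {
    pssm <- counts_to_pssm(cm, config$pseudocount)
    for (strand in config$strands) {
      scans[[length(scans) + 1L]] <-
        scan_block(block, pssm, bg, strand = strand,
                   column_sum_policy = config$column_sum_policy,
                   mode = config$bg_mode)
    }
  }
  rows <- lapply(rho_grid, function(rho) {
    spreads <- numeric(0)
    nsig <- 0L
    for (cs in scans) {
      cl <- find_clusters(cs, block, rho = rho, K = config$K)
      sig <- cl[cl$p_value <= thr, , drop = FALSE]
      spreads <- c(spreads, sig$spread)
      nsig <- nsig + nrow(sig)
    }
    tibble(rho = rho,
           median_spread = if (length(spreads)) stats::median(spreads) else NA_real_,
           n_significant = nsig)
  })
  out <- dplyr::bind_rows(rows)
  ok <- !is.na(out$median_spread) & out$median_spread <= target_spread
  rec <- if (any(ok)) out$rho[which(ok)[1L]] else NA_real_
  out$recommended <- !is.na(rec) & out$rho == rec
  attr(out, "recommended_rho") <- rec
  out
}

#' Grayscale intersection matrix
#'
#' Renders the pairwise intersection p-values as a lower-triangle
#' grayscale matrix: black is p = 0, white is p = 1, and the significance
#' threshold maps to exactly 50% gray (piecewise-linear on either side).
#' Rows/columns are the clusters sorted alphabetically by TF and then by
#' cluster p-value; the diagonal (a group against itself) is omitted.
#'
#' @param result a [run_pipeline()] result, or an intersection tibble.
#' @param mode which tail to render, `"right"` (default) or `"left"`.
#' @param threshold p-value mapping to mid-gray; defaults to the
#'   Bonferroni threshold stored with the intersections.
#' @return An `intersection_matrix`: list with `gray` (numeric matrix in
#'   `[0,1]`, upper triangle and diagonal `NA`), `p` (the p-value matrix),
#'   `keys`, `threshold`. Use `autoplot()` to draw it.
#' @export
render_intersection_matrix <- function(result, mode = c("right", "left"),
                                       threshold = NULL) {
  mode <- match.arg(mode)
  ints <- if (inherits(result, "pipeline_result")) result$intersections else result
  if (nrow(ints) < 1L) abort("need at least one tested pair (>= 2 clusters)")
  threshold <- threshold %||% ints$threshold[1L]
  keys <- sort(unique(c(ints$key_a, ints$key_b)))
  if (inherits(result, "pipeline_result") && nrow(result$significant)) {
    sig <- result$significant[order(result$significant$tf_name,
                                    result$significant$p_value), ]
    keys <- sig$cluster_key
  }
  k <- length(keys)
  P <- matrix(NA_real_, k, k, dimnames = list(keys, keys))
  pcol <- if (mode == "right") ints$p_right else ints$p_left
  ia <- match(ints$key_a, keys); ib <- match(ints$key_b, keys)
  lo <- pmax(ia, ib); hi <- pmin(ia, ib)
  P[cbind(lo, hi)] <- pcol  # lower triangle only
  gray <- gray_from_p(P, threshold)
  structure(list(gray = gray, p = P, keys = keys, threshold = threshold,
                 mode = mode),
            class = "intersection_matrix")
}

# internal: piecewise-linear p -> gray mapping with threshold at 0.5
gray_from_p <- function(p, threshold) {
  ifelse(p <= threshold,
         0.5 * p / threshold,
         0.5 + 0.5 * (p - threshold) / (1 - threshold))
}

#' @export
print.intersection_matrix <- function(x, ...) {
  cat(sprintf("<intersection_matrix> %d clusters, %s tail; threshold %.3g at 50%% gray\n",
              length(x$keys), x$mode, x$threshold))
  invisible(x)
}

#' @method autoplot intersection_matrix
#' @export
autoplot.intersection_matrix <- function(object, ...) {
  df <- as.data.frame(as.table(object$gray), stringsAsFactors = FALSE)
  names(df) <- c("row", "col", "gray")
  df <- df[!is.na(df$gray), ]
  df$row <- factor(df$row, levels = rev(object$keys))
  df$col <- factor(df$col, levels = object$keys)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$gray)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), name = "gray") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s-tail intersection p-values", object$mode)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
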