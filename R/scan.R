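#' Log-odds score of one candidate site
#'
#' Scores a single (sequence, strand, position) candidate: the motif model
#' log-probability of the site letters minus their background
#' log-probability under the piecewise Markov model with flank
#' conditioning. On the minus strand the motif model is applied to the
#' reverse complement of the plus-strand window, while the background is
#' evaluated on the plus-strand letters of the same window (one background
#' model per block serves both strands). Positions are assigned to the
#' motif's 3' base: on the plus strand that is the rightmost occupied
#' column; on the minus strand the leftmost (5'-most plus-strand) column.
#'
#' @param pssm a [counts_to_pssm()] model.
#' @param bg_model a [fit_background()] model fitted on the same block.
#' @param block the [promoter_block()].
#' @param seq_index 1-based sequence index.
#' @param strand `"+"` or `"-"`.
#' @param col3p 0-based alignment column of the motif's 3' base.
#' @param mode background mode, `"context2"` (default) or `"left"`.
#' @return A finite log-odds score (natural log).
#' @export
score_site <- function(pssm, bg_model, block, seq_index, strand, col3p,
                       mode = c("context2", "left")) {
  mode <- match.arg(mode)
  m <- encode_block(block)
  L <- block$L
  w <- pssm$width
  ord <- bg_model$order
  c1 <- col3p + 1L  # 1-based
  if (strand == "+") {
    a <- c1 - w + 1L; e <- c1
  } else {
    a <- c1; e <- c1 + w - 1L
  }
  if (a < 1L || e > L) abort("site out of range")
  plus_site <- m[seq_index, a:e]
  lf <- if (a > 1L) m[seq_index, max(1L, a - ord):(a - 1L)] else integer(0)
  rf <- if (e < L) m[seq_index, (e + 1L):min(L, e + ord)] else integer(0)
  lp <- if (strand == "+") pssm$log_prob else log(revcomp_prob(pssm$prob))
  motif_lp <- sum(lp[cbind(plus_site, seq_len(w))])
  bg_lp <- site_log_prob(bg_model, plus_site, lf, rf, mode = mode,
                         col3p = col3p)
  motif_lp - bg_lp
}

#' Scan one strand of a promoter block with one motif
#'
#' Scores every admissible (sequence, position) pair, records motif hits
#' (positive-scoring sites) positioned at their 3' base, and aggregates a
#' nonnegative score for every alignment column:
#'
#' * `"positive_sum"` (default): the column score is the sum of the motif
#'   (positive) scores whose 3' bases fall in the column;
#' * `"clamped_total"`: the sum over all sequences of the raw score at the
#'   column, negative sums set to 0.
#'
#' @inheritParams score_site
#' @param column_sum_policy `"positive_sum"` or `"clamped_total"`.
#' @param mode background conditioning mode passed to the background model.
#' @return An object of class `column_scores`: list with `tf_name`,
#'   `strand`, `x` (length-L numeric, `x[c+1]` scores 0-based column `c`),
#'   `hits` (tibble: `seq_index`, `strand`, `col3p`, `coord`, `width`,
#'   `score`), `policy`, `width`, `L`, `tss_col`.
#' @export
scan_block <- function(block, pssm, bg_model, strand = "+",
                       column_sum_policy = c("positive_sum", "clamped_total"),
                       mode = "context2") {
  column_sum_policy <- match.arg(column_sum_policy)
  if (!strand %in% c("+", "-")) abort("strand must be '+' or '-'")
  sc <- scan_scores(block, pssm, bg_model, strand, mode = mode)
  n <- nrow(sc$score); A <- ncol(sc$score)
  L <- block$L
  pos <- sc$score > 0
  x <- numeric(L)
  if (column_sum_policy == "positive_sum") {
    x[sc$col3p_col] <- colSums(sc$score * pos)
  } else {
    x[sc$col3p_col] <- pmax(0, colSums(sc$score))
  }
  idx <- which(pos, arr.ind = TRUE)
  hits <- tibble(
    seq_index = idx[, 1L],
    strand = strand,
    col3p = sc$col3p_col[idx[, 2L]] - 1L,
    width = pssm$width,
    score = sc$score[idx])
  hits$coord <- col_to_coord(hits$col3p, block)
  hits <- hits[order(hits$col3p, hits$seq_index), c("seq_index", "strand",
                                                    "col3p", "coord", "width", "score")]
  structure(list(tf_name = pssm$tf_name, strand = strand, x = x,
                 hits = hits, policy = column_sum_policy,
                 width = pssm$width, L = L, tss_col = block$tss_col),
            class = "column_scores")
}

#' @export
print.column_scores <- function(x, ...) {
  cat(sprintf("<column_scores> %s strand %s: %d hits over %d columns (policy %s); max x = %.3f\n",
              x$tf_name, x$strand, nrow(x$hits), x$L, x$policy, max(x$x)))
  invisible(x)
}

#' @method tidy column_scores
#' @export
tidy.column_scores <- function(x, ...) x$hits

#' @method autoplot column_scores
#' @export
autoplot.column_scores <- function(object, ...) {
  map <- list(tss_col = object$tss_col, L = object$L)
  df <- tibble(coord = col_to_coord(0:(object$L - 1L), map), x = object$x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coord, y = .data$x)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "position relative to TSS (bp)",
                  y = "column score",
                  title = sprintf("%s (%s strand)", object$tf_name, object$strand)) +
    ggplot2::theme_minimal()
}

# internal: full score matrix for one (pssm, strand).
# Returns list(score = n x A matrix over site start columns a = 1..A,
#              col3p_col = 1-based 3'-base column per a).
scan_scores <- function(block, pssm, bg, strand, mode = "context2") {
  m <- encode_block(block)
  n <- nrow(m); L <- block$L
  w <- pssm$width
  ord <- bg$order; S <- bg$S
  nblk <- length(bg$block_starts)
  if (L < w) abort("motif wider than the alignment")
  A <- L - w + 1L
  lp <- if (strand == "+") pssm$log_prob else log(revcomp_prob(pssm$prob))
  ctx <- context_codes(m, ord)
  lt <- log(bg$trans)  # (nblk, S, 4), linear index blk + nblk*(ctx-1) + nblk*S*(base-1)

  e_of_a <- (1:A) + w - 1L
  col3p_col <- if (strand == "+") e_of_a else 1:A
  blkv <- bg$col2block[col3p_col]

  # motif log-probability, all start positions
  M <- matrix(0, n, A)
  for (j in seq_len(w)) {
    lpj <- lp[, j]
    M <- M + matrix(lpj[m[, j:(j + A - 1L), drop = FALSE]], n, A)
  }
  if (mode == "left") {
    B <- bg_left_matrix(bg, m, ctx, lt, blkv, w, A)
  } else {
    B <- bg_context2_matrix(bg, m, ctx, lt, blkv, w, A)
  }
  list(score = M - B, col3p_col = col3p_col)
}

# internal: chain (left-conditioned) background log-prob per site start
bg_left_matrix <- function(bg, m, ctx, lt, blkv, w, A) {
  n <- nrow(m); L <- ncol(m); ord <- bg$order; S <- bg$S
  nblk <- length(bg$block_starts)
  B <- matrix(NA_real_, n, A)
  main <- which((1:A) >= ord + 1L)
  if (length(main)) {
    acc <- matrix(0, n, length(main))
    for (j in seq_len(w)) {
      cols <- main + j - 1L
      idx <- rep(blkv[main], each = n) +
        (ctx[, cols, drop = FALSE] - 1L) * nblk +
        (m[, cols, drop = FALSE] - 1L) * (nblk * S)
      acc <- acc + matrix(lt[idx], n, length(main))
    }
    B[, main] <- acc
  }
  for (a in seq_len(min(ord, A))) {
    e <- a + w - 1L
    blk <- blkv[a]
    for (i in seq_len(n)) {
      lf <- if (a > 1L) m[i, 1:(a - 1L)] else integer(0)
      B[i, a] <- chain_log_prob(bg, blk, c(lf, m[i, a:e]), n_context = length(lf))
    }
  }
  B
}

# internal: two-sided (context2) background log-prob per site start
bg_context2_matrix <- function(bg, m, ctx, lt, blkv, w, A) {
  n <- nrow(m); L <- ncol(m); ord <- bg$order; S <- bg$S
  nblk <- length(bg$block_starts)
  B <- matrix(NA_real_, n, A)

  # log T^(w+ord) per block, for the full-flank denominator
  key <- sprintf("logTw3_%d", w)
  logTw3 <- bg$cache[[key]]
  if (is.null(logTw3)) {
    logTw3 <- array(NA_real_, c(nblk, S, S))
    for (blk in seq_len(nblk)) {
      logTw3[blk, , ] <- log(transfer_power(bg, blk, w + ord))
    }
    bg$cache[[key]] <- logTw3
  }

  # main region: full left context (a >= ord+1) and full right flank
  main <- which((1:A) >= ord + 1L & (e_of <- (1:A) + w - 1L) <= L - ord)
  if (length(main)) {
    acc <- matrix(0, n, length(main))
    for (j in seq_len(w)) {            # P(site | left)
      cols <- main + j - 1L
      idx <- rep(blkv[main], each = n) +
        (ctx[, cols, drop = FALSE] - 1L) * nblk +
        (m[, cols, drop = FALSE] - 1L) * (nblk * S)
      acc <- acc + matrix(lt[idx], n, length(main))
    }
    emain <- main + w - 1L
    for (k in seq_len(ord)) {          # P(right | site tail)
      cols <- emain + k
      idx <- rep(blkv[main], each = n) +
        (ctx[, cols, drop = FALSE] - 1L) * nblk +
        (m[, cols, drop = FALSE] - 1L) * (nblk * S)
      acc <- acc + matrix(lt[idx], n, length(main))
    }
    # denominator: log P(right | left) across w free steps
    left_code <- ctx[, main, drop = FALSE]
    right_code <- ctx[, emain + ord + 1L, drop = FALSE]
    idx <- rep(blkv[main], each = n) +
      (left_code - 1L) * nblk +
      (right_code - 1L) * (nblk * S)
    acc <- acc - matrix(logTw3[idx], n, length(main))
    B[, main] <- acc
  }

  # right edge: full left context, truncated right flank (r < ord)
  redge <- which((1:A) >= ord + 1L & (1:A) + w - 1L > L - ord)
  for (a in redge) {
    e <- a + w - 1L
    r <- L - e
    blk <- blkv[a]
    # P(site | left)
    acc <- numeric(n)
    for (j in seq_len(w)) {
      cc <- a + j - 1L
      acc <- acc + lt[blk + (ctx[, cc] - 1L) * nblk + (m[, cc] - 1L) * (nblk * S)]
    }
    if (r > 0L) {
      for (k in seq_len(r)) {
        cc <- e + k
        acc <- acc + lt[blk + (ctx[, cc] - 1L) * nblk + (m[, cc] - 1L) * (nblk * S)]
      }
      DenR <- denr_matrix(bg, blk, w, r)  # S x 4^r
      rc <- integer(n)
      for (k in seq_len(r)) rc <- rc * 4L + (m[, e + k] - 1L)
      acc <- acc - log(DenR[cbind(ctx[, a], rc + 1L)])
    }
    B[, a] <- acc
  }

  # left edge: truncated left context -- exact per-sequence propagation
  for (a in seq_len(min(ord, A))) {
    e <- a + w - 1L
    blk <- blkv[a]
    for (i in seq_len(n)) {
      lf <- if (a > 1L) m[i, 1:(a - 1L)] else integer(0)
      rf <- if (e < L) m[i, (e + 1L):min(L, e + ord)] else integer(0)
      # any 0-based column inside block blkv[a] selects the right tables
      B[i, a] <- site_log_prob(bg, m[i, a:e], lf, rf, mode = "context2",
                               col3p = bg$block_starts[blkv[a]] - 1L)
    }
  }
  B
}

# internal: S x 4^r matrix of P(r right letters | left state) after w free
# steps; cached per (block, w, r)
denr_matrix <- function(bg, blk, w, r) {
  key <- sprintf("DenR_%d_%d_%d", blk, w, r)
  if (!is.null(bg$cache[[key]])) return(bg$cache[[key]])
  S <- bg$S; ord <- bg$order
  # indicator of a state's most recent r letters
  st <- seq_len(S) - 1L
  lastr <- st %% 4L^r
  Mr <- matrix(0, S, 4L^r)
  Mr[cbind(seq_len(S), lastr + 1L)] <- 1
  Ar <- transfer_power(bg, blk, r) %*% Mr
  out <- transfer_power(bg, blk, w) %*% Ar
  bg$cache[[key]] <- out
  out
}

#' Export motif hits as BED-like TSV
#'
#' Writes hits as 0-based half-open plus-strand intervals with name,
#' score, and strand columns (`seq`, `start`, `end`, `name`, `score`,
#' `strand`), one row per hit.
#'
#' @param column_scores a [scan_block()] result (or a list of them).
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_hits_bed <- function(column_scores, path) {
  if (inherits(column_scores, "column_scores")) {
    column_scores <- list(column_scores)
  }
  rows <- lapply(column_scores, function(cs) {
    h <- cs$hits
    w <- cs$width
    start <- ifelse(h$strand == "+", h$col3p - w + 1L, h$col3p)
    tibble(seq = sprintf("seq%05d", h$seq_index),
           start = start, end = start + w,
           name = cs$tf_name, score = h$score, strand = h$strand)
  })
  readr::write_tsv(dplyr::bind_rows(rows), path, col_names = TRUE)
  invisible(path)
}
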