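#' Fit a position-varying Markov background model
#'
#' Promoter composition changes sharply with distance from the TSS, so a
#' single background model misstates motif odds. The model fitted here is
#' piecewise: alignment columns are grouped into consecutive blocks of
#' `block_size` columns, and for each block an order-`order` Markov
#' transition table is estimated from a fitting window around the block.
#' With the defaults the window has length
#' `window_pad_left + block_size + window_pad_right = 24 + 23 + 3 = 50`
#' columns: the 5' pad accommodates the widest scanned matrix (21) plus an
#' order-3 left flank, and the 3' pad an order-3 right flank, so every site
#' whose 3' base falls in the block is scored entirely from data inside the
#' block's own window. Windows are clipped at the alignment edges.
#'
#' Counts of (context, next base) pairs are accumulated over all sequences
#' and all window positions whose full context lies inside the window; a
#' pseudocount is added to every (context, base) cell and rows are
#' normalized. Lower-order fallback tables (contexts of length
#' `order-1 .. 0`, obtained by marginalizing the same counts) are kept so
#' columns near the alignment edge remain scoreable.
#'
#' @param block a [promoter_block()].
#' @param block_size number of alignment columns sharing one transition
#'   table (default 23).
#' @param window_pad_left,window_pad_right columns added 5' and 3' of each
#'   block to form its fitting window (defaults 24 and 3).
#' @param pseudocount added to every (context, base) count cell
#'   (default 0.5).
#' @param order Markov order (default 3; contexts are `order`-mers).
#' @return An object of class `background_model`.
#' @export
fit_background <- function(block, block_size = 23L,
                           window_pad_left = 24L, window_pad_right = 3L,
                           pseudocount = 0.5, order = 3L) {
  stopifnot(block_size >= 1L, order >= 1L, pseudocount > 0)
  m <- encode_block(block)
  L <- block$L
  ord <- as.integer(order)
  S <- 4L^ord
  if (L < ord + 1L) abort("block too short for the requested Markov order")

  # ctx[i, c] = 1-based code of the `ord` letters ending at column c-1
  # (i.e. the context that precedes column c); defined for c >= ord+1.
  ctx <- context_codes(m, ord)

  block_starts <- seq(1L, L, by = block_size)
  nblk <- length(block_starts)
  col2block <- rep(seq_len(nblk), each = block_size, length.out = L)

  trans <- array(NA_real_, c(nblk, S, 4L))
  fallback <- lapply(0:(ord - 1L), function(l) array(NA_real_, c(nblk, 4L^l, 4L)))
  ctx_marg <- matrix(NA_real_, nblk, S)

  for (k in seq_len(nblk)) {
    ws <- max(1L, block_starts[k] - window_pad_left)
    we <- min(L, block_starts[k] + block_size - 1L + window_pad_right)
    if (we - ws + 1L < ord + 1L) abort("fitting window shorter than order + 1 columns")
    cols <- (ws + ord):we  # emitted positions with full context inside window
    idx <- (ctx[, cols, drop = FALSE] - 1L) * 4L + m[, cols, drop = FALSE]
    counts <- matrix(tabulate(idx, nbins = S * 4L), nrow = S, byrow = TRUE)
    trans[k, , ] <- (counts + pseudocount) /
      (rowSums(counts) + 4 * pseudocount)
    ctx_marg[k, ] <- (rowSums(counts) + pseudocount) /
      (sum(counts) + S * pseudocount)
    for (l in 0:(ord - 1L)) {
      if (l == 0L) {
        cl <- matrix(colSums(counts), nrow = 1L)
      } else {
        grp <- ((seq_len(S) - 1L) %% 4L^l) + 1L  # keep the most recent l letters
        cl <- rowsum(counts, grp)
      }
      fallback[[l + 1L]][k, , ] <- (cl + pseudocount) / (rowSums(cl) + 4 * pseudocount)
    }
  }

  structure(
    list(order = ord, S = S, block_size = as.integer(block_size),
         window_pad_left = as.integer(window_pad_left),
         window_pad_right = as.integer(window_pad_right),
         pseudocount = pseudocount, L = L,
         block_starts = block_starts, col2block = col2block,
         trans = trans, fallback = fallback, ctx_marg = ctx_marg,
         cache = new.env(parent = emptyenv())),
    class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf(
    "<background_model> order-%d Markov, %d blocks of %d column(s) over %d columns (window %d+%d+%d), pseudocount %g\n",
    x$order, length(x$block_starts), x$block_size, x$L,
    x$window_pad_left, x$block_size, x$window_pad_right, x$pseudocount))
  invisible(x)
}

# internal: context codes matrix with L+1 columns; ctx[i, c] codes
# m[i, (c-ord)..(c-1)], oldest letter most significant (so column L+1 holds
# the code of the final ord letters); NA where the context would leave the
# block.
context_codes <- function(m, ord) {
  L <- ncol(m)
  ctx <- matrix(NA_integer_, nrow(m), L + 1L)
  if (L >= ord) {
    cc <- 0L
    for (j in seq_len(ord)) {
      # letters at columns (c-ord) .. (c-1) for c in (ord+1)..(L+1)
      cc <- cc * 4L + (m[, j:(L - ord + j), drop = FALSE] - 1L)
    }
    ctx[, (ord + 1L):(L + 1L)] <- cc + 1L
  }
  ctx
}

# internal: dense transfer matrix T[state, state'] for one block's table;
# cached per (model, blk).
transfer_matrix <- function(model, blk) {
  key <- sprintf("T%d", blk)
  if (!is.null(model$cache[[key]])) return(model$cache[[key]])
  S <- model$S
  Tm <- matrix(0, S, S)
  ns <- next_states(model$order)  # S x 4
  for (b in 1:4) Tm[cbind(seq_len(S), ns[, b])] <- model$trans[blk, , b]
  model$cache[[key]] <- Tm
  Tm
}

# internal: matrix power of the transfer matrix, cached
transfer_power <- function(model, blk, e) {
  if (e == 0L) return(diag(model$S))
  key <- sprintf("T%d^%d", blk, e)
  if (!is.null(model$cache[[key]])) return(model$cache[[key]])
  Tm <- transfer_matrix(model, blk)
  P <- Tm
  if (e > 1L) for (i in 2:e) P <- P %*% Tm
  model$cache[[key]] <- P
  P
}

# internal: next_states[state, base] = state after emitting base
next_states <- function(ord) {
  S <- 4L^ord
  st <- seq_len(S) - 1L
  rest <- st %% 4L^(ord - 1L)
  outer(rest * 4L, 1:4, "+")
}

# internal: one propagation step with a fixed emitted letter.
# v is a mass vector over states; returns the updated mass vector.
step_letter <- function(v, trans_blk, letter, ord) {
  S <- length(v)
  contrib <- v * trans_blk[, letter]
  half <- 4L^(ord - 1L)
  # states sharing the same "recent ord-1 letters" are spaced `half` apart
  agg <- rowSums(matrix(contrib, nrow = half, ncol = 4L))
  v_new <- numeric(S)
  v_new[(seq_len(half) - 1L) * 4L + letter] <- agg
  v_new
}

#' Background log-probability of a candidate site
#'
#' Computes the log-probability of a site's letters under the fitted
#' background model, conditioning on flanking sequence context. Two modes:
#'
#' * `"left"`: the plain Markov chain probability
#'   `log prod_i P(s_i | preceding order-mer)`, seeded by `left_flank`.
#' * `"context2"`: two-sided conditioning
#'   `log P(site | left_flank, right_flank)`; by Bayes' rule this equals
#'   `log P(site | left) + log P(right | last context of site) -
#'    log P(right | left)`, where the denominator marginalizes over all
#'   possible intervening sites by propagating the model's state-transfer
#'   matrix across the site's width. Summed over all `4^w` sites the
#'   conditional probability is exactly 1.
#'
#' Flanks shorter than the model order (at alignment edges) are handled by
#' conditioning on the available letters: the left start measure becomes the
#' window's marginal context distribution restricted to the observed suffix,
#' and a short right flank simply shortens the conditioning.
#'
#' @param model a [fit_background()] model.
#' @param site site letters, a string over {A,C,G,T} (width `w >= 1`).
#' @param left_flank,right_flank flanking letters (strings, up to `order`
#'   letters; possibly shorter or empty at alignment edges).
#' @param mode `"context2"` (default) or `"left"`.
#' @param col3p 0-based alignment column of the site's 3' base, used to pick
#'   the 23-column block whose tables apply. Defaults to the last column.
#' @return A finite negative number (natural log probability).
#' @export
site_log_prob <- function(model, site, left_flank = "", right_flank = "",
                          mode = c("context2", "left"), col3p = NULL) {
  mode <- match.arg(mode)
  s <- str_to_codes(site)
  w <- length(s)
  if (w < 1L) abort("empty site")
  lf <- str_to_codes(left_flank)
  rf <- str_to_codes(right_flank)
  ord <- model$order
  if (length(lf) > ord) lf <- tail(lf, ord)
  if (length(rf) > ord) rf <- head(rf, ord)
  if (is.null(col3p)) col3p <- model$L - 1L
  blk <- model$col2block[col3p + 1L]

  if (mode == "left") {
    return(chain_log_prob(model, blk, c(lf, s), n_context = length(lf)))
  }

  tb <- model$trans[blk, , ]
  v0 <- left_start_measure(model, blk, lf)
  # numerator: mass after emitting site then right letters
  v <- v0
  for (b in s) v <- step_letter(v, tb, b, ord)
  for (b in rf) v <- step_letter(v, tb, b, ord)
  num <- sum(v)
  # denominator: free propagation across the site, then the right letters
  v <- v0 %*% transfer_power(model, blk, w)
  v <- as.numeric(v)
  for (b in rf) v <- step_letter(v, tb, b, ord)
  den <- sum(v)
  log(num) - log(den)
}

# internal: start mass over states given a (possibly short) left flank
left_start_measure <- function(model, blk, lf) {
  S <- model$S
  ord <- model$order
  l <- length(lf)
  if (l == ord) {
    v <- numeric(S)
    v[codes_to_ctx(lf)] <- 1
    return(v)
  }
  pi0 <- model$ctx_marg[blk, ]
  if (l == 0L) return(pi0)
  suff <- 0L
  for (b in lf) suff <- suff * 4L + (b - 1L)
  match_suffix <- ((seq_len(S) - 1L) %% 4L^l) == suff
  v <- ifelse(match_suffix, pi0, 0)
  v / sum(v)
}

# internal: chain probability of letters[(n_context+1)..end] given the first
# n_context letters, with order fallback where context is short
chain_log_prob <- function(model, blk, letters, n_context) {
  ord <- model$order
  lp <- 0
  for (i in (n_context + 1L):length(letters)) {
    avail <- min(ord, i - 1L)
    b <- letters[i]
    if (avail == ord) {
      ctxc <- codes_to_ctx(letters[(i - ord):(i - 1L)])
      lp <- lp + log(model$trans[blk, ctxc, b])
    } else if (avail == 0L) {
      lp <- lp + log(model$fallback[[1L]][blk, 1L, b])
    } else {
      ctxc <- codes_to_ctx(letters[(i - avail):(i - 1L)])
      lp <- lp + log(model$fallback[[avail + 1L]][blk, ctxc, b])
    }
  }
  lp
}

# internal helpers for letter codes
str_to_codes <- function(x) {
  if (length(x) == 1L && is.character(x)) {
    if (nchar(x) == 0L) return(integer(0))
    out <- match(strsplit(toupper(x), "", fixed = TRUE)[[1L]], DNA_BASES4)
    if (anyNA(out)) abort("letters outside {A,C,G,T}")
    return(out)
  }
  as.integer(x)
}

codes_to_ctx <- function(codes) {
  cc <- 0L
  for (b in codes) cc <- cc * 4L + (b - 1L)
  cc + 1L
}

#' Serialize / restore a background model as JSON
#'
#' @param model a [fit_background()] model.
#' @param path file path.
#' @return `write_background_json` invisibly returns `path`;
#'   `read_background_json` returns a `background_model`.
#' @export
write_background_json <- function(model, path) {
  out <- model[c("order", "S", "block_size", "window_pad_left",
                 "window_pad_right", "pseudocount", "L", "block_starts",
                 "col2block")]
  # arrays are stored flattened (column-major) and rebuilt on read
  out$trans <- as.numeric(model$trans)
  out$fallback <- lapply(model$fallback, as.numeric)
  out$ctx_marg <- as.numeric(model$ctx_marg)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_background_json
#' @export
read_background_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$trans <- array(x$trans, dim = c(length(x$block_starts), x$S, 4L))
  x$fallback <- lapply(seq_len(x$order), function(i) {
    array(x$fallback[[i]], dim = c(length(x$block_starts), 4L^(i - 1L), 4L))
  })
  x$ctx_marg <- matrix(x$ctx_marg, nrow = length(x$block_starts))
  for (f in c("order", "S", "block_size", "window_pad_left",
              "window_pad_right", "L", "block_starts", "col2block")) {
    x[[f]] <- as.integer(x[[f]])
  }
  x$cache <- new.env(parent = emptyenv())
  structure(x, class = "background_model")
}
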