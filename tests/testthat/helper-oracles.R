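# Independent oracles used across the suite. These deliberately use naive
# algorithms (enumeration, recursion, direct summation) so they share no
# code with the implementation paths they check.

# All maximal scoring subsequences by recursive extraction: find the
# highest-scoring segment by exhaustive O(n^2) enumeration (shortest, then
# leftmost, among ties), remove it, recurse on both sides.
brute_maximal_segments <- function(d) {
  n <- length(d)
  if (n == 0L) return(data.frame(start = integer(0), end = integer(0), score = numeric(0)))
  best <- NULL
  for (i in seq_len(n)) {
    s <- 0
    for (j in i:n) {
      s <- s + d[j]
      if (s > 0) {
        better <- is.null(best) || s > best$score + 1e-12 ||
          (abs(s - best$score) <= 1e-12 && (j - i) < (best$end - best$start))
        if (better) best <- list(start = i, end = j, score = s)
      }
    }
  }
  if (is.null(best)) return(data.frame(start = integer(0), end = integer(0), score = numeric(0)))
  left <- if (best$start > 1L) brute_maximal_segments(d[1:(best$start - 1L)]) else
    data.frame(start = integer(0), end = integer(0), score = numeric(0))
  right <- if (best$end < n) brute_maximal_segments(d[(best$end + 1L):n]) else
    data.frame(start = integer(0), end = integer(0), score = numeric(0))
  if (nrow(right)) {
    right$start <- right$start + best$end
    right$end <- right$end + best$end
  }
  out <- rbind(left, data.frame(start = best$start, end = best$end, score = best$score), right)
  out[order(out$start), , drop = FALSE]
}

# Right/left hypergeometric tails by direct summation over the support,
# using only choose().
brute_hyper_tails <- function(N, mA, mB, a) {
  support <- max(0L, mA + mB - N):min(mA, mB)
  pmf <- vapply(support, function(k) {
    choose(mA, k) * choose(N - mA, mB - k) / choose(N, mB)
  }, 0)
  c(right = sum(pmf[support >= a]), left = sum(pmf[support <= a]))
}

# Build a promoter block directly from strings (no filtering surprises).
make_block <- function(seqs, genes = sprintf("g%03d", seq_along(seqs)),
                       tss_col = 0L, filter = FALSE) {
  promoter_block(seqs, genes, tss_col = tss_col, filter = filter, quiet = TRUE)
}

# Random DNA string helper.
rand_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                              collapse = "")

# A deterministic small block plus fitted background for reuse.
small_bg_fixture <- function(n_seq = 40, L = 150, tss = 100, seed = 5) {
  b <- generate_background_block(n_seq = n_seq, length = L, tss_col = tss,
                                 seed = seed)
  list(block = b, bg = fit_background(b))
}
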