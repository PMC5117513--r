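test_that("read_jaspar accepts both pfm dialects and validates shape", {
  dir <- withr::local_tempdir()
  bracketed <- file.path(dir, "b.pfm")
  writeLines(c(">M0001 TFX",
               "A [ 4 19 0 ]",
               "C [ 16 0 20 ]",
               "G [ 0 1 0 ]",
               "T [ 0 0 0 ]"), bracketed)
  bare <- file.path(dir, "bare.pfm")
  writeLines(c(">M0001 TFX",
               "4 19 0",
               "16 0 20",
               "0 1 0",
               "0 0 0"), bare)
  m1 <- read_jaspar(bracketed)[[1]]
  m2 <- read_jaspar(bare)[[1]]
  expect_equal(m1$width, 3L)
  expect_identical(unname(m1$counts), unname(m2$counts))
  expect_equal(m1$tf_name, "TFX")

  bad <- file.path(dir, "bad.pfm")
  writeLines(c(">M0002 TFY", "A [ 1 2 3 ]", "C [ 1 2 3 4 ]",
               "G [ 1 2 3 ]", "T [ 1 2 3 ]"), bad)
  expect_error(read_jaspar(bad), "unequal width")

  # shuffled labelled rows are normalized to A,C,G,T order
  shuf <- file.path(dir, "shuf.pfm")
  writeLines(c(">M0001 TFX",
               "T [ 0 0 0 ]",
               "G [ 0 1 0 ]",
               "C [ 16 0 20 ]",
               "A [ 4 19 0 ]"), shuf)
  expect_identical(read_jaspar(shuf)[[1]]$counts, m1$counts)

  # bundled synthetic fixture parses and round-trips through write_jaspar
  fx <- system.file("extdata", "synthetic_motifs.pfm", package = "promclust")
  ms <- read_jaspar(fx)
  expect_equal(length(ms), 3L)
  expect_true(all(vapply(ms, `[[`, 0L, "width") <= 21L))
  out <- file.path(dir, "rt.pfm")
  write_jaspar(ms, out)
  ms2 <- read_jaspar(out)
  expect_equal(lapply(ms2, `[[`, "counts"), lapply(ms, `[[`, "counts"))
})

test_that("counts_to_pssm applies the pseudo-count 0.5 prior exactly", {
  cm <- count_matrix(matrix(c(0, 0, 0, 1,   # col sums 1
                              1, 1, 1, 1,
                              3, 0, 0, 0), 4, 3), tf_name = "T1")
  # a column with a single count of 1: (c + .5)/(1 + 2)
  p <- counts_to_pssm(cm)$prob
  expect_equal(unname(p[, 1]), c(0.5, 0.5, 0.5, 1.5) / 3)
  expect_equal(unname(p[, 2]), rep(0.25, 4))          # symmetric counts
  expect_equal(unname(p[, 3]), c(0.7, 0.1, 0.1, 0.1)) # (3+.5)/5 etc.
  expect_true(all(abs(colSums(p) - 1) < 1e-12))
  expect_true(all(p > 0))
})

test_that("matrix descriptors: symmetry, information limit, palindromes", {
  uni <- count_matrix(matrix(5, 4, 4), tf_name = "UNI")
  d <- matrix_descriptors(uni)
  expect_equal(d$gc_content, 0.5)
  expect_equal(d$information_content_bits, 0, tolerance = 1e-12)
  expect_equal(d$palindromicity, 1)

  # one dominated column: IC tends to 2 bits as counts grow
  strong <- count_matrix(matrix(c(1e6, 0, 0, 0), 4, 1), tf_name = "A1")
  expect_equal(matrix_descriptors(strong)$information_content_bits, 2,
               tolerance = 1e-3)

  # all-A then all-T is exactly self-reverse-complementary
  pal <- count_matrix(matrix(c(9, 0, 0, 0, 0, 0, 0, 9), 4, 2), tf_name = "AT")
  expect_equal(matrix_descriptors(pal)$palindromicity, 1, tolerance = 1e-12)
})

test_that("score_site gives the closed-form log-odds in simple cases", {
  # independent uniform background via an explicit uniform model
  b <- make_block(rep("ACGTACGTACGTACGTACGTACGTACGTACGT", 4),
                  genes = sprintf("g%d", 1:4), tss_col = 16)
  bg <- fit_background(b, block_size = 32, window_pad_left = 0,
                       window_pad_right = 0)
  bg$trans[1, , ] <- 0.25
  for (l in 0:2) bg$fallback[[l + 1]][1, , ] <- 0.25
  bg$ctx_marg[1, ] <- 1 / 64
  bg$cache <- new.env(parent = emptyenv())

  # w = 1, pssm column (0.7, .1, .1, .1), site 'A': log(0.7 / 0.25)
  cm <- count_matrix(matrix(c(3, 0, 0, 0), 4, 1), tf_name = "A1")
  pssm <- counts_to_pssm(cm)
  s <- score_site(pssm, bg, b, seq_index = 1, strand = "+", col3p = 8)
  expect_equal(s, log(0.7 / 0.25), tolerance = 1e-12)

  # motif model equal to background => score 0
  unip <- counts_to_pssm(count_matrix(matrix(1, 4, 3), tf_name = "U3"))
  s0 <- score_site(unip, bg, b, 2, "+", 10)
  expect_equal(s0, 0, tolerance = 1e-12)
})

test_that("palindromic matrices score both strands of a locus identically", {
  fx <- small_bg_fixture(seed = 13)
  # exactly reverse-complement-symmetric counts (ACGT-style palindrome)
  counts <- matrix(c(9, 1, 1, 1,
                     1, 9, 1, 1,
                     1, 1, 9, 1,
                     1, 1, 1, 9), 4, 4)
  pal <- counts_to_pssm(count_matrix(counts, tf_name = "PAL"))
  expect_equal(pal$prob, revcomp_prob(pal$prob), ignore_attr = TRUE)
  # same occupied window: plus 3' base at c, minus 3' base at c - w + 1
  for (c3 in c(30, 77, 120)) {
    sp <- score_site(pal, fx$bg, fx$block, 5, "+", c3)
    sm <- score_site(pal, fx$bg, fx$block, 5, "-", c3 - 3)
    # background block table may differ across the window; scores match when
    # both 3' columns map to the same 23-column block
    if (fx$bg$col2block[c3 + 1] == fx$bg$col2block[c3 - 3 + 1]) {
      expect_equal(sp, sm, tolerance = 1e-10)
    }
  }
})

test_that("scan_block matches score_site site by site (dual route)", {
  fx <- small_bg_fixture(seed = 5)
  pssm <- counts_to_pssm(synthetic_count_matrix(5, dominance = 0.9, seed = 2))
  for (strand in c("+", "-")) {
    cs <- scan_block(fx$block, pssm, fx$bg, strand = strand)
    lookup <- setNames(cs$hits$score,
                       paste(cs$hits$seq_index, cs$hits$col3p))
    withr::with_seed(3, {
      cols <- if (strand == "+") sample(4:149, 30) else sample(0:145, 30)
      iseq <- sample(length(fx$block$sequences), 30, replace = TRUE)
    })
    for (k in seq_along(cols)) {
      s <- score_site(pssm, fx$bg, fx$block, iseq[k], strand, cols[k])
      key <- paste(iseq[k], cols[k])
      if (s > 1e-12) {
        expect_equal(unname(lookup[key]), s, tolerance = 1e-9)
      } else {
        expect_false(key %in% names(lookup))
      }
    }
  }
})

test_that("column policies aggregate as defined and x stays nonnegative", {
  fx <- small_bg_fixture(seed = 21)
  pssm <- counts_to_pssm(synthetic_count_matrix(4, dominance = 0.9, seed = 9))
  cs_pos <- scan_block(fx$block, pssm, fx$bg, "+", "positive_sum")
  cs_clamp <- scan_block(fx$block, pssm, fx$bg, "+", "clamped_total")
  expect_true(all(cs_pos$x >= 0))
  expect_true(all(cs_clamp$x >= 0))
  # positive_sum at each column equals the sum of that column's hit scores
  agg <- tapply(cs_pos$hits$score, cs_pos$hits$col3p, sum)
  expect_equal(unname(cs_pos$x[as.integer(names(agg)) + 1L]),
               as.numeric(agg), tolerance = 1e-12)
  # clamping can only lower a column's aggregate
  expect_true(all(cs_clamp$x <= cs_pos$x + 1e-9))
  expect_error(scan_block(fx$block, pssm, fx$bg, "+", "bogus"))
})

test_that("strand symmetry: scanning the reverse-complemented block mirrors hits", {
  fx <- small_bg_fixture(n_seq = 25, L = 90, tss = 45, seed = 17)
  pssm <- counts_to_pssm(synthetic_count_matrix(5, dominance = 0.9, seed = 4))
  L <- fx$block$L
  rc <- chartr("ACGT", "TGCA", vapply(fx$block$sequences, function(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), ""))
  brc <- promoter_block(unname(rc), fx$block$gene_ids, tss_col = L - 1L - fx$block$tss_col,
                        filter = FALSE)
  # an exactly strand-symmetric background isolates the scanner's strand
  # logic (a refitted model is only approximately reversible)
  uniformize <- function(bg) {
    bg$trans[] <- 0.25
    for (l in seq_along(bg$fallback)) bg$fallback[[l]][] <- 0.25
    bg$ctx_marg[] <- 1 / 64
    bg$cache <- new.env(parent = emptyenv())
    bg
  }
  bg_f <- uniformize(fit_background(fx$block, block_size = L,
                                    window_pad_left = 0, window_pad_right = 0))
  bg_r <- uniformize(fit_background(brc, block_size = L,
                                    window_pad_left = 0, window_pad_right = 0))
  h_minus <- scan_block(fx$block, pssm, bg_f, "-")$hits
  h_plus_rc <- scan_block(brc, pssm, bg_r, "+")$hits
  # a minus-strand motif at plus column c maps to column L-1-c of the
  # reverse-complemented block (3' base flips ends of the window)
  expect_equal(nrow(h_minus), nrow(h_plus_rc))
  key1 <- sort(paste(h_minus$seq_index, L - 1L - h_minus$col3p - (pssm$width - 1L),
                     round(h_minus$score, 6)))
  key2 <- sort(paste(h_plus_rc$seq_index, h_plus_rc$col3p - (pssm$width - 1L),
                     round(h_plus_rc$score, 6)))
  expect_equal(key1, key2)
})

test_that("hits are equivariant under sequence order permutation", {
  fx <- small_bg_fixture(n_seq = 20, L = 80, tss = 40, seed = 23)
  pssm <- counts_to_pssm(synthetic_count_matrix(4, dominance = 0.9, seed = 5))
  cs <- scan_block(fx$block, pssm, fx$bg, "+")
  withr::with_seed(1, perm <- sample(20))
  bp <- promoter_block(fx$block$sequences[perm], fx$block$gene_ids[perm],
                       tss_col = 40, filter = FALSE)
  csp <- scan_block(bp, pssm, fit_background(bp), "+")
  expect_equal(csp$x, cs$x, tolerance = 1e-9)
  expect_equal(nrow(csp$hits), nrow(cs$hits))
  # map permuted indices back and compare hit sets
  k1 <- sort(paste(perm[csp$hits$seq_index], csp$hits$col3p,
                   round(csp$hits$score, 6)))
  k2 <- sort(paste(cs$hits$seq_index, cs$hits$col3p, round(cs$hits$score, 6)))
  expect_equal(k1, k2)
})

test_that("a planted column dominates the column scores", {
  withr::with_seed(31, {
    seqs <- replicate(100, rand_seq(200))
  })
  b <- promoter_block(seqs, sprintf("g%d", 1:100), tss_col = 100, quiet = TRUE)
  cm <- synthetic_count_matrix(6, dominance = 0.95, seed = 7)
  spec <- rm_spec(list(list(cm = cm, strand = "+", offset_bp = 20)),
                  carrier_fraction = 0.5)
  study <- plant_rm(b, spec, seed = 8)
  bg <- fit_background(study$block)
  cs <- scan_block(study$block, counts_to_pssm(cm), bg, "+")
  planted_col <- coord_to_col(20, study$block)
  expect_equal(which.max(cs$x) - 1L, planted_col)
})

test_that("hit export writes half-open plus-strand BED-like intervals", {
  fx <- small_bg_fixture(n_seq = 10, L = 60, tss = 30, seed = 41)
  pssm <- counts_to_pssm(synthetic_count_matrix(4, dominance = 0.9, seed = 42))
  cs_p <- scan_block(fx$block, pssm, fx$bg, "+")
  cs_m <- scan_block(fx$block, pssm, fx$bg, "-")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits_bed(list(cs_p, cs_m), path)
  bed <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(bed), nrow(cs_p$hits) + nrow(cs_m$hits))
  expect_true(all(bed$end - bed$start == 4))
  expect_true(all(bed$start >= 0 & bed$end <= 60))
  # plus-strand rows end just past the 3' base; minus-strand rows start at it
  plus <- bed[bed$strand == "+", ]
  expect_equal(sort(plus$end - 1L), sort(cs_p$hits$col3p))
  minus <- bed[bed$strand == "-", ]
  expect_equal(sort(minus$start), sort(cs_m$hits$col3p))
})
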