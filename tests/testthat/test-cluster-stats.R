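test_that("gap penalty normalizes by the mean column score", {
  expect_equal(gap_penalty(c(1, 1, 1, 1), 1.4), 1.4)
  x <- c(0, 2, 5, 1)
  expect_equal(gap_penalty(x, 1), mean(x))
  expect_equal(gap_penalty(3 * x, 1.4), 3 * gap_penalty(x, 1.4))
  expect_error(gap_penalty(numeric(4), 1.4), "zero")
  expect_error(gap_penalty(c(-1, 2), 1.4), "nonnegative")
})

test_that("ruzzo_tompa handles joins, ties, and empty results", {
  # the join [1,4] scores 4 - 1 - 1 + 3 = 5 > either part, so the parts merge
  rt <- ruzzo_tompa(c(5, 0, 0, 4), 1)
  expect_equal(rt$start, 1L)
  expect_equal(rt$end, 4L)
  expect_equal(rt$score, 5)
  # with one more zero the join only ties the best part: parts stay separate
  rt2 <- ruzzo_tompa(c(5, 0, 0, 0, 4), 1)
  expect_equal(rt2$start, c(1L, 5L))
  expect_equal(rt2$score, c(4, 3))
  # interior run
  rt3 <- ruzzo_tompa(c(0, 3, 3, 0), 1)
  expect_equal(rt3[, c("start", "end")], tibble::tibble(start = 2L, end = 3L))
  expect_equal(rt3$score, 4)
  # nothing above the penalty
  expect_equal(nrow(ruzzo_tompa(c(0.5, 0.9, 0), 1)), 0L)
})

test_that("ruzzo_tompa equals brute-force recursive extraction on random cases", {
  withr::with_seed(404, {
    for (case in 1:500) {
      n <- sample(1:50, 1)
      # mix continuous and small-integer scores so ties actually occur
      x <- if (case %% 2 == 0) round(runif(n, 0, 4)) else runif(n, 0, 4)
      g <- if (case %% 3 == 0) 1 else runif(1, 0.5, 2)
      got <- ruzzo_tompa(x, g)
      want <- brute_maximal_segments(x - g)
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$score, want$score, tolerance = 1e-10)
      # segment scores recompute independently from the definition
      if (nrow(got)) {
        resum <- mapply(function(s, e) sum(x[s:e] - g), got$start, got$end)
        expect_equal(got$score, unname(resum), tolerance = 1e-10)
      }
    }
  })
})

test_that("karlin_lambda recovers the two-point closed form and scales", {
  # x - g in {+1 w.p. 1/4, -1 w.p. 3/4}: lambda = ln 3
  x <- c(rep(2, 25), rep(0, 75))
  kp <- karlin_lambda(x, g = 1)
  expect_equal(kp$lambda, log(3), tolerance = 1e-9)
  expect_lt(abs(mean(exp(kp$lambda * (x - 1))) - 1), 1e-9)
  # p = 0.1 variant
  x2 <- c(rep(2, 10), rep(0, 90))
  expect_equal(karlin_lambda(x2, 1)$lambda, log(9), tolerance = 1e-9)
  # doubling the penalized scores halves lambda
  expect_equal(karlin_lambda(2 * x, 2)$lambda, log(3) / 2, tolerance = 1e-9)
  # regime violations are named errors
  expect_error(karlin_lambda(c(2, 2, 0, 0), 1), "logarithmic")
  expect_error(karlin_lambda(c(1, 1, 1, 1), 2), "logarithmic|lambda undefined")
})

test_that("cluster p-values follow the Karlin-Altschul closed form", {
  kp <- structure(list(lambda = 2, n = 100L, g = 1), class = "karlin_params")
  # K n exp(-lambda s) = ln 2  =>  p = 1/2
  s_half <- (log(100) - log(log(2))) / 2
  expect_equal(cluster_pvalue(s_half, kp), 0.5, tolerance = 1e-12)
  # monotone decreasing, limits
  ss <- seq(0.5, 200, length.out = 50)
  ps <- cluster_pvalue(ss, kp)
  expect_true(all(diff(ps) <= 0))
  expect_lt(cluster_pvalue(500, kp), 1e-300)
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("permutation p-value follows the add-one rule and edge cases", {
  fx <- small_bg_fixture(seed = 19)
  pssm <- counts_to_pssm(synthetic_count_matrix(4, dominance = 0.9, seed = 6))
  cs <- scan_block(fx$block, pssm, fx$bg, "+")
  g <- gap_penalty(cs$x)
  # observed score far above anything achievable: p = 1/(n_perm + 1)
  expect_equal(permutation_pvalue(cs, g, 1e6, n_perm = 99, seed = 1), 1 / 100)
  # zero observed score: every replicate ties or exceeds
  expect_equal(permutation_pvalue(cs, g, 0, n_perm = 9, seed = 1), 1)
  # reproducible under the same seed, different under another
  p1 <- permutation_pvalue(cs, g, 20, n_perm = 49, seed = 7)
  p2 <- permutation_pvalue(cs, g, 20, n_perm = 49, seed = 7)
  expect_identical(p1, p2)
  # no hits: p = 1
  empty <- cs
  empty$hits <- cs$hits[0, ]
  expect_equal(permutation_pvalue(empty, g, 5, n_perm = 9, seed = 1), 1)
})

test_that("permutation and Karlin p-values rank candidate segments alike", {
  # a batch of simulated datasets with graded planted signal so both
  # p-values spread over their full ranges
  cm <- synthetic_count_matrix(5, dominance = 0.95, seed = 3)
  fracs <- c(0.01, 0.02, 0.04, 0.06, 0.1, 0.15, 0.22, 0.3)
  p_k <- numeric(length(fracs)); p_p <- numeric(length(fracs))
  for (i in seq_along(fracs)) {
    b <- generate_background_block(n_seq = 80, length = 250, tss_col = 150,
                                   seed = 600 + i)
    spec <- rm_spec(list(list(cm = cm, strand = "+", offset_bp = 9)),
                    carrier_fraction = fracs[i])
    study <- plant_rm(b, spec, seed = 700 + i)
    bg <- fit_background(study$block)
    cs <- scan_block(study$block, counts_to_pssm(cm), bg, "+")
    cl <- find_clusters(cs, study$block)
    p_k[i] <- min(cl$p_value)
    best <- max(cl$score)
    p_p[i] <- permutation_pvalue(cs, attr(cl, "g"), best, n_perm = 199,
                                 seed = 800 + i)
  }
  expect_gte(suppressWarnings(cor(p_k, p_p, method = "spearman")), 0.9)
})

test_that("describe_cluster computes spread and multiple motifs as defined", {
  map <- list(tss_col = 100L, L = 300L)
  hits <- tibble::tibble(seq_index = c(1L, 1L, 1L, 2L, 3L),
                         col3p = c(50L, 51L, 52L, 50L, 52L),
                         score = c(1, 1, 1, 1, 1))
  seg <- list(start = 51L, end = 53L, score = 4.2)
  d <- describe_cluster(seg, hits, map)
  # sequence 1 contributes three motifs: two of them are "multiple"
  expect_equal(d$n_hits, 5L)
  expect_equal(d$pct_multiple_motifs, 2 / 5)
  expect_equal(d$From, col_to_coord(50L, map))
  expect_equal(d$To, col_to_coord(52L, map))
  expect_equal(d$spread, 3L)
  # one sequence with 3 hits alone: 2 multiple motifs, fraction 2/3
  d1 <- describe_cluster(seg, hits[hits$seq_index == 1L, ], map)
  expect_equal(d1$pct_multiple_motifs, 2 / 3)
  # every sequence at most one hit: fraction 0
  d0 <- describe_cluster(seg, hits[c(4, 5), ], map)
  expect_equal(d0$pct_multiple_motifs, 0)
  # spread arithmetic on reported coordinates: -78..-36 spans 43 columns
  expect_equal(-36 - -78 + 1, 43)
  seg2 <- list(start = coord_to_col(-78, map) + 1L,
               end = coord_to_col(-36, map) + 1L, score = 1)
  expect_equal(describe_cluster(seg2, hits[0, ], map)$spread, 43L)
})

test_that("find_clusters assembles keys, gene groups, and masked lambda", {
  withr::with_seed(55, seqs <- replicate(120, rand_seq(300)))
  b <- promoter_block(seqs, rep(sprintf("g%03d", 1:60), each = 2),
                      tss_col = 150, quiet = TRUE)
  cm <- synthetic_count_matrix(6, dominance = 0.95, seed = 14)
  spec <- rm_spec(list(list(cm = cm, strand = "+", offset_bp = -30)),
                  carrier_fraction = 0.5)
  study <- plant_rm(b, spec, seed = 15)
  bg <- fit_background(study$block)
  cs <- scan_block(study$block, counts_to_pssm(cm), bg, "+")
  cl <- find_clusters(cs, study$block)
  expect_s3_class(cl, "cluster_set")
  top <- cl[1, ]
  planted_col <- coord_to_col(-30, study$block)
  expect_true(top$start - 1L <= planted_col && planted_col <= top$end - 1L)
  expect_lt(top$p_value, 1e-10)
  # cluster key round-trips through the naming grammar
  parsed <- parse_cluster_key(top$cluster_key)
  expect_equal(parsed$tf_name, top$tf_name)
  expect_equal(parsed$From, top$From)
  expect_equal(parsed$To, top$To)
  expect_equal(parsed$strand, top$strand)
  # gene group contains most carriers (sampled sites can miss)
  expect_gt(length(intersect(top$genes[[1]], study$carriers)),
            0.8 * length(study$carriers))
  # masked lambda reported via glance
  gl <- glance(cl)
  expect_equal(gl$n_clusters, nrow(cl))
  expect_gt(gl$lambda, 0)
})
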