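#' Synthetic promoter blocks with known truth
#'
#' Generators emulating the structure of a TSS-anchored promoter database:
#' fixed-length sequences over {A,C,G,T}, many-to-one sequence-to-gene
#' mapping (promoter databases are redundant), position-varying
#' composition, and optionally planted regulatory-module sites at fixed
#' offsets from the TSS. All generators are deterministic given their seed.
#'
#' `generate_background_block()` draws signal-free sequences from an
#' order-3 Markov chain (uniform i.i.d. by default, the "random database"
#' negative control). With `gc_gradient > 0` the G+C propensity increases
#' linearly toward the TSS column, emulating GC-rich proximal promoters.
#'
#' @param n_seq number of sequences (ignored when `n_genes` is given).
#' @param length sequence length in bp (default 3001).
#' @param tss_col 0-based TSS column (default 2000).
#' @param trans optional 64 x 4 order-3 transition matrix (rows: contexts,
#'   oldest letter most significant; columns A,C,G,T). `NULL` = uniform.
#' @param gc_gradient number in `[0, 1)`: maximal admixture weight, at the
#'   TSS column, of a GC-rich base distribution (0 disables the gradient).
#' @param n_genes if given, genes are emitted with `sample(dup_range)`
#'   duplicate sequences each (independent backgrounds), emulating
#'   database redundancy; otherwise one gene per sequence.
#' @param dup_range integer vector of possible duplicates per gene.
#' @param seed integer seed.
#' @return A [promoter_block()].
#' @export
generate_background_block <- function(n_seq = 100L, length = 3001L,
                                      tss_col = 2000L, trans = NULL,
                                      gc_gradient = 0, n_genes = NULL,
                                      dup_range = 1:5, seed = 1L) {
  L <- as.integer(length)
  stopifnot(L >= 50L, gc_gradient >= 0, gc_gradient < 1)
  if (!is.null(trans)) {
    trans <- as.matrix(trans)
    if (!identical(dim(trans), c(64L, 4L)) || any(trans < 0) ||
        any(abs(rowSums(trans) - 1) > 1e-8)) {
      abort("trans must be a 64 x 4 stochastic matrix")
    }
  }
  withr::with_seed(seed, {
    if (!is.null(n_genes)) {
      k <- sample(dup_range, n_genes, replace = TRUE)
      gene_ids <- rep(sprintf("g%05d", seq_len(n_genes)), times = k)
      n <- sum(k)
    } else {
      n <- as.integer(n_seq)
      gene_ids <- sprintf("g%05d", seq_len(n))
    }
    m <- sample_markov_block(n, L, trans, gc_gradient, tss_col)
    promoter_block(decode_rows(m), gene_ids, tss_col = tss_col, quiet = TRUE)
  })
}

# internal: sample n x L integer base matrix from the order-3 chain
sample_markov_block <- function(n, L, trans, gc_gradient, tss_col) {
  gc_dist <- c(0.1, 0.4, 0.4, 0.1)
  alpha <- if (gc_gradient > 0) {
    dist <- abs((0:(L - 1L)) - tss_col)
    gc_gradient * (1 - dist / max(dist))
  } else {
    numeric(L)
  }
  m <- matrix(0L, n, L)
  if (is.null(trans)) {
    base_probs <- matrix(0.25, 1L, 4L)
    for (c in seq_len(L)) {
      p <- (1 - alpha[c]) * base_probs[1L, ] + alpha[c] * gc_dist
      m[, c] <- sample.int(4L, n, replace = TRUE, prob = p)
    }
    return(m)
  }
  marg <- colSums(trans) / sum(trans)
  for (c in 1:3) {
    p0 <- (1 - alpha[c]) * marg + alpha[c] * gc_dist
    m[, c] <- sample.int(4L, n, replace = TRUE, prob = p0)
  }
  state <- (m[, 1L] - 1L) * 16L + (m[, 2L] - 1L) * 4L + m[, 3L]
  for (c in 4:L) {
    p <- trans[state, , drop = FALSE]
    if (alpha[c] > 0) p <- (1 - alpha[c]) * p + alpha[c] * rep(gc_dist, each = n)
    cp <- p[, 1L] + p[, 2L]
    cp2 <- cp + p[, 3L]
    tot <- cp2 + p[, 4L]
    u <- runif(n) * tot
    b <- 1L + (u > p[, 1L]) + (u > cp) + (u > cp2)
    m[, c] <- b
    state <- (state - 1L) %% 16L * 4L + b
  }
  m
}

#' Specify a regulatory module to plant
#'
#' A regulatory module (RM) is a set of binding sites with tight relative
#' positioning: each member is a count matrix placed on a strand with its
#' 3' base at a fixed signed offset from the TSS.
#'
#' @param members list of members, each a list with `cm` (a
#'   [count_matrix()]), `strand` (`"+"`/`"-"`) and `offset_bp` (signed,
#'   nonzero 3'-base coordinate).
#' @param carrier_fraction fraction of genes carrying the module, in (0,1].
#' @param offset_jitter_sd per-gene Gaussian positional noise in bp
#'   (default 0).
#' @return An `rm_spec` object.
#' @export
rm_spec <- function(members, carrier_fraction = 0.3, offset_jitter_sd = 0) {
  stopifnot(carrier_fraction > 0, carrier_fraction <= 1, offset_jitter_sd >= 0)
  for (mem in members) {
    if (!inherits(mem$cm, "count_matrix")) abort("each member needs a count_matrix `cm`")
    if (!mem$strand %in% c("+", "-")) abort("member strand must be '+' or '-'")
    if (mem$offset_bp == 0) abort("offsets use TSS coordinates: 0 does not exist")
  }
  structure(list(members = members, carrier_fraction = carrier_fraction,
                 offset_jitter_sd = offset_jitter_sd),
            class = "rm_spec")
}

#' Plant a regulatory module into a promoter block
#'
#' For each carrier gene, each module member's site is sampled column-wise
#' from the member's pseudocounted probability matrix (so planted sites
#' carry realistic within-motif variability and scanning can miss
#' weak draws), reverse-complemented for minus-strand members, and written
#' at the member's offset (plus per-gene jitter) into *all* of the gene's
#' sequences -- duplicates represent the same promoter, so they share the
#' planted site. Every write is recorded in the truth table.
#'
#' @param block a [promoter_block()].
#' @param spec an [rm_spec()].
#' @param gene_assignment optional character vector of carrier gene ids;
#'   by default carriers are sampled without replacement.
#' @param seed integer seed.
#' @param pseudocount passed to [counts_to_pssm()] when sampling sites.
#' @return A `synthetic_study`: list with `block` (sites written in),
#'   `truth` (tibble: `gene`, `seq_index`, `tf_name`, `strand`, `col3p`,
#'   `coord`, `site`), `spec`, `carriers`, `seed`.
#' @export
plant_rm <- function(block, spec, gene_assignment = NULL, seed = 1L,
                     pseudocount = 0.5) {
  stopifnot(inherits(spec, "rm_spec"))
  m <- encode_block(block)
  L <- block$L
  genes <- unique(block$gene_ids)
  withr::with_seed(seed, {
    carriers <- gene_assignment %||%
      sample(genes, max(1L, round(spec$carrier_fraction * length(genes))))
    if (!all(carriers %in% genes)) abort("gene_assignment contains unknown genes")
    pssms <- lapply(spec$members, function(mem) counts_to_pssm(mem$cm, pseudocount))
    truth <- list()
    for (gene in carriers) {
      rows <- which(block$gene_ids == gene)
      occupied <- matrix(integer(0), nrow = 0L, ncol = 2L)
      for (j in seq_along(spec$members)) {
        mem <- spec$members[[j]]
        p <- pssms[[j]]$prob
        w <- ncol(p)
        off <- mem$offset_bp
        if (spec$offset_jitter_sd > 0) {
          off <- off + as.integer(round(rnorm(1, 0, spec$offset_jitter_sd)))
          if (off == 0L) off <- if (mem$offset_bp > 0) 1L else -1L
        }
        col3p <- coord_to_col(off, block)
        site <- vapply(seq_len(w), function(jj) {
          sample.int(4L, 1L, prob = p[, jj])
        }, 0L)
        if (mem$strand == "+") {
          cols <- (col3p - w + 1L):col3p
          plus_letters <- site
        } else {
          cols <- col3p:(col3p + w - 1L)
          plus_letters <- COMP4[rev(site)]
        }
        if (cols[1L] < 0L || cols[length(cols)] > L - 1L) {
          abort("planted site does not fit inside the block")
        }
        if (nrow(occupied) &&
            any(cols[1L] <= occupied[, 2L] & cols[length(cols)] >= occupied[, 1L])) {
          abort("planted regulatory-module sites overlap within one sequence")
        }
        occupied <- rbind(occupied, c(cols[1L], cols[length(cols)]))
        m[rows, cols + 1L] <- rep(plus_letters, each = length(rows))
        truth[[length(truth) + 1L]] <- tibble(
          gene = gene, seq_index = rows,
          tf_name = pssms[[j]]$tf_name, strand = mem$strand,
          col3p = col3p, coord = off,
          site = paste(DNA_BASES4[site], collapse = ""))
      }
    }
    out_block <- promoter_block(decode_rows(m), block$gene_ids,
                                tss_col = block$tss_col, filter = FALSE)
    structure(list(block = out_block, truth = dplyr::bind_rows(truth),
                   spec = spec, carriers = sort(carriers), seed = seed),
              class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d planted site(s) in %d carrier gene(s); seed %d\n",
              nrow(x$truth), length(x$carriers), x$seed))
  print(x$block)
  invisible(x)
}

#' Negative control: random database with offsets
#'
#' Promoter databases contain overlapping sequences (many sequences per
#' gene); p-values could in principle be deflated by that overlap alone.
#' This control reproduces the overlap structure without signal: for each
#' gene, one random source string is drawn and each of the gene's
#' sequences is an offset copy of it (offsets drawn from `offset_law`,
#' default uniform on ±`offset_max` bp).
#'
#' @param block a [promoter_block()] whose gene structure to copy.
#' @param offset_max maximal absolute offset in bp (default 500).
#' @param offset_law optional `function(k)` returning `k` integer offsets.
#' @param seed integer seed.
#' @return A [promoter_block()] (replicate copies produced by zero offsets
#'   are removed by the standard filter).
#' @export
generate_random_with_offsets <- function(block, offset_max = 500L,
                                         offset_law = NULL, seed = 1L) {
  L <- block$L
  law <- offset_law %||% (function(k) sample.int(2L * offset_max + 1L, k,
                                                 replace = TRUE) - offset_max - 1L)
  withr::with_seed(seed, {
    genes <- unique(block$gene_ids)
    seqs <- character(length(block$gene_ids))
    for (gene in genes) {
      rows <- which(block$gene_ids == gene)
      src <- sample.int(4L, L + 2L * offset_max, replace = TRUE)
      offs <- law(length(rows))
      if (any(abs(offs) > offset_max)) abort("offset law exceeded offset_max")
      for (i in seq_along(rows)) {
        a <- offset_max + 1L + offs[i]
        seqs[rows[i]] <- paste(DNA_BASES4[src[a:(a + L - 1L)]], collapse = "")
      }
    }
    promoter_block(seqs, block$gene_ids, tss_col = block$tss_col, quiet = TRUE)
  })
}

#' Synthetic count matrix with controllable information content
#'
#' Draws a random consensus and multinomial counts concentrated on it:
#' `dominance` is the expected probability mass of the consensus base per
#' column, so information content per column approaches
#' `2 + dominance*log2(dominance) + (1-dominance)*log2((1-dominance)/3)`
#' bits for large `n_sites`.
#'
#' @param width motif width.
#' @param dominance consensus base probability per column, in (0.25, 1).
#' @param n_sites number of sites behind the counts (default 100).
#' @param tf_name matrix name.
#' @param seed integer seed.
#' @return A [count_matrix()].
#' @export
synthetic_count_matrix <- function(width, dominance = 0.9, n_sites = 100L,
                                   tf_name = "SYN", seed = 1L) {
  stopifnot(width >= 1L, dominance > 0.25, dominance < 1)
  withr::with_seed(seed, {
    consensus <- sample.int(4L, width, replace = TRUE)
    counts <- vapply(seq_len(width), function(j) {
      p <- rep((1 - dominance) / 3, 4L)
      p[consensus[j]] <- dominance
      as.numeric(stats::rmultinom(1L, n_sites, p))
    }, numeric(4L))
    count_matrix(counts, tf_name = tf_name,
                 matrix_id = sprintf("%s_w%d", tf_name, width))
  })
}

#' Write a synthetic study to disk
#'
#' Writes `<dir>/block.fasta`, `<dir>/block.tsv` (record/gene metadata)
#' and `<dir>/truth.tsv` (the planted-site records).
#'
#' @param study a [plant_rm()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- write_promoter_block(study$block, file.path(dir, "block"))
  truth_path <- file.path(dir, "truth.tsv")
  readr::write_tsv(study$truth, truth_path)
  invisible(c(paths, truth_path))
}

#' Build a synthetic study from a YAML config
#'
#' Reads a YAML file describing the background block and the regulatory
#' module to plant, and generates the study. Recognized keys:
#' `n_genes` (or `n_seq`), `length`, `tss_col`, `dup_min`/`dup_max`,
#' `gc_gradient`, `seed`, `carrier_fraction`, `offset_jitter_sd`, and a
#' `members` list whose entries have `width`, `dominance`, `strand`,
#' `offset_bp` and optionally `tf_name`.
#'
#' @param path YAML file.
#' @return A `synthetic_study` (see [plant_rm()]).
#' @export
study_from_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("the yaml package is required to read study configs")
  }
  cfg <- yaml::read_yaml(path)
  seed <- as.integer(cfg$seed %||% 1L)
  block <- generate_background_block(
    n_seq = cfg$n_seq %||% 100L,
    length = cfg$length %||% 3001L,
    tss_col = cfg$tss_col %||% 2000L,
    gc_gradient = cfg$gc_gradient %||% 0,
    n_genes = cfg$n_genes,
    dup_range = (cfg$dup_min %||% 1L):(cfg$dup_max %||% 5L),
    seed = seed)
  members <- lapply(seq_along(cfg$members), function(i) {
    m <- cfg$members[[i]]
    list(cm = synthetic_count_matrix(
           width = m$width,
           dominance = m$dominance %||% 0.9,
           tf_name = m$tf_name %||% sprintf("RM%d", i),
           seed = seed + i),
         strand = m$strand %||% "+",
         offset_bp = m$offset_bp)
  })
  spec <- rm_spec(members,
                  carrier_fraction = cfg$carrier_fraction %||% 0.3,
                  offset_jitter_sd = cfg$offset_jitter_sd %||% 0)
  plant_rm(block, spec, seed = seed + 1000L)
}
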