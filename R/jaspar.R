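#' Read JASPAR-style count matrices
#'
#' Parses transcription-factor binding-site count matrices in JASPAR pfm
#' format. Both common dialects are accepted: the bracketed form
#' (`A [ 4 19 0 ]`) and the bare four-row form (one whitespace-separated
#' count row per base). Headers are `>matrix_id name`; when base labels are
#' present the rows are normalized to A, C, G, T order, otherwise the four
#' rows are taken in that order.
#'
#' @param pfm_source path to a pfm file (one or more records).
#' @return A named list of `count_matrix` objects (named by TF name), each a
#'   list with fields `tf_name`, `matrix_id`, `counts` (4 x w numeric matrix,
#'   rows A,C,G,T) and `width`.
#' @export
read_jaspar <- function(pfm_source) {
  lines <- readLines(pfm_source, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (length(starts) == 0L) abort("no '>' headers found in pfm input")
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- lapply(seq_along(starts), function(i) {
    header <- sub("^>\\s*", "", lines[starts[i]])
    toks <- strsplit(header, "\\s+")[[1L]]
    matrix_id <- toks[1L]
    tf_name <- if (length(toks) >= 2L) paste(toks[-1L], collapse = "_") else toks[1L]
    body <- lines[(starts[i] + 1L):ends[i]]
    if (length(body) != 4L) {
      abort(sprintf("record '%s': expected 4 count rows, found %d",
                    matrix_id, length(body)))
    }
    labelled <- grepl("^[ACGTacgt]\\b|^[ACGTacgt]\\s*\\[", body)
    rows <- lapply(body, function(ln) {
      lab <- NA_character_
      if (grepl("^[ACGTacgt]", ln)) {
        lab <- toupper(substr(ln, 1L, 1L))
        ln <- sub("^[ACGTacgt]", "", ln)
      }
      ln <- gsub("[][]", " ", ln)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1L]]))
      if (anyNA(vals)) abort(sprintf("record '%s': malformed count row", matrix_id))
      list(lab = lab, vals = vals)
    })
    widths <- lengths(lapply(rows, `[[`, "vals"))
    if (length(unique(widths)) != 1L) {
      abort(sprintf("record '%s': count rows of unequal width", matrix_id))
    }
    counts <- do.call(rbind, lapply(rows, `[[`, "vals"))
    labs <- vapply(rows, `[[`, "", "lab")
    if (all(!is.na(labs))) {
      if (!setequal(labs, DNA_BASES4)) {
        abort(sprintf("record '%s': missing base row (saw %s)",
                      matrix_id, paste(labs, collapse = ",")))
      }
      counts <- counts[match(DNA_BASES4, labs), , drop = FALSE]
    } else if (any(!is.na(labs))) {
      abort(sprintf("record '%s': mixed labelled/unlabelled rows", matrix_id))
    }
    count_matrix(counts, tf_name = tf_name, matrix_id = matrix_id)
  })
  names(out) <- vapply(out, `[[`, "", "tf_name")
  out
}

#' Construct a count matrix
#'
#' @param counts 4 x w nonnegative numeric matrix, rows in A,C,G,T order.
#' @param tf_name,matrix_id identifiers.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, tf_name = "TF", matrix_id = tf_name) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) abort("count matrix must have 4 rows (A,C,G,T)")
  if (ncol(counts) < 1L) abort("count matrix must have width >= 1")
  if (any(counts < 0)) abort("negative counts")
  if (any(colSums(counts) <= 0)) abort("every column needs a positive count")
  rownames(counts) <- DNA_BASES4
  structure(list(tf_name = tf_name, matrix_id = matrix_id,
                 counts = counts, width = ncol(counts)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %s (%s), width %d\n", x$tf_name, x$matrix_id, x$width))
  print(x$counts)
  invisible(x)
}

#' Convert counts to a position-specific probability matrix
#'
#' Applies a symmetric Dirichlet prior: each probability is
#' `(count + pseudocount) / (column total + 4 * pseudocount)`, so every
#' column sums to 1 and all entries are strictly positive.
#'
#' @param cm a [count_matrix()].
#' @param pseudocount per-nucleotide pseudocount (default 0.5).
#' @return A `pssm` object: fields `tf_name`, `matrix_id`, `prob` (4 x w),
#'   `log_prob`, `width`, `pseudocount`.
#' @export
counts_to_pssm <- function(cm, pseudocount = 0.5) {
  p <- sweep(cm$counts + pseudocount, 2L, colSums(cm$counts) + 4 * pseudocount, "/")
  structure(list(tf_name = cm$tf_name, matrix_id = cm$matrix_id,
                 prob = p, log_prob = log(p), width = ncol(p),
                 pseudocount = pseudocount),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm> %s, width %d (pseudocount %g)\n", x$tf_name, x$width, x$pseudocount))
  print(round(x$prob, 3))
  invisible(x)
}

# internal: reverse-complemented probability matrix (4 x w)
revcomp_prob <- function(p) {
  p[COMP4, rev(seq_len(ncol(p))), drop = FALSE]
}

#' Summary descriptors of a count matrix
#'
#' Computes, from the pseudocounted probability matrix:
#' * `gc_content`: mean per-column probability of G or C;
#' * `information_content_bits`: total information content,
#'   `sum_j (2 + sum_b p log2 p)`;
#' * `palindromicity`: Pearson correlation between the flattened
#'   probability matrix and its reverse complement (1 for perfectly
#'   reverse-palindromic motifs).
#'
#' @param cm a [count_matrix()].
#' @param pseudocount passed to [counts_to_pssm()].
#' @return A one-row tibble with `tf_name`, `width`, `gc_content`,
#'   `information_content_bits`, `palindromicity`.
#' @export
matrix_descriptors <- function(cm, pseudocount = 0.5) {
  p <- counts_to_pssm(cm, pseudocount)$prob
  gc <- mean(p["C", ] + p["G", ])
  ic <- sum(2 + colSums(p * log2(p)))
  rc <- revcomp_prob(p)
  pal <- if (stats::sd(as.numeric(p)) == 0) 1 else
    stats::cor(as.numeric(p), as.numeric(rc))
  tibble(tf_name = cm$tf_name, width = cm$width, gc_content = gc,
         information_content_bits = ic, palindromicity = pal)
}

#' Write count matrices in JASPAR pfm format (bracketed dialect)
#'
#' @param matrices list of [count_matrix()] objects.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_jaspar <- function(matrices, path) {
  lines <- unlist(lapply(matrices, function(cm) {
    c(sprintf(">%s %s", cm$matrix_id, cm$tf_name),
      vapply(1:4, function(r) {
        sprintf("%s [ %s ]", DNA_BASES4[r],
                paste(format(cm$counts[r, ], trim = TRUE), collapse = " "))
      }, ""))
  }))
  writeLines(lines, path)
  invisible(path)
}
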