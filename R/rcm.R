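#' Relative complexity measure (RCM) distance between two sequences
#'
#' Alignment-free distance built from production complexities: with
#' \eqn{c(\cdot)} the LZ complexity ([lz_complexity()]) and \eqn{S_1 S_2}
#' plain concatenation,
#' \deqn{d(S_1,S_2) = \frac{(c(S_1S_2) - c(S_1)) + (c(S_2S_1) - c(S_2))}
#'                         {\tfrac12 (c(S_1S_2) + c(S_2S_1))}.}
#' The term \eqn{c(S_2S_1) - c(S_2)} is the number of production steps
#' needed to generate \eqn{S_1} when the full history of \eqn{S_2} is
#' already available, so related sequences -- which can be largely copied
#' from each other -- score small distances. The measure is symmetric by
#' construction and lies in \eqn{[0, 2]}.
#'
#' Note \eqn{d(S,S) > 0}: a sequence concatenated with itself still costs
#' one extra whole-copy step, so the self-distance is
#' \eqn{2(c(SS)-c(S))/c(SS)} (= 2/7 for the 12-mer `TGATGCGACACA`).
#' [rcm_distance_matrix()] writes 0 on the diagonal by convention.
#'
#' @param s1,s2 Single nucleotide strings over `{A,C,G,T}`.
#' @return Non-negative distance.
#' @export
#' @examples
#' s <- "TGATGCGACACA"
#' rcm_distance(s, s)  # 2/7
rcm_distance <- function(s1, s2) {
  c1 <- lz_complexity(s1)
  c2 <- lz_complexity(s2)
  c12 <- concat_complexity(s1, s2)
  c21 <- concat_complexity(s2, s1)
  ((c12 - c1) + (c21 - c2)) / (0.5 * (c12 + c21))
}

#' RCM distance matrix for a set of sequences
#'
#' Fills all unordered pairs via [rcm_distance()]; the diagonal is written
#' as 0 (required by neighbor-joining and the PHYLIP matrix format, even
#' though the raw self-distance of the measure is strictly positive).
#' Per-sequence complexities are computed once and reused; only the two
#' concatenation complexities are computed per pair.
#'
#' @param x Sequences accepted by [as_seq_tbl()]; at least 3, with unique
#'   IDs (neighbor-joining needs >= 3 leaves).
#' @return A symmetric numeric matrix with dimnames in input order.
#' @seealso [nj_tree()], [write_phylip_dist()]
#' @export
rcm_distance_matrix <- function(x) {
  x <- as_seq_tbl(x)
  n <- nrow(x)
  if (n < 3)
    stop("need at least 3 sequences to build a distance matrix", call. = FALSE)
  cs <- unname(lz_complexity(x$seq))
  d <- matrix(0, n, n, dimnames = list(x$id, x$id))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      cij <- concat_complexity(x$seq[i], x$seq[j])
      cji <- concat_complexity(x$seq[j], x$seq[i])
      d[i, j] <- d[j, i] <-
        ((cij - cs[i]) + (cji - cs[j])) / (0.5 * (cij + cji))
    }
  }
  stopifnot(all(is.finite(d)), all(d >= 0),
            isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
  d
}

#' Write a distance matrix in PHYLIP square format
#'
#' First line: taxon count; then one row per taxon. In the strict dialect
#' names are padded/truncated to 10 characters (the classic PHYLIP
#' interchange format); `relaxed = TRUE` keeps full names, whitespace
#' separated.
#'
#' @param d Symmetric numeric matrix with dimnames.
#' @param path Output path.
#' @param relaxed Use the relaxed (full-name) dialect?
#' @param digits Significant digits to print.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(d, path, relaxed = FALSE, digits = 6) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), !is.null(rownames(d)))
  nm <- rownames(d)
  if (!relaxed) nm <- formatC(substr(nm, 1, 10), width = -10)
  rows <- vapply(seq_len(nrow(d)), function(i) {
    paste0(nm[i], if (relaxed) "  " else "",
           paste(formatC(d[i, ], format = "f", digits = digits),
                 collapse = "  "))
  }, character(1))
  writeLines(c(sprintf("%5d", nrow(d)), rows), path)
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' Accepts both the strict dialect (name fixed at 10 characters) and the
#' relaxed dialect (whitespace-separated name). Rows may wrap across
#' lines; values are re-assembled by count.
#'
#' @param path Path to a PHYLIP square matrix file.
#' @param relaxed Strict 10-character names (`FALSE`, default) or
#'   whitespace-delimited names (`TRUE`)?
#' @return A symmetric numeric matrix with dimnames.
#' @export
read_phylip_dist <- function(path, relaxed = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || n < 2) stop("bad PHYLIP header: ", lines[1], call. = FALSE)
  body <- lines[-1]
  labels <- character(n)
  vals <- vector("list", n)
  row <- 0L
  for (ln in body) {
    need_new <- row == 0L || length(vals[[row]]) >= n
    if (need_new) {
      row <- row + 1L
      if (row > n) stop("too many rows in matrix", call. = FALSE)
      if (relaxed) {
        toks <- strsplit(trimws(ln), "\\s+")[[1]]
        labels[row] <- toks[1]
        vals[[row]] <- as.numeric(toks[-1])
      } else {
        labels[row] <- trimws(substr(ln, 1, 10))
        vals[[row]] <- as.numeric(strsplit(trimws(substr(ln, 11, nchar(ln))),
                                           "\\s+")[[1]])
      }
    } else {
      vals[[row]] <- c(vals[[row]],
                       as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
    }
  }
  if (row < n || any(lengths(vals) != n))
    stop("matrix body does not match declared taxon count", call. = FALSE)
  d <- do.call(rbind, vals)
  dimnames(d) <- list(labels, labels)
  d
}
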