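#' Exhaustive-history (LZ76) parse of a nucleotide sequence
#'
#' Parses a sequence into its exhaustive production history: starting from
#' the empty state, each step copies the longest substring of the sequence
#' generated so far (the copy source may self-overlap, i.e. extend into
#' symbols written during the current step) and then appends one new
#' symbol. The final component may be a bare copy, with no appended symbol,
#' when the sequence ends mid-copy. The number of steps is the sequence's
#' production (LZ) complexity.
#'
#' For example, `"TGATGCGACACA"` parses as `T.G.A.TGC.GAC.ACA`, complexity
#' 6: the first three steps add single new symbols, step 4 copies `TG` and
#' adds `C`, step 5 copies `GA` and adds `C`, and step 6 copies `ACA` in
#' one self-overlapping copy with nothing left to add.
#'
#' @param seq A single nucleotide string over `{A,C,G,T}` (see
#'   [clean_sequences()] for the input policy).
#' @return An object of class `lz_parse`: a list with `components`
#'   (character vector whose concatenation is the input), `complexity`
#'   (number of components), and `steps`, a tibble with one row per step
#'   (`step`, `copy_len`, `add` -- `NA` for a bare-copy final step --
#'   and `component`).
#' @seealso [lz_complexity()], [concat_complexity()], [rcm_distance()]
#' @export
#' @examples
#' p <- lz_parse("TGATGCGACACA")
#' p$complexity
#' format(p)  # "T.G.A.TGC.GAC.ACA"
lz_parse <- function(seq) {
  check_bases(seq)
  raw <- .lz_parse_cpp(seq)
  comps <- substring(seq, raw$start, raw$start + raw$length - 1L)
  adds <- ifelse(raw$has_add == 1L,
                 substring(seq, raw$start + raw$length - 1L,
                           raw$start + raw$length - 1L),
                 NA_character_)
  out <- list(
    components = comps,
    complexity = length(comps),
    steps = tibble(
      step = seq_along(comps),
      copy_len = raw$copy_len,
      add = adds,
      component = comps
    )
  )
  class(out) <- "lz_parse"
  out
}

#' @export
format.lz_parse <- function(x, ...) paste(x$components, collapse = ".")

#' @export
print.lz_parse <- function(x, ...) {
  cat("LZ76 exhaustive-history parse\n")
  cat("  components:", format(x), "\n")
  cat("  complexity:", x$complexity, "\n")
  invisible(x)
}

#' @export
tidy.lz_parse <- function(x, ...) x$steps

#' Lempel-Ziv production complexity
#'
#' Number of steps in the exhaustive-history parse ([lz_parse()]) of each
#' sequence: the number of copy-and-add productions needed to generate the
#' sequence from the empty state using its own history as the copy source.
#'
#' @param seq Character vector of nucleotide strings (vectorised).
#' @return Integer vector of complexities.
#' @export
#' @examples
#' lz_complexity("TGATGCGACACA")  # 6
lz_complexity <- function(seq) {
  vapply(seq, function(s) {
    check_bases(s)
    .lz_complexity_cpp(s)
  }, integer(1), USE.NAMES = !is.null(names(seq)))
}

#' Complexity of a concatenation
#'
#' `lz_complexity` of `s1` followed directly by `s2` (no separator symbol
#' is inserted). Provided as its own operation so the distance layer can
#' never concatenate incorrectly. `c(s2 s1) - c(s2)` measures the number of
#' production steps needed to generate `s1` given the full history of
#' `s2`, the quantity at the heart of the relative complexity measure.
#'
#' @param s1,s2 Single nucleotide strings.
#' @return Integer complexity of the concatenation.
#' @export
#' @examples
#' s <- "TGATGCGACACA"
#' concat_complexity(s, s)  # 7: one extra whole-copy step
concat_complexity <- function(s1, s2) {
  check_bases(s1, "s1")
  check_bases(s2, "s2")
  .lz_concat_complexity_cpp(s1, s2)
}

#' Per-sequence complexity table
#'
#' Computes length and LZ complexity for every sequence in a sequence
#' table; optionally includes the dotted parse string.
#'
#' @param x Sequences accepted by [as_seq_tbl()].
#' @param show_parse Include a `parse` column with the dot-joined
#'   components (e.g. `T.G.A.TGC.GAC.ACA`)?
#' @return A tibble with columns `id`, `length`, `lz_complexity`, and
#'   optionally `parse`.
#' @export
complexity_table <- function(x, show_parse = FALSE) {
  x <- as_seq_tbl(x)
  out <- tibble(
    id = x$id,
    length = nchar(x$seq),
    lz_complexity = unname(lz_complexity(x$seq))
  )
  if (show_parse)
    out$parse <- vapply(x$seq, function(s) format(lz_parse(s)), character(1),
                        USE.NAMES = FALSE)
  out
}
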