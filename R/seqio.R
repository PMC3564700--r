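#' Read nucleotide sequences from a FASTA file
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped lines) into a
#' sequence table: a tibble with one row per record and columns `id` (the
#' first whitespace-delimited token of the header) and `seq` (the bases as
#' a single uppercase string).
#'
#' Sequences are cleaned on read: letters are uppercased, and `U` is mapped
#' to `T` with a warning (RNA-style records are common in public
#' repositories). IUPAC ambiguity codes (`N`, `R`, `Y`, ...) are rejected
#' with an error naming the offending record, position and symbol, because
#' complexity parsing over a silently enlarged alphabet changes results
#' without notice. Set `ambiguous = "strip"` to instead delete ambiguous
#' positions, with a warning reporting how many were removed.
#'
#' @param path Path to a FASTA file.
#' @param ambiguous Policy for non-ACGT symbols: `"error"` (default) or
#'   `"strip"`.
#' @return A tibble with columns `id` and `seq`.
#' @seealso [write_fasta()], [clean_sequences()]
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 first", "ACGTAC", ">s2", "ggttaa"), fa)
#' read_fasta(fa)
read_fasta <- function(path, ambiguous = c("error", "strip")) {
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             whole.header = FALSE)
  x <- tibble(
    id  = unname(vapply(recs, function(r) attr(r, "name"), character(1))),
    seq = unname(vapply(recs, function(r) as.character(r)[1], character(1)))
  )
  clean_sequences(x, ambiguous = ambiguous)
}

#' Write a sequence table to FASTA
#'
#' @param x A sequence table (tibble with `id`, `seq`) or a named character
#'   vector.
#' @param path Output path.
#' @param linewidth Characters per sequence line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, linewidth = 70) {
  x <- as_seq_tbl(x, clean = FALSE)
  seqinr::write.fasta(as.list(x$seq), names = x$id, file.out = path,
                      nbchar = linewidth, as.string = TRUE)
  invisible(path)
}

#' Coerce to a sequence table
#'
#' Accepts a tibble/data frame with `id` and `seq` columns or a named
#' character vector, and returns a validated sequence table. IDs must be
#' unique and sequences non-empty.
#'
#' @param x Input sequences.
#' @param clean Apply [clean_sequences()] (uppercase, U to T, ambiguity
#'   policy)? Default `TRUE`.
#' @param ambiguous Passed to [clean_sequences()].
#' @return A tibble with columns `id` and `seq`.
#' @export
as_seq_tbl <- function(x, clean = TRUE, ambiguous = c("error", "strip")) {
  if (is.character(x)) {
    ids <- names(x) %||% paste0("seq", seq_along(x))
    x <- tibble(id = ids, seq = unname(x))
  } else if (is.data.frame(x)) {
    if (!all(c("id", "seq") %in% names(x)))
      stop("sequence table needs columns 'id' and 'seq'", call. = FALSE)
    x <- as_tibble(x[, c("id", "seq")])
  } else {
    stop("cannot interpret input as sequences", call. = FALSE)
  }
  dup <- unique(x$id[duplicated(x$id)])
  if (length(dup))
    stop("duplicate sequence IDs: ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(x$seq)))
    stop("empty sequence(s): ",
         paste(x$id[!nzchar(x$seq)], collapse = ", "), call. = FALSE)
  if (clean) x <- clean_sequences(x, ambiguous = ambiguous)
  x
}

#' Clean and validate nucleotide sequences
#'
#' Uppercases, maps `U` to `T` (with a warning), and applies the ambiguity
#' policy: `"error"` rejects any symbol outside `{A,C,G,T}` naming the
#' record, position and symbol; `"strip"` deletes such positions and warns
#' with the per-record counts.
#'
#' @inheritParams as_seq_tbl
#' @return The cleaned sequence table.
#' @export
clean_sequences <- function(x, ambiguous = c("error", "strip")) {
  ambiguous <- match.arg(ambiguous)
  x <- as_seq_tbl(x, clean = FALSE)
  x$seq <- toupper(x$seq)
  n_u <- sum(vapply(gregexpr("U", x$seq, fixed = TRUE),
                    function(m) sum(m > 0), numeric(1)))
  if (n_u > 0) {
    warning(sprintf("mapped %d 'U' base(s) to 'T'", n_u), call. = FALSE)
    x$seq <- gsub("U", "T", x$seq, fixed = TRUE)
  }
  bad_at <- regexpr("[^ACGT]", x$seq)
  if (any(bad_at > 0)) {
    if (ambiguous == "error") {
      i <- which(bad_at > 0)[1]
      stop(sprintf(
        "sequence '%s' has non-ACGT symbol '%s' at position %d (use ambiguous = \"strip\" to drop such positions)",
        x$id[i], substr(x$seq[i], bad_at[i], bad_at[i]), bad_at[i]),
        call. = FALSE)
    }
    before <- nchar(x$seq)
    x$seq <- gsub("[^ACGT]", "", x$seq)
    removed <- before - nchar(x$seq)
    warning(sprintf("stripped %d ambiguous base(s) from %d sequence(s)",
                    sum(removed), sum(removed > 0)), call. = FALSE)
    if (any(!nzchar(x$seq)))
      stop("sequence(s) empty after stripping ambiguous bases: ",
           paste(x$id[!nzchar(x$seq)], collapse = ", "), call. = FALSE)
  }
  x
}

# Internal: validate a single bases string for the complexity layer.
check_bases <- function(s, what = "sequence") {
  if (!is.character(s) || length(s) != 1 || is.na(s))
    stop(what, " must be a single string", call. = FALSE)
  if (!nzchar(s)) stop(what, " is empty", call. = FALSE)
  bad <- regexpr("[^ACGT]", s)
  if (bad > 0)
    stop(sprintf("%s has non-ACGT symbol '%s' at position %d",
                 what, substr(s, bad, bad), bad), call. = FALSE)
  invisible(s)
}
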