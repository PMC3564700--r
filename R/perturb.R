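#' Three-way mutation split for a perturbation rate
#'
#' Number of mutations applied to a sequence of length `length` at rate
#' `rate`: `n_total = round(rate * length)` (half-up), divided into equal
#' thirds of deletions, substitutions and insertions up to rounding. The
#' deletion and insertion counts are kept exactly equal
#' (`n_del = n_ins = round(n_total/3)`, remainder to substitutions) so
#' that sequence length -- and, together with the pool mechanics, base
#' composition -- is conserved.
#'
#' @param length Sequence length.
#' @param rate Fraction of bases to mutate, in `[0, 1)`.
#' @return A list with `n_total`, `n_del`, `n_sub`, `n_ins`.
#' @export
mutation_counts <- function(length, rate) {
  if (!is.finite(rate) || rate < 0 || rate >= 1)
    stop("rate must be a finite fraction in [0, 1)", call. = FALSE)
  n_total <- floor(rate * length + 0.5)
  if (n_total == 0)
    return(list(n_total = 0L, n_del = 0L, n_sub = 0L, n_ins = 0L))
  if (n_total > length)
    stop("rate yields more mutations than sequence positions", call. = FALSE)
  if (n_total < 3)
    stop(sprintf(
      "rate %g on length %d yields only %d mutation(s); need >= 3 so that deletion, substitution and insertion each occur",
      rate, length, n_total), call. = FALSE)
  n_del <- as.integer(floor(n_total / 3 + 0.5))
  list(n_total = as.integer(n_total), n_del = n_del,
       n_sub = as.integer(n_total - 2L * n_del), n_ins = n_del)
}

#' Perturb one sequence with the pool-based mutation scheme
#'
#' Mimics mutation while conserving base composition exactly. Three phases
#' act in order on the current state of the sequence:
#' \enumerate{
#'   \item \emph{Delete} `n_del` bases at distinct uniformly chosen
#'     positions; each deleted base enters a pool.
#'   \item \emph{Substitute} at `n_sub` distinct positions: the resident
#'     base is swapped with a base drawn uniformly from the pool (the
#'     resident enters the pool; the draw may return the same letter -- a
#'     silent substitution).
#'   \item \emph{Insert} every base remaining in the pool, one at a time,
#'     each at an independent uniform position of the current (growing)
#'     sequence.
#' }
#' Because deletions feed the pool, substitutions swap one-for-one and
#' insertions drain it, every replicate has exactly the source's base
#' multiset and length; both are asserted before returning.
#'
#' @param seq Single nucleotide string.
#' @param rate Fraction of bases to mutate (e.g. `0.10`).
#' @param seed Integer seed for this replicate's substream.
#' @return A list with `seq` (the perturbed string) and `audit`, a tibble
#'   of the individual events (`phase`, `position`, `base_out`,
#'   `base_in`); positions are 1-based in the sequence state current at
#'   the time of each event.
#' @seealso [perturb_replicate()], [perturb_dataset()]
#' @export
perturb_sequence <- function(seq, rate, seed) {
  check_bases(seq)
  L <- nchar(seq)
  cnt <- mutation_counts(L, rate)
  if (cnt$n_total == 0)
    return(list(seq = seq,
                audit = tibble(phase = character(), position = integer(),
                               base_out = character(), base_in = character())))
  with_seed(as.integer(seed), {
    s <- strsplit(seq, "", fixed = TRUE)[[1]]

    del_pos <- sort(sample.int(length(s), cnt$n_del))
    pool <- s[del_pos]
    s <- s[-del_pos]
    audit <- list(tibble(phase = "del", position = del_pos,
                         base_out = pool, base_in = NA_character_))

    sub_pos <- sample.int(length(s), cnt$n_sub)
    sub_out <- character(cnt$n_sub); sub_in <- character(cnt$n_sub)
    for (k in seq_len(cnt$n_sub)) {
      draw <- sample.int(length(pool), 1)
      sub_out[k] <- s[sub_pos[k]]
      sub_in[k] <- pool[draw]
      pool[draw] <- s[sub_pos[k]]
      s[sub_pos[k]] <- sub_in[k]
    }
    audit[[2]] <- tibble(phase = "sub", position = sub_pos,
                         base_out = sub_out, base_in = sub_in)

    ins_pos <- integer(cnt$n_ins); ins_base <- character(cnt$n_ins)
    for (k in seq_len(cnt$n_ins)) {
      draw <- sample.int(length(pool), 1)
      pos <- sample.int(length(s) + 1, 1)  # slot before position `pos`
      s <- append(s, pool[draw], after = pos - 1L)
      ins_pos[k] <- pos; ins_base[k] <- pool[draw]
      pool <- pool[-draw]
    }
    audit[[3]] <- tibble(phase = "ins", position = ins_pos,
                         base_out = NA_character_, base_in = ins_base)

    out <- paste(s, collapse = "")
    # hard conservation guarantees, not just test-time checks
    stopifnot(length(pool) == 0, nchar(out) == L,
              identical(sort(s), sort(strsplit(seq, "")[[1]])))
    list(seq = out, audit = dplyr::bind_rows(audit))
  })
}

#' Perturb every sequence of a dataset for one replicate
#'
#' Applies [perturb_sequence()] independently to each sequence using a
#' deterministic per-(sequence, replicate) substream derived from the
#' master seed, so any single replicate can be regenerated without
#' generating its predecessors and perturbing one sequence never shifts
#' another's randomness.
#'
#' @param x Sequences accepted by [as_seq_tbl()].
#' @param rate Mutation fraction.
#' @param replicate_index 1-based replicate number.
#' @param seed Master integer seed.
#' @return A sequence table (tibble `id`, `seq`) of the same shape as `x`.
#' @export
perturb_replicate <- function(x, rate, replicate_index, seed) {
  x <- as_seq_tbl(x)
  rate_tag <- as.integer(round(rate * 1e6))
  x$seq <- vapply(seq_len(nrow(x)), function(i) {
    sub_seed <- derive_seed(seed, rate_tag, replicate_index, i,
                            utf8ToInt(substr(x$id[i], 1, 1)))
    perturb_sequence(x$seq[i], rate, sub_seed)$seq
  }, character(1))
  x
}

#' Generate a stream of perturbed replicate datasets
#'
#' The paper-style resampling design uses 1000 replicates at each of the
#' mutation levels 1%, 2%, 5%, 10%, 15%, 20% and 25%; here both the rate
#' and the replicate count are free parameters.
#'
#' @inheritParams perturb_replicate
#' @param n_replicates Number of replicate datasets.
#' @param .f Optional function applied to each replicate dataset in turn;
#'   when supplied, the list of its results is returned instead of the
#'   (memory-heavier) list of datasets, keeping only one replicate in
#'   memory at a time.
#' @return A list of `n_replicates` sequence tables, or of `.f` results.
#' @export
perturb_dataset <- function(x, rate, n_replicates, seed, .f = NULL) {
  x <- as_seq_tbl(x)
  lapply(seq_len(n_replicates), function(r) {
    rep_x <- perturb_replicate(x, rate, r, seed)
    if (is.null(.f)) rep_x else .f(rep_x)
  })
}
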