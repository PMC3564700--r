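# Sequence-evolution simulator: K2P / F84 substitution models with
# optional simple indels, used to benchmark alignment-free reconstruction
# against a known true topology.

BASES <- c("A", "C", "G", "T")
PURINE <- c(TRUE, FALSE, TRUE, FALSE)  # A, G

#' Nucleotide substitution model (K2P or F84)
#'
#' Builds a reversible rate matrix for the Kimura 2-parameter model
#' (equal base frequencies) or the Felsenstein 1984 model (arbitrary
#' frequencies), scaled to one expected substitution per site per unit
#' branch length, and pre-computes its spectral decomposition so
#' transition probabilities for any branch length come from the exact
#' matrix exponential.
#'
#' `tstv` is the expected transition/transversion ratio at stationarity
#' (the PHYLIP-style parameter; default 2). For K2P, `tstv = 0.5` makes
#' all rates equal, i.e. the Jukes-Cantor model.
#'
#' @param model `"K2P"` or `"F84"`.
#' @param tstv Expected transition/transversion ratio (> 0; for F84 it
#'   must exceed the pure-transversion minimum implied by the
#'   frequencies).
#' @param base_freq Stationary frequencies in A, C, G, T order, summing
#'   to 1. Ignored (fixed at 1/4 each) for K2P.
#' @return An object of class `subst_model` with elements `name`, `tstv`,
#'   `freq`, `Q` and the eigen-decomposition used by
#'   [transition_probs()].
#' @export
subst_model <- function(model = c("K2P", "F84"), tstv = 2,
                        base_freq = c(0.3, 0.2, 0.2, 0.3)) {
  model <- match.arg(model)
  stopifnot(is.finite(tstv), tstv > 0)
  if (model == "K2P") {
    freq <- rep(0.25, 4)
    alpha <- 2 * tstv  # beta = 1
    Q <- matrix(1, 4, 4)
    for (i in 1:4) for (j in 1:4)
      if (i != j && PURINE[i] == PURINE[j]) Q[i, j] <- alpha
  } else {
    freq <- base_freq
    stopifnot(length(freq) == 4, all(freq > 0),
              abs(sum(freq) - 1) < 1e-12)
    piR <- freq[1] + freq[3]; piY <- freq[2] + freq[4]
    T1 <- 2 * (freq[1] * freq[3] + freq[2] * freq[4])
    T2 <- 2 * (freq[1] * freq[3] / piR + freq[2] * freq[4] / piY)
    V1 <- 2 * piR * piY
    alpha <- (tstv * V1 - T1) / T2  # beta = 1
    if (alpha < 0)
      stop(sprintf(
        "tstv = %g is below the pure-transversion minimum %g for these frequencies",
        tstv, T1 / V1), call. = FALSE)
    Q <- matrix(0, 4, 4)
    for (i in 1:4) for (j in 1:4) {
      if (i == j) next
      Q[i, j] <- freq[j]
      if (PURINE[i] == PURINE[j])
        Q[i, j] <- Q[i, j] + alpha * freq[j] / (if (PURINE[j]) piR else piY)
    }
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  # scale to 1 expected substitution / site / unit time
  mu <- -sum(freq * diag(Q))
  Q <- Q / mu
  dimnames(Q) <- list(BASES, BASES)
  # reversible: symmetrize with sqrt(pi) similarity for a stable eigen
  s <- sqrt(freq)
  B <- diag(s) %*% Q %*% diag(1 / s)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(list(name = model, tstv = tstv, freq = freq, Q = Q,
                 eig_values = eig$values,
                 right = diag(1 / s) %*% eig$vectors,
                 left = t(eig$vectors) %*% diag(s)),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("%s substitution model (ts/tv = %g)\n", x$name, x$tstv))
  cat("  base frequencies:",
      paste(sprintf("%s=%.3f", BASES, x$freq), collapse = " "), "\n")
  invisible(x)
}

#' Transition probability matrix for a branch
#'
#' Exact matrix exponential `P(t) = exp(Q t)` of the model's generator;
#' rows are the ancestral base (A, C, G, T), columns the descendant base.
#'
#' @param model A [subst_model()].
#' @param t Branch length in expected substitutions per site (>= 0).
#' @return A 4x4 stochastic matrix.
#' @export
transition_probs <- function(model, t) {
  stopifnot(inherits(model, "subst_model"), is.finite(t), t >= 0)
  P <- model$right %*% diag(exp(model$eig_values * t)) %*% model$left
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(BASES, BASES)
  P
}

# Evolve integer-coded bases one branch: vectorised by ancestral base.
mutate_bases <- function(bases, P) {
  out <- bases
  for (b in 1:4) {
    idx <- which(bases == b)
    if (length(idx))
      out[idx] <- sample.int(4, length(idx), replace = TRUE, prob = P[b, ])
  }
  out
}

#' Simulate one sequence family along a tree
#'
#' Draws a root sequence i.i.d. from the model's stationary frequencies
#' and evolves it down the tree: per branch, each site substitutes
#' according to the model's exact transition probabilities for that
#' branch length, and (optionally) indel events occur with probability
#' `indel_rate` per site per branch, each a deletion or insertion (equal
#' odds) of geometric length. The full homology history is logged, so the
#' true multiple alignment of the leaves is returned alongside the
#' unaligned sequences.
#'
#' @param tree `phylo` with branch lengths in expected
#'   substitutions/site; fully resolved.
#' @param model A [subst_model()].
#' @param root_length Root sequence length (exact by default; see
#'   `length_jitter`).
#' @param indel_rate Per-site probability of an indel event per branch
#'   (0 = substitution-only).
#' @param indel_geom_p Success probability of the geometric indel-length
#'   distribution (mean length `1/indel_geom_p`).
#' @param length_jitter If `TRUE`, draw the root length uniformly within
#'   +/- 5\% of `length` instead of using it exactly.
#' @param seed Integer seed; the simulation is fully reproducible from
#'   it.
#' @return A list with `tree` (the generating tree), `sequences` (tibble
#'   `id`, `seq` of unaligned leaf sequences) and `alignment` (character
#'   matrix, leaves x columns, with `-` gaps: the true alignment implied
#'   by the logged indel history).
#' @export
evolve_family <- function(tree, model, root_length = 500, indel_rate = 0,
                          indel_geom_p = 0.5, length_jitter = FALSE,
                          seed = 1) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            inherits(model, "subst_model"), root_length >= 1)
  with_seed(as.integer(seed), {
    L0 <- if (length_jitter)
      sample(seq(floor(root_length * 0.95), ceiling(root_length * 1.05)), 1)
    else as.integer(root_length)
    n_tip <- length(tree$tip.label)
    root <- n_tip + 1L
    # homology columns: global order of column ids; every indel event
    # splices this order so leaf rows line up into the true alignment
    col_order <- seq_len(L0)
    next_col <- L0 + 1L
    node_seq <- vector("list", max(tree$edge))
    node_col <- vector("list", max(tree$edge))
    node_seq[[root]] <- sample.int(4, L0, replace = TRUE, prob = model$freq)
    node_col[[root]] <- seq_len(L0)

    edges <- ape::reorder.phylo(tree, "cladewise")$edge
    elen <- ape::reorder.phylo(tree, "cladewise")$edge.length
    for (e in seq_len(nrow(edges))) {
      par <- edges[e, 1]; chd <- edges[e, 2]
      s <- node_seq[[par]]; cl <- node_col[[par]]
      s <- mutate_bases(s, transition_probs(model, elen[e]))
      if (indel_rate > 0 && length(s) > 0) {
        n_ev <- stats::rbinom(1, length(s), indel_rate)
        for (ev in seq_len(n_ev)) {
          len <- stats::rgeom(1, indel_geom_p) + 1L
          if (stats::runif(1) < 0.5 && length(s) > len) {  # deletion
            at <- sample.int(length(s) - len + 1L, 1)
            keep <- setdiff(seq_along(s), at:(at + len - 1L))
            s <- s[keep]; cl <- cl[keep]
          } else {                                          # insertion
            at <- sample.int(length(s) + 1L, 1) - 1L  # insert after `at`
            new_cols <- seq(next_col, length.out = len)
            next_col <- next_col + len
            ins_bases <- sample.int(4, len, replace = TRUE, prob = model$freq)
            anchor <- if (at == 0L) {
              if (length(cl)) match(cl[1], col_order) - 1L else length(col_order)
            } else match(cl[at], col_order)
            col_order <- append(col_order, new_cols, after = anchor)
            s <- append(s, ins_bases, after = at)
            cl <- append(cl, new_cols, after = at)
          }
        }
      }
      node_seq[[chd]] <- s; node_col[[chd]] <- cl
    }

    ids <- tree$tip.label
    seqs <- vapply(seq_len(n_tip), function(i)
      paste(BASES[node_seq[[i]]], collapse = ""), character(1))
    aln <- matrix("-", n_tip, length(col_order),
                  dimnames = list(ids, NULL))
    pos_of <- match(seq_len(next_col - 1L), col_order)
    for (i in seq_len(n_tip))
      aln[i, pos_of[node_col[[i]]]] <- BASES[node_seq[[i]]]
    aln <- aln[, colSums(aln != "-") > 0, drop = FALSE]
    list(tree = tree,
         sequences = tibble(id = ids, seq = unname(seqs)),
         alignment = aln)
  })
}

#' Benchmark alignment-free reconstruction accuracy by simulation
#'
#' Simulates `n_families` independent sequence families on a known
#' topology and, for each, reconstructs the tree from the \emph{unaligned}
#' leaf sequences via the RCM distance matrix and neighbor joining, then
#' scores the Robinson-Foulds symmetric distance (raw and normalized by
#' `2(n-3)`) to the true tree. Additional reconstruction methods can be
#' scored on the same families via `extra_methods`, each a function
#' `f(sequences)` returning a `phylo` on the same leaves (this is how
#' externally produced trees are folded into the comparison).
#'
#' The defaults reproduce the low-divergence benchmark design: the
#' balanced 16-leaf topology with all branches 0.026 substitutions/site
#' (sister leaves about 95\% identical), root length 500, ts/tv 2, and a
#' 1\% per-site indel probability per branch.
#'
#' @param n_families Number of independent families (0 gives an empty
#'   result).
#' @param model A [subst_model()].
#' @param tree Generating topology with branch lengths.
#' @param root_length,indel_rate,indel_geom_p,length_jitter Passed to
#'   [evolve_family()].
#' @param extra_methods Named list of functions `f(sequences_tbl) ->
#'   phylo` scored alongside RCM.
#' @param seed Master seed; family `i` uses an independent substream.
#' @return An object of class `rcm_benchmark`: list with `scores` (tibble
#'   `family`, `method`, `rf`, `rf_normalized`) and `config`.
#' @export
benchmark_rcm <- function(n_families, model, tree = balanced_tree(),
                          root_length = 500, indel_rate = 0.01,
                          indel_geom_p = 0.5, length_jitter = FALSE,
                          extra_methods = list(), seed = 1) {
  methods <- c(list(RCM = function(seqs) nj_tree(rcm_distance_matrix(seqs))),
               extra_methods)
  rows <- vector("list", n_families)
  for (f in seq_len(n_families)) {
    fam <- evolve_family(tree, model, root_length = root_length,
                         indel_rate = indel_rate,
                         indel_geom_p = indel_geom_p,
                         length_jitter = length_jitter,
                         seed = derive_seed(seed, 101L, f))
    rows[[f]] <- dplyr::bind_rows(lapply(names(methods), function(m) {
      est <- methods[[m]](fam$sequences)
      tibble(family = f, method = m,
             rf = rf_distance(est, fam$tree),
             rf_normalized = rf_distance(est, fam$tree, normalized = TRUE))
    }))
  }
  structure(list(
    scores = if (n_families) dplyr::bind_rows(rows) else
      tibble(family = integer(), method = character(),
             rf = numeric(), rf_normalized = numeric()),
    config = list(model = model$name, tstv = model$tstv,
                  base_freq = model$freq, n_families = n_families,
                  root_length = root_length, indel_rate = indel_rate,
                  seed = seed)),
    class = "rcm_benchmark")
}

#' @export
tidy.rcm_benchmark <- function(x, ...) x$scores

#' @export
glance.rcm_benchmark <- function(x, ...) {
  if (!nrow(x$scores))
    return(tibble(model = character(), method = character(),
                  n_families = integer(), mean_rf = numeric(),
                  sd_rf = numeric(), mean_rf_normalized = numeric(),
                  sd_rf_normalized = numeric()))
  x$scores |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(n_families = dplyr::n(),
                     mean_rf = mean(.data$rf), sd_rf = sd(.data$rf),
                     mean_rf_normalized = mean(.data$rf_normalized),
                     sd_rf_normalized = sd(.data$rf_normalized),
                     .groups = "drop") |>
    dplyr::mutate(model = x$config$model, .before = 1)
}

#' @export
print.rcm_benchmark <- function(x, ...) {
  cat(sprintf("Simulation benchmark: %d families, %s model\n",
              x$config$n_families, x$config$model))
  print(glance(x))
  invisible(x)
}
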