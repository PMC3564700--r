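#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}'s implementation of the
#' standard Q-criterion and branch-length formulas) on a labeled symmetric
#' distance matrix, returning an unrooted tree. On an additive matrix the
#' generating topology and branch lengths are recovered exactly. Negative
#' branch lengths can arise on non-additive input and are kept as computed
#' unless `clamp_negative = TRUE`, which sets them to zero and transfers
#' the difference to the adjacent branch (the classic PHYLIP adjustment).
#'
#' @param d Symmetric numeric matrix with dimnames (or `dist` object),
#'   at least 3 taxa, all entries finite.
#' @param clamp_negative Zero out negative branch lengths, moving the
#'   difference to the adjacent branch?
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d, clamp_negative = FALSE) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (is.null(rownames(d)))
    dimnames(d) <- list(paste0("t", seq_len(nrow(d))),
                        paste0("t", seq_len(nrow(d))))
  if (nrow(d) < 3) stop("neighbor joining needs >= 3 taxa", call. = FALSE)
  if (!all(is.finite(d))) stop("distance matrix has non-finite entries",
                               call. = FALSE)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix is not symmetric", call. = FALSE)
  tr <- ape::nj(d)
  if (clamp_negative && any(tr$edge.length < 0)) {
    # zero the negative edge and move its amount onto one adjacent edge,
    # keeping the total tree length unchanged
    for (e in which(tr$edge.length < 0)) {
      parent <- tr$edge[e, 1]
      sib <- which(tr$edge[, 1] == parent & seq_len(nrow(tr$edge)) != e)[1]
      if (!is.na(sib))
        tr$edge.length[sib] <- tr$edge.length[sib] + tr$edge.length[e]
      tr$edge.length[e] <- 0
    }
  }
  tr
}

#' Nontrivial bipartitions of a tree
#'
#' Every internal edge of an unrooted tree splits the leaves in two; this
#' returns those splits in a canonical orientation (the side \emph{not}
#' containing the alphabetically first leaf), excluding trivial
#' single-leaf splits, so split sets from different trees on the same
#' leaves compare by simple set equality.
#'
#' @param tree A `phylo` object.
#' @return A tibble with columns `key` (canonical `|`-joined label
#'   string) and `tips` (list column of leaf labels on the canonical
#'   side).
#' @export
tree_splits <- function(tree) {
  labels <- sort(tree$tip.label)
  ref <- labels[1]
  n <- length(labels)
  pp <- ape::prop.part(tree)
  sides <- lapply(pp, function(idx) attr(pp, "labels")[idx])
  keys <- character(0); tips <- list()
  for (side in sides) {
    if (ref %in% side) side <- setdiff(labels, side)
    side <- sort(side)
    if (length(side) < 2 || length(side) > n - 2) next
    k <- paste(side, collapse = "|")
    if (!k %in% keys) { keys <- c(keys, k); tips <- c(tips, list(side)) }
  }
  tibble(key = keys, tips = tips)
}

#' Robinson-Foulds symmetric topology distance
#'
#' Number of nontrivial bipartitions present in exactly one of the two
#' trees (branch lengths are ignored). Works on partially resolved trees,
#' counting only splits actually present. For two fully resolved unrooted
#' trees on `n` leaves the maximum is `2(n-3)`, which is the denominator
#' used when `normalized = TRUE`.
#'
#' @param t1,t2 `phylo` trees on identical leaf sets.
#' @param normalized Divide by `2(n-3)`?
#' @return The symmetric distance: an even non-negative integer (or a
#'   fraction in `[0, 1]` when normalized).
#' @export
rf_distance <- function(t1, t2, normalized = FALSE) {
  only1 <- setdiff(t1$tip.label, t2$tip.label)
  only2 <- setdiff(t2$tip.label, t1$tip.label)
  if (length(only1) || length(only2))
    stop("leaf sets differ; only in first: [",
         paste(only1, collapse = ", "), "], only in second: [",
         paste(only2, collapse = ", "), "]", call. = FALSE)
  # phangorn warns on multifurcating input; partially resolved trees are a
  # supported case here (standard RF on the splits actually present)
  rf <- as.numeric(withCallingHandlers(
    phangorn::RF.dist(t1, t2, check.labels = TRUE),
    warning = function(w) {
      if (grepl("not binary", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }))
  if (normalized) {
    n <- length(t1$tip.label)
    if (n < 4) stop("normalized RF undefined for < 4 leaves", call. = FALSE)
    rf <- rf / (2 * (n - 3))
  }
  rf
}

# Two canonically oriented splits (reference leaf outside both) are
# compatible iff one side contains the other or they are disjoint.
splits_compatible <- function(a, b) {
  i <- length(intersect(a, b))
  i == 0 || i == length(a) || i == length(b)
}

# Build a phylo tree from a laminar family of canonical splits, annotated
# with per-split support counts, by emitting newick with internal-node
# labels. `ref` (the leaf excluded from every split side) hangs off the
# root, which makes each split side a clade.
splits_to_tree <- function(labels, split_tips, support) {
  stopifnot(length(split_tips) == length(support))
  ord <- order(-lengths(split_tips))
  split_tips <- split_tips[ord]; support <- support[ord]
  n_cl <- length(split_tips)
  # parent of each clade: smallest strictly containing clade (0 = root)
  parent <- integer(n_cl)
  for (i in seq_len(n_cl)) {
    parent[i] <- 0L
    if (i > 1) for (j in seq(i - 1, 1)) {
      if (length(split_tips[[j]]) > length(split_tips[[i]]) &&
          all(split_tips[[i]] %in% split_tips[[j]])) {
        # descending j: first hit is the smallest containing clade
        parent[i] <- j
        break
      }
    }
  }
  tip_parent <- vapply(labels, function(tp) {
    holders <- which(vapply(split_tips, function(s) tp %in% s, logical(1)))
    if (!length(holders)) 0L else holders[which.min(lengths(split_tips[holders]))]
  }, integer(1))
  emit <- function(cl) {
    kids_cl <- which(parent == cl)
    kids_tip <- labels[tip_parent == cl]
    parts <- c(kids_tip,
               vapply(kids_cl, emit, character(1)))
    if (cl == 0L) paste0("(", paste(parts, collapse = ","), ");")
    else paste0("(", paste(parts, collapse = ","), ")", support[cl])
  }
  ape::read.tree(text = emit(0L))
}

#' Extended-majority-rule (MRe) consensus tree
#'
#' Consensus of trees on a common leaf set, as computed by the classic
#' CONSENSE extended majority rule: every bipartition occurring in more
#' than half of the input trees is included, then the remaining splits are
#' considered in order of decreasing frequency (ties broken by the
#' canonical split key) and greedily added while compatible with
#' everything already retained, until the tree is fully resolved or no
#' compatible split remains. Each retained branch is annotated with its
#' occurrence count as the internal node label (the "numbers at branching
#' points" style of support display).
#'
#' @param trees A list of `phylo` trees (or a `multiPhylo`) on identical
#'   leaf sets.
#' @return A `phylo` tree whose `node.label` holds occurrence counts;
#'   attribute `"splits"` carries a tibble of all observed splits with
#'   columns `key`, `tips`, `count` and `retained`.
#' @export
consensus_mre <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (!length(trees)) stop("need at least one tree", call. = FALSE)
  labels <- sort(trees[[1]]$tip.label)
  for (t in trees)
    if (!identical(sort(t$tip.label), labels))
      stop("trees have differing leaf sets", call. = FALSE)
  n <- length(labels)
  n_tree <- length(trees)

  counts <- new.env(parent = emptyenv())
  tipsets <- new.env(parent = emptyenv())
  for (t in trees) {
    sp <- tree_splits(t)
    for (i in seq_len(nrow(sp))) {
      k <- sp$key[i]
      assign(k, (get0(k, envir = counts) %||% 0L) + 1L, envir = counts)
      if (is.null(get0(k, envir = tipsets)))
        assign(k, sp$tips[[i]], envir = tipsets)
    }
  }
  keys <- ls(counts)
  cnt <- vapply(keys, get, integer(1), envir = counts)
  obs <- tibble(key = keys, count = as.integer(cnt))
  obs <- obs[order(-obs$count, obs$key), ]
  obs$tips <- lapply(obs$key, get, envir = tipsets)

  retained <- logical(nrow(obs))
  sel_tips <- list(); sel_support <- integer(0)
  for (i in seq_len(nrow(obs))) {
    if (length(sel_tips) >= n - 3) break
    cand <- obs$tips[[i]]
    majority <- obs$count[i] > n_tree / 2
    ok <- all(vapply(sel_tips, splits_compatible, logical(1), b = cand))
    # majority splits of proper trees are mutually compatible; the guard
    # matters only for the greedy extension
    if (majority || ok) {
      if (!ok) stop("incompatible majority splits (malformed input trees)",
                    call. = FALSE)
      retained[i] <- TRUE
      sel_tips <- c(sel_tips, list(cand))
      sel_support <- c(sel_support, obs$count[i])
    }
  }
  tr <- splits_to_tree(labels, sel_tips, sel_support)
  obs$retained <- retained
  attr(tr, "splits") <- obs[, c("key", "tips", "count", "retained")]
  tr
}

#' Balanced phylogeny with equal branch lengths
#'
#' The fully balanced (depth `log2(n)`) topology with every branch the
#' same length -- the 16-leaf version is the classic benchmark shape for
#' simulation studies of reconstruction accuracy.
#'
#' @param n_leaves Number of leaves; must be a power of 2 (default 16).
#' @param branch_length Length of every branch, in expected substitutions
#'   per site.
#' @return A rooted `phylo` tree with tips `t1 ... tn`.
#' @export
balanced_tree <- function(n_leaves = 16, branch_length = 0.026) {
  if (n_leaves < 4 || bitwAnd(n_leaves, n_leaves - 1L) != 0)
    stop("n_leaves must be a power of 2, >= 4", call. = FALSE)
  tr <- ape::stree(n_leaves, type = "balanced")
  tr$edge.length <- rep(branch_length, nrow(tr$edge))
  tr
}
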