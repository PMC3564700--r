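# Independent reference implementations used only as test oracles.
# Deliberately naive and structurally different from the package code.

# Brute-force exhaustive-history parse: at each position try every history
# start and every copy length explicitly (O(L^3)).  Self-overlapping copies
# allowed; final component may be a bare copy.
oracle_lz_parse <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  comps <- character(0)
  i <- 1
  while (i <= n) {
    best <- 0
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        k <- 0
        while (i + k <= n && ch[j + k] == ch[i + k]) k <- k + 1
        if (k > best) best <- k
      }
    }
    if (i + best <= n) {
      comps <- c(comps, paste(ch[i:(i + best)], collapse = ""))
      i <- i + best + 1
    } else {
      comps <- c(comps, paste(ch[i:n], collapse = ""))
      i <- n + 1
    }
  }
  comps
}

oracle_lz_complexity <- function(s) length(oracle_lz_parse(s))

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# Bipartitions of an unrooted tree by direct edge traversal of the edge
# matrix (no ape helpers): for each internal edge, the tip set reachable
# from the child side.
oracle_splits <- function(tree) {
  n <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  below <- function(v) {
    if (v <= n) return(tree$tip.label[v])
    unlist(lapply(kids[[as.character(v)]], below))
  }
  ref <- sort(tree$tip.label)[1]
  keys <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= n) next
    side <- sort(below(child))
    if (ref %in% side) side <- sort(setdiff(tree$tip.label, side))
    if (length(side) < 2 || length(side) > n - 2) next
    keys <- c(keys, paste(side, collapse = "|"))
  }
  unique(keys)
}

oracle_rf <- function(t1, t2) {
  a <- oracle_splits(t1); b <- oracle_splits(t2)
  length(setdiff(a, b)) + length(setdiff(b, a))
}

# Split occurrence counts across a list of trees, keyed canonically.
oracle_split_counts <- function(trees) {
  all <- unlist(lapply(trees, oracle_splits))
  table(all)
}

# Random unrooted binary tree topology on n tips (no branch lengths).
random_topology <- function(n, labels = paste0("t", seq_len(n))) {
  ape::rtree(n, rooted = FALSE, br = NULL, tip.label = sample(labels))
}

base_tally <- function(s) sort(strsplit(s, "")[[1]])
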