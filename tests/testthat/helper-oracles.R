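# Independent oracles, deliberately sharing no code with the package.

# Anderson's one-way pseudo-F computed from first principles
oracle_permanova_f <- function(d, labels) {
  m <- as.matrix(d)
  n <- nrow(m)
  labels <- as.factor(labels)
  ss_total <- sum(m[upper.tri(m)]^2) / n
  ss_within <- 0
  for (g in levels(labels)) {
    idx <- which(labels == g)
    sub <- m[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  a <- nlevels(labels)
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

# exact permutation p by exhaustive enumeration of all label orderings
oracle_permanova_exact_p <- function(d, labels) {
  n <- length(labels)
  perms <- all_permutations(n)
  f_obs <- oracle_permanova_f(d, labels)
  fs <- apply(perms, 1, function(ix) oracle_permanova_f(d, labels[ix]))
  mean(fs >= f_obs - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
  }))
}

# hand Bray-Curtis on two count vectors
oracle_bray <- function(x, y) 1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))

# weighted UniFrac by naive per-tip root-path accumulation:
# sum over branches of l_b |A_b - B_b| where a tip contributes its
# proportion to every branch on its path to the root
oracle_wunifrac <- function(px, py, tree, normalized) {
  n_edge <- nrow(tree$edge)
  A <- B <- numeric(n_edge)
  root <- length(tree$tip.label) + 1L
  for (tip in seq_along(tree$tip.label)) {
    node <- tip
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      lab <- tree$tip.label[tip]
      A[e] <- A[e] + px[lab]
      B[e] <- B[e] + py[lab]
      node <- tree$edge[e, 1]
    }
  }
  num <- sum(tree$edge.length * abs(A - B))
  if (!normalized) return(num)
  den <- sum(tree$edge.length * (A + B))
  if (den > 0) num / den else 0
}
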