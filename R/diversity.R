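# Alpha diversity, beta diversity, ordination and permutation tests.

#' Shannon diversity of one sample
#'
#' H = -sum p_i log p_i over the positive counts of a single sample.
#'
#' @param x count (or abundance) vector with at least one positive entry.
#' @param base logarithm base; natural log by default, giving nats.
#' @return non-negative Shannon index.
#' @export
shannon <- function(x, base = exp(1)) {
  if (anyNA(x) || any(x < 0)) stop("counts must be non-negative")
  if (sum(x) == 0) stop("all-zero count vector has no defined diversity")
  as.numeric(vegan::diversity(x, index = "shannon", base = base))
}

#' Bray-Curtis dissimilarities between samples
#'
#' BC(x, y) = 1 - 2 sum_i min(x_i, y_i) / (sum x + sum y), computed over the
#' columns of a count table.
#'
#' @param counts count table (ASVs x samples); all depths must be positive.
#' @return `dist` object labelled with the sample ids.
#' @export
bray_curtis <- function(counts) {
  counts <- validate_count_table(counts)
  if (any(sample_depths(counts) == 0))
    stop("zero-depth sample(s): ",
         paste(colnames(counts)[sample_depths(counts) == 0], collapse = ", "))
  vegan::vegdist(t(counts), method = "bray")
}

#' Weighted UniFrac distances between samples
#'
#' For each branch b of the rooted tree, let A_b and B_b be the fractions of
#' samples x and y whose reads descend through b.  The raw weighted UniFrac
#' distance is sum_b l_b |A_b - B_b|; the normalized variant divides by
#' sum_b l_b (A_b + B_b) and is bounded in \[0, 1\].
#'
#' @param counts count table; every ASV (row) must be a leaf of `tree`.
#' @param tree rooted `phylo` tree with branch lengths >= 0.
#' @param normalized return the normalized variant (default) or the raw sum.
#' @return `dist` object labelled with the sample ids.
#' @export
weighted_unifrac <- function(counts, tree, normalized = TRUE) {
  counts <- validate_count_table(counts)
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (!ape::is.rooted(tree)) stop("weighted UniFrac requires a rooted tree")
  missing <- setdiff(rownames(counts), tree$tip.label)
  if (length(missing) > 0)
    stop("ASV(s) missing from tree: ", paste(missing, collapse = ", "))
  if (any(sample_depths(counts) == 0))
    stop("zero-depth sample(s): ",
         paste(colnames(counts)[sample_depths(counts) == 0], collapse = ", "))

  p <- relative_abundance(counts)
  ntip <- length(tree$tip.label)
  nsamp <- ncol(p)
  # per-node subtree proportions, accumulated tipward-to-rootward
  tree <- stats::reorder(tree, "postorder")
  node_p <- matrix(0, nrow = ntip + tree$Nnode, ncol = nsamp)
  idx <- match(tree$tip.label, rownames(counts))
  present <- !is.na(idx)
  node_p[which(present), ] <- p[idx[present], , drop = FALSE]
  for (e in seq_len(nrow(tree$edge))) {
    node_p[tree$edge[e, 1], ] <-
      node_p[tree$edge[e, 1], ] + node_p[tree$edge[e, 2], ]
  }
  A <- node_p[tree$edge[, 2], , drop = FALSE]  # edges x samples
  len <- tree$edge.length

  d <- matrix(0, nsamp, nsamp, dimnames = list(colnames(p), colnames(p)))
  for (i in seq_len(nsamp - 1)) {
    for (j in seq(i + 1, nsamp)) {
      num <- sum(len * abs(A[, i] - A[, j]))
      if (normalized) {
        den <- sum(len * (A[, i] + A[, j]))
        d[i, j] <- d[j, i] <- if (den > 0) num / den else 0
      } else {
        d[i, j] <- d[j, i] <- num
      }
    }
  }
  stats::as.dist(d)
}

#' Principal coordinates analysis
#'
#' Gower double-centering of the squared distances followed by an
#' eigendecomposition; coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues.  Axes with eigenvalue <= 0 are
#' reported in `eigenvalues` but excluded from the coordinates.
#'
#' @param d `dist` object or symmetric distance matrix.
#' @param k number of axes requested (>= 1).
#' @return list with `coordinates` (samples x axes), `eigenvalues`
#'   (non-increasing, all of them), `proportion_explained` (per returned
#'   axis, relative to the positive eigenvalues) and `n_axes_warning`
#'   (NULL, or a message when fewer than k positive axes exist).
#' @export
pcoa <- function(d, k = 2) {
  if (!inherits(d, "dist")) d <- stats::as.dist(as.matrix(d))
  if (length(k) != 1 || k < 1 || k != round(k)) stop("k must be an integer >= 1")
  n <- attr(d, "Size")
  fit <- suppressWarnings(stats::cmdscale(d, k = min(k, n - 1), eig = TRUE))
  eig <- sort(fit$eig, decreasing = TRUE)
  pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig), 1))
  warn <- NULL
  k_eff <- min(k, pos)
  if (pos < k) {
    warn <- sprintf("only %d positive-eigenvalue axes available (%d requested)",
                    pos, k)
    warning(warn)
  }
  coords <- fit$points[, seq_len(min(k_eff, ncol(fit$points))), drop = FALSE]
  if (k_eff == 0) coords <- matrix(0, n, 0, dimnames = list(labels(d), NULL))
  rownames(coords) <- labels(d)
  if (ncol(coords) > 0)
    colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  prop <- if (pos > 0) eig[seq_len(k_eff)] / sum(eig[eig > 0]) else numeric(0)
  list(coordinates = coords, eigenvalues = eig,
       proportion_explained = prop, n_axes_warning = warn)
}

#' One-way PERMANOVA
#'
#' Distance-based permutational MANOVA (Anderson's pseudo-F) with free label
#' permutation, as implemented by `vegan::adonis2`.  The permutation p-value
#' is (1 + #\{permuted F >= observed F\}) / (1 + n_perm) and can never be 0.
#'
#' @param d `dist` object or symmetric distance matrix.
#' @param labels group assignment, one per sample; at least two groups.
#' @param n_perm number of random permutations (default 999).
#' @param seed integer seed making the permutation p reproducible.
#' @return list with `F`, `R2`, `p`, `n_perm` and `seed`.
#' @export
permanova <- function(d, labels, n_perm = 999, seed = 1L) {
  if (!inherits(d, "dist")) d <- stats::as.dist(as.matrix(d))
  n <- attr(d, "Size")
  labels <- as.factor(labels)
  if (length(labels) != n) stop("labels length must match the distance matrix")
  if (nlevels(droplevels(labels)) < 2)
    stop("need at least two groups (one group spans the whole sample set)")
  if (n_perm < 1) stop("n_perm must be >= 1")
  df <- data.frame(.group = droplevels(labels))
  fit <- with_seed(seed, vegan::adonis2(d ~ .group, data = df,
                                        permutations = n_perm))
  list(F = fit$F[1], R2 = fit$R2[1], p = fit$`Pr(>F)`[1],
       n_perm = as.integer(n_perm), seed = as.integer(seed))
}

#' Wilcoxon rank-sum tests with Benjamini-Hochberg adjustment
#'
#' Two-sided Wilcoxon (Mann-Whitney) rank-sum tests of a per-sample
#' statistic between two groups; exact enumeration when both groups are
#' small and tie-free, normal approximation with tie correction otherwise
#' (the behaviour of `stats::wilcox.test`).  The Benjamini-Hochberg step-up
#' correction is applied across the supplied family of comparisons.
#'
#' @param values numeric vector (one comparison), matrix with one
#'   comparison per row and one column per sample, or a named list of
#'   vectors (one comparison each, with `groups` a matching list).
#' @param groups two-level labels, one per sample (shared across rows of a
#'   matrix `values`), or a list of label vectors parallel to a list
#'   `values`.
#' @return data.frame with columns comparison, W, p and p_adj.
#' @export
wilcoxon_bh <- function(values, groups) {
  if (is.list(values) && !is.data.frame(values)) {
    if (!is.list(groups) || length(groups) != length(values))
      stop("with a list of comparisons, groups must be a parallel list")
    parts <- mapply(wilcoxon_bh, values, groups, SIMPLIFY = FALSE)
    out <- do.call(rbind, parts)
    out$comparison <- names(values) %||% as.character(seq_along(values))
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    rownames(out) <- NULL
    return(out)
  }
  if (is.null(dim(values))) values <- matrix(values, nrow = 1,
                                             dimnames = list("comparison"))
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2)
    stop("groups must have exactly two non-empty levels")
  if (ncol(values) != length(groups))
    stop("values columns must match groups length")
  lv <- levels(droplevels(groups))
  res <- t(apply(values, 1, function(v) {
    ht <- suppressWarnings(stats::wilcox.test(v[groups == lv[1]],
                                              v[groups == lv[2]],
                                              alternative = "two.sided"))
    c(W = unname(ht$statistic), p = ht$p.value)
  }))
  out <- data.frame(comparison = rownames(values),
                    W = res[, "W"], p = res[, "p"],
                    p_adj = stats::p.adjust(res[, "p"], method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Write a distance matrix as a square TSV
#'
#' @param d `dist` object.
#' @param path output path.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(sample = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
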