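# Sample exclusion, rarefaction and relative abundance.

#' Exclude shallow samples
#'
#' Drops every sample whose depth (column sum) falls below `min_depth`; the
#' boundary is inclusive, so a sample at exactly `min_depth` reads is kept.
#' This is the self-consistent companion of rarefaction: a sample can be
#' rarefied to depth d iff it holds at least d reads.
#'
#' @param counts count table matrix (ASVs x samples).
#' @param min_depth minimum number of reads a retained sample must hold
#'   (>= 1).
#' @return list with `counts` (the retained columns) and `exclusion`, a
#'   data.frame of excluded sample ids and their depths plus the threshold
#'   used (attribute `min_depth`).
#' @export
exclude_low_depth <- function(counts, min_depth) {
  counts <- validate_count_table(counts)
  if (length(min_depth) != 1 || min_depth < 1 || min_depth != round(min_depth))
    stop("min_depth must be a single integer >= 1")
  depths <- sample_depths(counts)
  keep <- depths >= min_depth
  if (!any(keep)) stop("no samples retained at min_depth ", min_depth)
  excl <- data.frame(sample = colnames(counts)[!keep],
                     depth = unname(depths[!keep]),
                     stringsAsFactors = FALSE)
  attr(excl, "min_depth") <- as.integer(min_depth)
  list(counts = counts[, keep, drop = FALSE], exclusion = excl)
}

#' Rarefy a count table to a fixed depth
#'
#' Each sample's reads are subsampled uniformly at random WITHOUT
#' replacement down to exactly `depth` reads (multivariate hypergeometric
#' draw per sample).  Totals are conserved exactly and no count can exceed
#' its input value.  Reproducible under `seed`.
#'
#' @param counts count table; every sample must hold at least `depth` reads
#'   (run [exclude_low_depth()] first).
#' @param depth target reads per sample.
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return integer matrix of the same shape with all column sums == depth.
#' @export
rarefy <- function(counts, depth, seed = 1L) {
  counts <- validate_count_table(counts)
  if (length(depth) != 1 || depth < 1 || depth != round(depth))
    stop("depth must be a single integer >= 1")
  depth <- as.integer(depth)
  depths <- sample_depths(counts)
  if (any(depths < depth))
    stop("sample(s) with depth < ", depth, ": ",
         paste(colnames(counts)[depths < depth], collapse = ", "),
         "; exclude them first with exclude_low_depth()")
  out <- counts
  # each sample gets its own sub-seed derived from (seed, sample id), so the
  # draw for a sample does not depend on which other samples are present or
  # on column order
  for (j in seq_len(ncol(counts))) {
    sub_seed <- (as.integer(seed) + string_hash(colnames(counts)[j])) %%
      2147483647L
    out[, j] <- with_seed(sub_seed,
                          subsample_without_replacement(counts[, j], depth))
  }
  out
}

# deterministic 31-ary string hash into [0, 2^31 - 2]
string_hash <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

# Sequential (chained) hypergeometric draw: for each category in turn, the
# number of retained reads given how many reads and slots remain.  Equivalent
# to drawing `depth` reads uniformly without replacement from the pooled
# reads, in O(length(x)) time and memory.
subsample_without_replacement <- function(x, depth) {
  total <- sum(x)
  out <- integer(length(x))
  remaining <- total
  left <- as.integer(depth)
  for (i in seq_along(x)) {
    if (left == 0L) break
    xi <- x[i]
    if (xi == 0L) { remaining <- remaining - xi; next }
    if (remaining == xi) { out[i] <- left; left <- 0L; break }
    k <- stats::rhyper(1L, m = xi, n = remaining - xi, k = left)
    out[i] <- k
    left <- left - k
    remaining <- remaining - xi
  }
  out
}

#' Per-sample relative abundances
#'
#' @param counts count table; every sample depth must be positive.
#' @return numeric matrix of per-sample proportions; columns sum to 1.
#' @export
relative_abundance <- function(counts) {
  counts <- validate_count_table(counts)
  depths <- sample_depths(counts)
  if (any(depths == 0))
    stop("zero-depth sample(s): ",
         paste(colnames(counts)[depths == 0], collapse = ", "))
  sweep(counts, 2, depths, "/")
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (length(seed) != 1 || is.na(seed) || seed != round(seed))
    stop("seed must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
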