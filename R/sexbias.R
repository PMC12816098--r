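# The male-enrichment index i = (M - F)/M, its pseudocount floor, the
# cross-species consistency tally, and the taxon-level screens.

#' Pseudocount floor for mean relative abundances
#'
#' The smallest observable non-zero mean relative abundance in a design
#' rarefied to `depth` reads with at most `max_replicates` biological
#' replicates per sex-species combination: one read in one replicate gives a
#' mean of (1/depth)/max_replicates = 1/(depth * max_replicates).  Both M
#' and F are clamped from below at this floor before the index is formed,
#' so i is never undefined.
#'
#' @param depth rarefaction depth in reads (>= 1).
#' @param max_replicates maximum replicates per sex-species combination
#'   (>= 1).
#' @param value optional override of the floor value itself; the derived
#'   denominator is still recorded.
#' @return list of class `"floor_spec"` with fields `depth`,
#'   `max_replicates`, `denominator` (depth * max_replicates) and `floor`.
#' @export
pseudocount_floor <- function(depth, max_replicates, value = NULL) {
  if (length(depth) != 1 || depth < 1 || depth != round(depth))
    stop("depth must be a single integer >= 1")
  if (length(max_replicates) != 1 || max_replicates < 1 ||
      max_replicates != round(max_replicates))
    stop("max_replicates must be a single integer >= 1")
  den <- as.numeric(depth) * as.numeric(max_replicates)
  fl <- if (is.null(value)) 1 / den else as.numeric(value)
  if (fl <= 0) stop("floor must be positive")
  structure(list(depth = as.integer(depth),
                 max_replicates = as.integer(max_replicates),
                 denominator = den, floor = fl),
            class = "floor_spec")
}

floor_of <- function(floor) {
  if (inherits(floor, "floor_spec")) floor$floor
  else if (is.numeric(floor) && length(floor) == 1 && floor > 0) floor
  else stop("floor must be a floor_spec or a single positive number")
}

#' Group mean relative abundance
#'
#' Mean over the matching samples of the per-sample proportion vectors (the
#' mean of proportions, not the proportion of pooled reads; the two agree
#' only at equal depths, e.g. after rarefaction).
#'
#' @param counts count table.
#' @param meta sample metadata (see [read_sample_metadata()]).
#' @param species,sex labels selecting the group.
#' @return numeric vector over ASVs summing to 1, with attribute
#'   `n_replicates`.
#' @export
group_mean_relabund <- function(counts, meta, species, sex) {
  meta <- validate_sample_metadata(meta)
  ids <- meta$sample[meta$species == species & meta$sex == sex]
  ids <- intersect(colnames(counts), ids)
  if (length(ids) == 0)
    stop("no samples match species '", species, "', sex '", sex, "'")
  p <- relative_abundance(counts[, ids, drop = FALSE])
  out <- rowMeans(p)
  attr(out, "n_replicates") <- length(ids)
  out
}

#' The male-enrichment index i
#'
#' i = (M' - F')/M' where M' = max(M, floor) and F' = max(F, floor) are the
#' floored mean relative abundances in males and females.  Positive values
#' indicate male-enriched ASVs; i <= 1 always, and i = 0 whenever M' = F'
#' (including when both fall at the floor), while i is unbounded below.
#'
#' @param M,F mean relative abundances (vectors of equal length, >= 0).
#' @param floor a [pseudocount_floor()] spec or a positive number.
#' @return numeric vector of i values.
#' @export
i_index <- function(M, F, floor) {
  if (anyNA(M) || anyNA(F) || any(M < 0) || any(F < 0))
    stop("mean relative abundances must be non-negative")
  fl <- floor_of(floor)
  Mf <- pmax(M, fl)
  Ff <- pmax(F, fl)
  (Mf - Ff) / Mf
}

#' Per-ASV, per-species i index matrix
#'
#' Applies [i_index()] to the male and female group mean relative
#' abundances of every species in the metadata.
#'
#' @param counts count table (typically rarefied).
#' @param meta sample metadata; every species must have samples of both
#'   sexes.
#' @param floor a [pseudocount_floor()] spec or positive number.
#' @param male,female the two sex labels (defaults `"male"`, `"female"`).
#' @return list of class `"i_index_matrix"` with fields `i` (ASVs x
#'   species), `M` and `F` (the raw group means), `m_floored`/`f_floored`
#'   (logical matrices), `replicates` (2 x species counts) and `floor`.
#' @export
i_matrix <- function(counts, meta, floor, male = "male", female = "female") {
  counts <- validate_count_table(counts)
  meta <- validate_sample_metadata(meta)
  meta <- meta[meta$sample %in% colnames(counts), , drop = FALSE]
  species <- sort(unique(meta$species))
  have_both <- vapply(species, function(s) {
    all(c(male, female) %in% meta$sex[meta$species == s])
  }, logical(1))
  if (!all(have_both))
    stop("species missing a sex: ", paste(species[!have_both], collapse = ", "))
  fl <- floor_of(floor)
  nm <- list(rownames(counts), species)
  Mm <- Fm <- matrix(NA_real_, nrow(counts), length(species), dimnames = nm)
  reps <- matrix(NA_integer_, 2, length(species),
                 dimnames = list(c(male, female), species))
  for (k in seq_along(species)) {
    mv <- group_mean_relabund(counts, meta, species[k], male)
    fv <- group_mean_relabund(counts, meta, species[k], female)
    reps[1, k] <- attr(mv, "n_replicates")
    reps[2, k] <- attr(fv, "n_replicates")
    Mm[, k] <- mv
    Fm[, k] <- fv
  }
  structure(list(i = (pmax(Mm, fl) - pmax(Fm, fl)) / pmax(Mm, fl),
                 M = Mm, F = Fm,
                 m_floored = Mm < fl, f_floored = Fm < fl,
                 replicates = reps,
                 floor = if (inherits(floor, "floor_spec")) floor
                         else pseudocount_floor(1, 1, value = fl)),
            class = "i_index_matrix")
}

i_values <- function(im) {
  if (inherits(im, "i_index_matrix")) im$i
  else if (is.matrix(im)) im
  else stop("expected an i_index_matrix or a plain matrix of i values")
}

#' Cross-species consistency tally
#'
#' Partitions the ASVs by the exact number of species in which they are
#' male-enriched (i > 0, strictly; i = 0 does not count).  The counts over
#' k = 0..S always sum to the number of ASVs.
#'
#' @param im an [i_matrix()] result or a plain ASVs-x-species matrix of i
#'   values.
#' @return data.frame with columns `k` (0..S) and `n_asvs`.
#' @export
consistency_tally <- function(im) {
  iv <- i_values(im)
  k <- rowSums(iv > 0)
  S <- ncol(iv)
  data.frame(k = 0:S,
             n_asvs = as.integer(tabulate(k + 1L, nbins = S + 1L)))
}

#' Candidate male-enriched ASVs
#'
#' ASVs with i > 0 in at least `min_species` species, with per-species i
#' values reported only where positive (NA elsewhere), sorted by number of
#' positive species (descending), mean positive i (descending) and ASV id
#' (ascending).
#'
#' @param im an [i_matrix()] result or plain i-value matrix.
#' @param tax optional taxonomy table; lineages are joined onto the report.
#' @param min_species minimum number of species with i > 0 (1..S).
#' @return data.frame: asv, n_species_positive, mean_positive_i, one i
#'   column per species (NA where i <= 0), and lineage columns if `tax`
#'   given.  Zero rows when nothing qualifies.
#' @export
candidate_report <- function(im, tax = NULL, min_species = NULL) {
  iv <- i_values(im)
  S <- ncol(iv)
  if (is.null(min_species)) min_species <- S
  if (min_species < 1 || min_species > S)
    stop("min_species must lie in 1..", S)
  pos <- iv > 0
  npos <- rowSums(pos)
  keep <- which(npos >= min_species)
  shown <- iv
  shown[!pos] <- NA_real_
  mean_pos <- ifelse(npos > 0, rowSums(shown, na.rm = TRUE) / pmax(npos, 1),
                     NA_real_)
  out <- data.frame(asv = rownames(iv)[keep],
                    n_species_positive = as.integer(npos[keep]),
                    mean_positive_i = mean_pos[keep],
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(shown[keep, , drop = FALSE],
                                  stringsAsFactors = FALSE))
  rownames(out) <- NULL
  ord <- order(-out$n_species_positive, -out$mean_positive_i, out$asv)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(tax)) {
    tax <- validate_taxonomy(tax)
    out <- merge(out, tax, by = "asv", all.x = TRUE, sort = FALSE)
  }
  out
}

#' Per-species, per-sex screen of one taxon
#'
#' Sums the counts of every ASV assigned to `taxon` at `rank`, converts to
#' per-sample proportions, and averages within each (species, sex) group;
#' `present` flags whether the group holds any read of the taxon.  This is
#' the summed-count route behind statements such as a genus being present
#' only in males.
#'
#' @param counts count table.
#' @param meta sample metadata.
#' @param tax taxonomy table.
#' @param rank one of [taxonomic_ranks()].
#' @param taxon label to screen at that rank.
#' @return data.frame: species, sex, n_samples, mean_relative_abundance,
#'   present.
#' @export
taxon_sex_screen <- function(counts, meta, tax, rank, taxon) {
  counts <- validate_count_table(counts)
  meta <- validate_sample_metadata(meta)
  tax <- validate_taxonomy(tax)
  if (!rank %in% taxonomic_ranks())
    stop("rank must be one of: ", paste(taxonomic_ranks(), collapse = ", "))
  members <- tax$asv[tax[[rank]] == taxon]
  if (length(members) == 0)
    stop("taxon '", taxon, "' not found at rank '", rank, "'")
  members <- intersect(rownames(counts), members)
  meta <- meta[meta$sample %in% colnames(counts), , drop = FALSE]
  taxon_reads <- colSums(counts[members, , drop = FALSE])
  prop <- taxon_reads / sample_depths(counts)
  groups <- unique(meta[c("species", "sex")])
  groups <- groups[order(groups$species, groups$sex), , drop = FALSE]
  res <- lapply(seq_len(nrow(groups)), function(g) {
    ids <- meta$sample[meta$species == groups$species[g] &
                       meta$sex == groups$sex[g]]
    data.frame(species = groups$species[g], sex = groups$sex[g],
               n_samples = length(ids),
               mean_relative_abundance = mean(prop[ids]),
               present = any(taxon_reads[ids] > 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Mean community composition at a taxonomic rank with minor taxa pooled
#'
#' Per-sample proportions are summed within each taxon at `rank`, averaged
#' within each group (species x sex when `meta` is given, all samples
#' otherwise), and taxa whose overall mean relative abundance across all
#' samples falls below `other_threshold` are pooled into one "Others" row.
#' Each group column sums to 1.
#'
#' @param counts count table.
#' @param tax taxonomy table.
#' @param rank one of [taxonomic_ranks()].
#' @param other_threshold pooling threshold in \[0, 1); 0 pools nothing.
#' @param meta optional sample metadata defining the groups.
#' @param other_label row name of the pooled minor taxa.
#' @return matrix, taxa (plus possibly `other_label`) x groups.
#' @export
aggregate_composition <- function(counts, tax, rank, other_threshold = 0.005,
                                  meta = NULL, other_label = "Others") {
  counts <- validate_count_table(counts)
  tax <- validate_taxonomy(tax)
  if (!rank %in% taxonomic_ranks())
    stop("rank must be one of: ", paste(taxonomic_ranks(), collapse = ", "))
  if (other_threshold < 0 || other_threshold >= 1)
    stop("other_threshold must lie in [0, 1)")
  lineage <- tax[[rank]][match(rownames(counts), tax$asv)]
  lineage[is.na(lineage)] <- "unclassified"
  p <- relative_abundance(counts)
  by_taxon <- rowsum(p, group = lineage)  # taxa x samples, columns sum to 1
  if (is.null(meta)) {
    grp <- matrix(rowMeans(by_taxon), ncol = 1,
                  dimnames = list(rownames(by_taxon), "all"))
  } else {
    meta <- validate_sample_metadata(meta)
    meta <- meta[match(colnames(counts), meta$sample), , drop = FALSE]
    gl <- paste(meta$species, meta$sex, sep = ".")
    grp <- t(rowsum(t(by_taxon), group = gl) /
               as.vector(table(gl)[sort(unique(gl))]))
  }
  overall <- rowMeans(by_taxon)
  minor <- overall < other_threshold
  if (any(minor)) {
    pooled <- colSums(grp[minor, , drop = FALSE])
    grp <- rbind(grp[!minor, , drop = FALSE], pooled)
    rownames(grp)[nrow(grp)] <- other_label
  }
  grp[order(-rowMeans(grp) + (rownames(grp) == other_label)), , drop = FALSE]
}
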