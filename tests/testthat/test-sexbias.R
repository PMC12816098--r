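test_that("pseudocount floor derives 1/(depth x max_replicates)", {
  fl <- pseudocount_floor(428, 6)
  expect_equal(fl$denominator, 2568)
  expect_equal(fl$floor, 1 / 2568)
  expect_equal(pseudocount_floor(1, 1)$floor, 1)
  expect_equal(pseudocount_floor(100, 5)$floor, 0.002)
  # explicit override keeps the derived denominator on record
  fl <- pseudocount_floor(428, 6, value = 3.89408e-5)
  expect_equal(fl$floor, 3.89408e-5)
  expect_equal(fl$denominator, 2568)
  expect_error(pseudocount_floor(0, 6), "depth")
  expect_error(pseudocount_floor(428, 0), "max_replicates")
})

test_that("group mean relative abundance averages proportions, not pooled reads", {
  tab <- make_counts(matrix(c(2L, 8L, 20L, 30L), 2), samples = c("a", "b"))
  meta <- make_meta(c("a", "b"), "spA", c("male", "male"))
  mv <- group_mean_relabund(tab, meta, "spA", "male")
  expect_equal(unname(mv), c(mean(c(0.2, 0.4)), mean(c(0.8, 0.6))),
               ignore_attr = TRUE)
  expect_identical(attr(mv, "n_replicates"), 2L)
  # single sample is its own proportion vector
  expect_equal(unname(group_mean_relabund(tab[, 1, drop = FALSE],
                                          meta[1, ], "spA", "male")),
               c(0.2, 0.8), ignore_attr = TRUE)
  expect_error(group_mean_relabund(tab, meta, "spA", "female"), "no samples")
  # equal depths: mean of proportions equals pooled proportions
  tab <- make_counts(matrix(c(3L, 7L, 6L, 4L), 2), samples = c("a", "b"))
  mv <- group_mean_relabund(tab, meta, "spA", "male")
  expect_equal(unname(mv), unname(rowSums(tab) / sum(tab)),
               ignore_attr = TRUE)
})

test_that("the i index follows (M'-F')/M' with both means floored", {
  fl <- pseudocount_floor(428, 6)
  expect_equal(i_index(0.3, 0.3, fl), 0)
  expect_equal(i_index(0, 0, fl), 0)          # both floored
  expect_equal(i_index(1e-9, 1e-8, fl), 0)    # both below floor
  expect_equal(i_index(0.25, 0, fl), 0.9984423676, tolerance = 1e-9)
  expect_equal(i_index(0, 0.1, fl), -255.8)   # unbounded below
  expect_error(i_index(-0.1, 0.2, fl), "non-negative")
  # vectorized, always <= 1
  M <- withr_seed(1, runif(50)); F <- withr_seed(2, runif(50))
  expect_true(all(i_index(M, F, fl) <= 1))
})

test_that("the i matrix composes per-species scalar indices and flags floors", {
  # identical male/female columns per species -> all i = 0
  tab <- make_counts(matrix(rep(c(5L, 3L, 2L), 4), nrow = 3),
                     samples = c("m1", "f1", "m2", "f2"))
  meta <- make_meta(c("m1", "f1", "m2", "f2"),
                    rep(c("spA", "spB"), each = 2),
                    rep(c("male", "female"), 2))
  im <- i_matrix(tab, meta, pseudocount_floor(10, 1))
  expect_true(all(im$i == 0))
  expect_identical(dim(im$i), c(3L, 2L))

  # hand-set proportions match scalar i_index per species
  tab <- make_counts(matrix(c(9L, 1L, 5L, 5L, 2L, 8L, 4L, 6L), nrow = 2),
                     samples = c("m1", "f1", "m2", "f2"))
  fl <- pseudocount_floor(10, 1)
  im <- i_matrix(tab, meta, fl)
  expect_equal(im$i["ASV1", "spA"], i_index(0.9, 0.5, fl))
  expect_equal(im$i["ASV2", "spB"], i_index(0.8, 0.6, fl))

  # permuting sample order leaves the matrix unchanged
  perm <- c(3, 1, 4, 2)
  im2 <- i_matrix(tab[, perm], meta[perm, ], fl)
  expect_equal(im2$i, im$i)

  # a species missing one sex is refused by name
  expect_error(i_matrix(tab[, 1:3], meta[1:3, ], fl), "spB")
})

test_that("floor flags and scale-freeness hold", {
  meta <- make_meta(c("m1", "f1"), "spA", c("male", "female"))
  tab <- make_counts(matrix(c(100L, 0L, 0L, 100L), 2),
                     samples = c("m1", "f1"))
  fl <- pseudocount_floor(100, 1)
  im <- i_matrix(tab, meta, fl)
  expect_true(im$f_floored["ASV1", "spA"])
  expect_true(im$m_floored["ASV2", "spA"])
  expect_false(im$m_floored["ASV1", "spA"])
  # common integer depth multiplier leaves i unchanged
  im7 <- i_matrix(tab * 7L, meta, fl)
  expect_equal(im7$i, im$i)
})

test_that("consistency tally partitions the ASVs by exact positive count", {
  iv <- rbind(a = c(0.2, 0.3), b = c(-0.1, 0.4), c = c(0, -1))
  tal <- consistency_tally(iv)
  expect_identical(tal$k, 0:2)
  expect_identical(tal$n_asvs, c(1L, 1L, 1L))

  expect_identical(consistency_tally(matrix(0, 4, 3))$n_asvs,
                   c(4L, 0L, 0L, 0L))
  for (seed in 1:5) {
    iv <- withr_seed(seed, matrix(rnorm(60), 20, 3))
    expect_identical(sum(consistency_tally(iv)$n_asvs), 20L)
  }
})

test_that("swapping sex labels negates the sign of every i", {
  ds <- simulate_dataset(simulation_config(n_species = 2, replicates = 3,
                                           n_asvs = 40, shallow_depths = integer(0),
                                           depth_meanlog = log(2000),
                                           depth_sdlog = 0.2, seed = 5))
  fl <- pseudocount_floor(500, 3)
  rar <- rarefy(exclude_low_depth(ds$counts, 500)$counts, 500, seed = 5)
  im_mf <- i_matrix(rar, ds$meta, fl)
  meta_sw <- ds$meta
  meta_sw$sex <- ifelse(meta_sw$sex == "male", "female", "male")
  im_fm <- i_matrix(rar, meta_sw, fl)
  expect_equal(sign(im_fm$i), -sign(im_mf$i))
  # hence male-positive and female-positive tallies re-partition the ASVs
  k_m <- rowSums(im_mf$i > 0)
  k_f <- rowSums(im_fm$i > 0)
  expect_true(all(k_m + k_f <= ncol(im_mf$i)))
})

test_that("candidate report filters, blanks non-positive cells and sorts", {
  iv <- rbind(ASV01 = c(0.9, 0.8, 0.7), ASV02 = c(0.5, -1, 0.2),
              ASV03 = c(0.99, 0.99, 0.99), ASV04 = c(-0.1, 0, -2))
  colnames(iv) <- paste0("sp", 1:3)
  rep3 <- candidate_report(iv, min_species = 3)
  expect_identical(rep3$asv, c("ASV03", "ASV01"))  # mean positive i desc
  expect_identical(rep3$n_species_positive, c(3L, 3L))

  rep1 <- candidate_report(iv, min_species = 1)
  expect_identical(sort(rep1$asv), c("ASV01", "ASV02", "ASV03"))
  expect_true(is.na(rep1$sp2[rep1$asv == "ASV02"]))  # blank where i <= 0
  expect_equal(rep1$sp1[rep1$asv == "ASV02"], 0.5)

  # monotone: report at S is a subset of the report at S-1
  expect_true(all(rep3$asv %in% candidate_report(iv, min_species = 2)$asv))
  # nothing qualifying gives an empty (not failing) report
  expect_identical(nrow(candidate_report(iv * 0 - 1, min_species = 1)), 0L)

  # taxonomy joins onto the report
  tax <- data.frame(asv = rownames(iv), domain = "Bacteria", phylum = "P",
                    class = "C", order = "O", family = "F",
                    genus = paste0("G", 1:4), stringsAsFactors = FALSE)
  repx <- candidate_report(iv, tax = tax, min_species = 3)
  expect_identical(repx$genus, c("G3", "G1"))
})

test_that("taxon screen reproduces a males-only presence pattern", {
  meta <- balanced_meta(2, 2)
  # ASV1+ASV2 are Staphylococcus; zero reads in every female sample
  counts <- make_counts(rbind(
    ASV1 = c(4L, 2L, 0L, 0L, 3L, 1L, 0L, 0L),
    ASV2 = c(1L, 0L, 0L, 0L, 2L, 2L, 0L, 0L),
    ASV3 = c(5L, 8L, 10L, 10L, 5L, 7L, 10L, 10L)),
    samples = meta$sample)
  tax <- data.frame(asv = paste0("ASV", 1:3), domain = "Bacteria",
                    phylum = c("Bacillota", "Bacillota", "Pseudomonadota"),
                    class = "c", order = "o",
                    family = c("Staphylococcaceae", "Staphylococcaceae", "x"),
                    genus = c("Staphylococcus", "Staphylococcus", "Pseudomonas"),
                    stringsAsFactors = FALSE)
  scr <- taxon_sex_screen(counts, meta, tax, "genus", "Staphylococcus")
  expect_true(all(scr$present[scr$sex == "male"]))
  expect_false(any(scr$present[scr$sex == "female"]))
  expect_true(all(scr$mean_relative_abundance[scr$sex == "female"] == 0))

  # a taxon covering all ASVs has summed relative abundance 1 everywhere
  tax_all <- tax; tax_all$phylum <- "OnePhylum"
  scr <- taxon_sex_screen(counts, meta, tax_all, "phylum", "OnePhylum")
  expect_true(all(abs(scr$mean_relative_abundance - 1) < 1e-12))

  # additivity: re-summing the member ASVs reproduces the screen
  p <- relative_abundance(counts)
  manual <- mean(colSums(p[1:2, meta$sex == "male" &
                             meta$species == "species1"]))
  expect_equal(scr$mean_relative_abundance[1], 1)  # sanity on ordering
  scr_g <- taxon_sex_screen(counts, meta, tax, "genus", "Staphylococcus")
  expect_equal(scr_g$mean_relative_abundance[
    scr_g$species == "species1" & scr_g$sex == "male"], manual)

  expect_error(taxon_sex_screen(counts, meta, tax, "genus", "Borrelia"),
               "not found")
})

test_that("composition aggregation pools minor taxa into Others", {
  counts <- make_counts(matrix(c(900L, 96L, 4L), 3), samples = "S1")
  tax <- data.frame(asv = paste0("ASV", 1:3), domain = "Bacteria",
                    phylum = c("A", "B", "C"), class = "c", order = "o",
                    family = "f", genus = "g", stringsAsFactors = FALSE)
  comp <- aggregate_composition(counts, tax, "phylum",
                                other_threshold = 0.005)
  expect_setequal(rownames(comp), c("A", "B", "Others"))
  expect_equal(comp["Others", "all"], 0.004)
  expect_equal(sum(comp[, "all"]), 1)

  # threshold 0 pools nothing; single taxon sits at 1
  comp0 <- aggregate_composition(counts, tax, "phylum", other_threshold = 0)
  expect_setequal(rownames(comp0), c("A", "B", "C"))
  tax1 <- tax; tax1$phylum <- "Only"
  comp1 <- aggregate_composition(counts, tax1, "phylum", 0.1)
  expect_equal(unname(comp1["Only", "all"]), 1)

  # grouped output sums to 1 per (species, sex) column
  meta <- balanced_meta(2, 2)
  big <- make_counts(matrix(10L + seq_len(3 * 8), 3), samples = meta$sample)
  compg <- aggregate_composition(big, tax, "phylum", 0, meta = meta)
  expect_identical(ncol(compg), 4L)
  expect_true(all(abs(colSums(compg) - 1) < 1e-12))
})
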