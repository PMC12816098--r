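# Dirichlet-multinomial generator of sex-stratified multi-species ASV count
# tables with known male-enrichment spike-ins.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Configuration of the synthetic amplicon dataset generator
#'
#' The defaults emulate a five-species, two-sex, six-replicate 16S study
#' after denoising: heavy-tailed ASV abundances (log-normal Dirichlet base
#' measure), Dirichlet-multinomial replicate scatter, log-normal library
#' sizes in the tens to hundreds of thousands of reads, and two forced
#' very-shallow libraries of 55 and 61 reads (failed samples).
#'
#' @param n_species number of host species.
#' @param replicates biological replicates per sex per species.
#' @param n_asvs number of ASVs.
#' @param concentration Dirichlet concentration of the per-species baseline
#'   composition; smaller values give stronger between-species differences.
#' @param base_sdlog sdlog of the log-normal base measure (heavy tail).
#' @param theta overdispersion of the per-sample Dirichlet-multinomial in
#'   (0, 1); the per-sample composition is Dirichlet with concentration
#'   mu * (1 - theta)/theta, so theta -> 0 degenerates to multinomial.
#' @param shared_spikes data.frame with columns `asv` (indices in
#'   1..n_asvs) and `fold` (>= 1): ASVs enriched in males of every species.
#' @param species_spikes data.frame with columns `species` (1..n_species),
#'   `asv`, `fold`: single-species male enrichments.
#' @param spike_baseline optional proportion; every spiked ASV's baseline
#'   (female) abundance is forced to this value before spiking, so
#'   effect sizes are controlled rather than drawn.
#' @param depth_meanlog,depth_sdlog log-normal library-size model.
#' @param shallow_depths forced shallow library sizes assigned to randomly
#'   chosen samples (empty vector for none).
#' @param seed integer seed of the dataset's single RNG stream.
#' @return list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_species = 5, replicates = 6, n_asvs = 500,
                              concentration = 20, base_sdlog = 2,
                              theta = 0.02,
                              shared_spikes = data.frame(asv = integer(0),
                                                         fold = numeric(0)),
                              species_spikes = data.frame(species = integer(0),
                                                          asv = integer(0),
                                                          fold = numeric(0)),
                              spike_baseline = NULL,
                              depth_meanlog = log(3e4), depth_sdlog = 1,
                              shallow_depths = c(55, 61),
                              seed = 1L) {
  shared_spikes <- as.data.frame(shared_spikes)
  species_spikes <- as.data.frame(species_spikes)
  if (n_species < 1 || replicates < 1 || n_asvs < 2)
    stop("n_species, replicates must be >= 1 and n_asvs >= 2")
  if (theta <= 0 || theta >= 1) stop("theta must lie in (0, 1)")
  if (nrow(shared_spikes) > 0) {
    if (!all(c("asv", "fold") %in% names(shared_spikes)))
      stop("shared_spikes needs columns asv and fold")
    bad <- shared_spikes$asv[shared_spikes$asv < 1 |
                             shared_spikes$asv > n_asvs |
                             shared_spikes$asv != round(shared_spikes$asv)]
    if (length(bad) > 0)
      stop("spike id out of range 1..", n_asvs, ": ",
           paste(bad, collapse = ", "))
    if (any(shared_spikes$fold < 1)) stop("fold-changes must be >= 1")
  }
  if (nrow(species_spikes) > 0) {
    if (!all(c("species", "asv", "fold") %in% names(species_spikes)))
      stop("species_spikes needs columns species, asv and fold")
    if (any(species_spikes$asv < 1 | species_spikes$asv > n_asvs))
      stop("spike id out of range 1..", n_asvs, ": ",
           paste(species_spikes$asv[species_spikes$asv < 1 |
                                    species_spikes$asv > n_asvs],
                 collapse = ", "))
    if (any(species_spikes$species < 1 | species_spikes$species > n_species))
      stop("species_spikes species index out of range")
    if (any(species_spikes$fold < 1)) stop("fold-changes must be >= 1")
  }
  if (!is.null(spike_baseline) &&
      (spike_baseline <= 0 || spike_baseline >= 0.5))
    stop("spike_baseline must lie in (0, 0.5)")
  if (any(shallow_depths < 1)) stop("depths must be >= 1")
  structure(list(n_species = as.integer(n_species),
                 replicates = as.integer(replicates),
                 n_asvs = as.integer(n_asvs),
                 concentration = concentration, base_sdlog = base_sdlog,
                 theta = theta,
                 shared_spikes = shared_spikes,
                 species_spikes = species_spikes,
                 spike_baseline = spike_baseline,
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 shallow_depths = as.integer(shallow_depths),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1  # degenerate tiny-alpha guard
  g / sum(g)
}

# small fixed lineage pool; includes the genera a sex screen is typically
# asked about so taxon-level screens can be exercised by name
lineage_pool <- function() {
  matrix(c(
    "Bacteria", "Actinomycetota", "Actinomycetes", "Propionibacteriales",
      "Propionibacteriaceae", "Cutibacterium",
    "Bacteria", "Bacillota", "Bacilli", "Caryophanales",
      "Staphylococcaceae", "Staphylococcus",
    "Bacteria", "Pseudomonadota", "Gammaproteobacteria", "Enterobacterales",
      "Enterobacteriaceae", "Enterobacter",
    "Bacteria", "Pseudomonadota", "Gammaproteobacteria", "Enterobacterales",
      "Enterobacteriaceae", "Escherichia",
    "Bacteria", "Pseudomonadota", "Gammaproteobacteria", "Pseudomonadales",
      "Pseudomonadaceae", "Pseudomonas",
    "Bacteria", "Pseudomonadota", "Gammaproteobacteria", "Moraxellales",
      "Moraxellaceae", "Acinetobacter",
    "Bacteria", "Bacillota", "Bacilli", "Lactobacillales",
      "Lactobacillaceae", "Lactobacillus",
    "Bacteria", "Bacillota", "Bacilli", "Caryophanales",
      "Bacillaceae", "Bacillus",
    "Bacteria", "Pseudomonadota", "Alphaproteobacteria", "Rickettsiales",
      "Ehrlichiaceae", "Wolbachia",
    "Bacteria", "Mycoplasmatota", "Mollicutes", "Entomoplasmatales",
      "Spiroplasmataceae", "Spiroplasma",
    "Bacteria", "Bacteroidota", "Bacteroidia", "Flavobacteriales",
      "Weeksellaceae", "Chryseobacterium",
    "Bacteria", "unclassified", "unclassified", "unclassified",
      "unclassified", "unclassified"), nrow = 6)
}

#' Simulate a sex-stratified multi-species ASV dataset
#'
#' Per species s, a baseline composition pi_s is drawn from a Dirichlet
#' whose base measure is log-normal (heavy tailed).  Females expect pi_s;
#' males expect pi_s with the spiked entries multiplied by their
#' fold-changes and the vector renormalized.  Each sample then draws a
#' composition from a Dirichlet centred on its group expectation with
#' overdispersion `theta`, and counts from a multinomial at its library
#' size.  Deterministic under the config seed.
#'
#' @param cfg a [simulation_config()].
#' @return list with `counts` (validated count table), `meta`, `tax`,
#'   `tree` (random coalescent over the ASVs), `truth` (spiked ASV ids with
#'   fold-changes and the expected per-group compositions) and `config`.
#' @export
simulate_dataset <- function(cfg) {
  if (!inherits(cfg, "simulation_config")) stop("cfg must be a simulation_config")
  n_asvs <- cfg$n_asvs
  asv_ids <- paste0("ASV", seq_len(n_asvs))
  species <- paste0("species", seq_len(cfg$n_species))
  n_samples <- cfg$n_species * 2L * cfg$replicates

  out <- with_seed(cfg$seed, {
    w <- stats::rlnorm(n_asvs, meanlog = 0, sdlog = cfg$base_sdlog)
    alpha <- cfg$concentration * w / sum(w)

    exp_m <- exp_f <- matrix(NA_real_, n_asvs, cfg$n_species,
                             dimnames = list(asv_ids, species))
    counts <- matrix(0L, n_asvs, n_samples)
    meta <- vector("list", cfg$n_species)
    col <- 0L
    sample_ids <- character(n_samples)

    for (s in seq_len(cfg$n_species)) {
      pi_s <- rdirichlet1(alpha)
      sp_spikes <- cfg$species_spikes[cfg$species_spikes$species == s, ,
                                      drop = FALSE]
      spike_idx <- c(cfg$shared_spikes$asv, sp_spikes$asv)
      spike_fold <- c(cfg$shared_spikes$fold, sp_spikes$fold)
      if (!is.null(cfg$spike_baseline) && length(spike_idx) > 0) {
        pi_s[spike_idx] <- cfg$spike_baseline
        rest <- setdiff(seq_len(n_asvs), spike_idx)
        pi_s[rest] <- pi_s[rest] / sum(pi_s[rest]) *
          (1 - cfg$spike_baseline * length(spike_idx))
      }
      mu_f <- pi_s
      mu_m <- pi_s
      mu_m[spike_idx] <- mu_m[spike_idx] * spike_fold
      mu_m <- mu_m / sum(mu_m)
      exp_f[, s] <- mu_f
      exp_m[, s] <- mu_m

      for (sex in c("male", "female")) {
        mu <- if (sex == "male") mu_m else mu_f
        for (r in seq_len(cfg$replicates)) {
          col <- col + 1L
          depth <- max(1L, round(stats::rlnorm(1, cfg$depth_meanlog,
                                               cfg$depth_sdlog)))
          comp <- rdirichlet1(mu * (1 - cfg$theta) / cfg$theta)
          counts[, col] <- stats::rmultinom(1, depth, comp)[, 1]
          sample_ids[col] <- sprintf("%s_%s_%d", species[s],
                                     if (sex == "male") "M" else "F", r)
        }
      }
      meta[[s]] <- data.frame(
        sample = sample_ids[(col - 2L * cfg$replicates + 1L):col],
        species = species[s],
        sex = rep(c("male", "female"), each = cfg$replicates),
        population = rep(ifelse(seq_len(cfg$replicates) <=
                                  ceiling(cfg$replicates / 2),
                                "pop1", "pop2"), 2),
        stringsAsFactors = FALSE)
    }

    # force the configured shallow library sizes onto random samples by
    # re-subsampling their reads without replacement
    if (length(cfg$shallow_depths) > 0) {
      shallow_at <- sample.int(n_samples, length(cfg$shallow_depths))
      for (q in seq_along(shallow_at)) {
        j <- shallow_at[q]
        d <- min(cfg$shallow_depths[q], sum(counts[, j]))
        counts[, j] <- subsample_without_replacement(counts[, j], d)
      }
    }

    tax_rows <- sample.int(ncol(lineage_pool()), n_asvs, replace = TRUE)
    list(counts = counts, sample_ids = sample_ids,
         meta = do.call(rbind, meta), exp_m = exp_m, exp_f = exp_f,
         tax_rows = tax_rows)
  })

  dimnames(out$counts) <- list(asv_ids, out$sample_ids)
  tax <- data.frame(asv = asv_ids,
                    t(lineage_pool()[, out$tax_rows, drop = FALSE]),
                    stringsAsFactors = FALSE)
  names(tax) <- c("asv", taxonomic_ranks())

  tree <- random_tree(n_asvs, seed = cfg$seed, labels = asv_ids)

  truth <- list(
    shared_spikes = data.frame(asv = asv_ids[cfg$shared_spikes$asv],
                               fold = cfg$shared_spikes$fold,
                               stringsAsFactors = FALSE),
    species_spikes = if (nrow(cfg$species_spikes) > 0)
      data.frame(species = species[cfg$species_spikes$species],
                 asv = asv_ids[cfg$species_spikes$asv],
                 fold = cfg$species_spikes$fold, stringsAsFactors = FALSE)
      else data.frame(species = character(0), asv = character(0),
                      fold = numeric(0)),
    expected_male = out$exp_m, expected_female = out$exp_f,
    seed = cfg$seed)

  list(counts = validate_count_table(out$counts),
       meta = validate_sample_metadata(out$meta),
       tax = validate_taxonomy(tax), tree = tree, truth = truth,
       config = cfg)
}

#' Random coalescent phylogeny over n taxa
#'
#' Rooted bifurcating topology from sequential random coalescence
#' (`ape::rcoal`), reproducible under the seed.
#'
#' @param n_taxa number of leaves (>= 2).
#' @param seed integer seed.
#' @param labels optional leaf labels (default t1..tn).
#' @return a rooted `phylo` object.
#' @export
random_tree <- function(n_taxa, seed = 1L, labels = NULL) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  with_seed(seed, ape::rcoal(n_taxa, tip.label = labels))
}

#' Write a simulated dataset to a fixture directory
#'
#' Emits counts.tsv, metadata.tsv, taxonomy.tsv, tree.nwk, truth.json and
#' config.yaml into `dir` (created if needed).
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir output directory.
#' @return the directory path, invisibly.
#' @export
write_fixtures <- function(dataset, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create fixture directory: ", dir)
  write_count_table(dataset$counts, file.path(dir, "counts.tsv"))
  utils::write.table(dataset$meta, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$tax, file.path(dir, "taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$tree))
    ape::write.tree(dataset$tree, file.path(dir, "tree.nwk"))
  truth <- dataset$truth
  truth$expected_male <- NULL   # large; regenerable from config + seed
  truth$expected_female <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  cfg <- unclass(dataset$config)
  cfg$shared_spikes <- as.list(dataset$config$shared_spikes)
  cfg$species_spikes <- as.list(dataset$config$species_spikes)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a fixture directory back into a dataset bundle
#'
#' @param dir directory written by [write_fixtures()].
#' @return list with `counts`, `meta`, `tax`, `tree` (NULL if absent) and
#'   `truth` (NULL if absent).
#' @export
read_fixtures <- function(dir) {
  if (!dir.exists(dir)) stop("fixture directory not found: ", dir)
  tree_path <- file.path(dir, "tree.nwk")
  truth_path <- file.path(dir, "truth.json")
  truth <- NULL
  if (file.exists(truth_path)) {
    truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    truth$shared_spikes <- as.data.frame(truth$shared_spikes)
    truth$species_spikes <- as.data.frame(truth$species_spikes)
  }
  list(counts = read_count_table(file.path(dir, "counts.tsv")),
       meta = read_sample_metadata(file.path(dir, "metadata.tsv")),
       tax = read_taxonomy(file.path(dir, "taxonomy.tsv")),
       tree = if (file.exists(tree_path)) ape::read.tree(tree_path) else NULL,
       truth = truth)
}
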