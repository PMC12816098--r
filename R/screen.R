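# End-to-end sex-bias screen: exclude -> rarefy -> i matrix -> tally ->
# candidates, packaged as a classed result with print/summary methods.

#' Screen a count table for consistently male-enriched ASVs
#'
#' Runs the full pipeline: samples below the rarefaction depth are excluded,
#' the rest are rarefied to `depth` reads, the i = (M - F)/M index is
#' computed per ASV and species with the pseudocount floor
#' 1/(depth x max_replicates), ASVs are tallied by the number of species in
#' which they are male-enriched, and those positive in at least
#' `min_species` species are reported as candidates.
#'
#' @param counts ASV count table (see [read_count_table()]).
#' @param meta sample metadata (see [read_sample_metadata()]).
#' @param depth rarefaction depth in reads (default 428).
#' @param max_replicates maximum replicates per sex-species combination used
#'   in the floor; by default the maximum group size among the retained
#'   samples.
#' @param min_species candidate threshold; defaults to all species.
#' @param tax optional taxonomy joined onto the candidate report.
#' @param seed rarefaction seed.
#' @param male,female the two sex labels.
#' @return object of class `"sex_bias_screen"`: a list with
#'   `counts_rarefied`, `exclusion`, `floor`, `i` (the
#'   [i_matrix()] result), `tally`, `candidates` and `params`.
#' @seealso [i_index()], [consistency_tally()], [candidate_report()]
#' @export
screen_sex_bias <- function(counts, meta, depth = 428, max_replicates = NULL,
                            min_species = NULL, tax = NULL, seed = 1L,
                            male = "male", female = "female") {
  counts <- validate_count_table(counts)
  meta <- validate_sample_metadata(meta)
  orphan <- setdiff(colnames(counts), meta$sample)
  if (length(orphan) > 0)
    stop("sample(s) without a metadata record: ",
         paste(orphan, collapse = ", "))
  filt <- exclude_low_depth(counts, depth)
  kept <- filt$counts
  kept_meta <- meta[meta$sample %in% colnames(kept), , drop = FALSE]
  if (is.null(max_replicates))
    max_replicates <- max(table(kept_meta$species, kept_meta$sex))
  rar <- rarefy(kept, depth, seed = seed)
  rar <- rar[rowSums(rar) > 0, , drop = FALSE]  # ASVs lost to rarefaction
  fl <- pseudocount_floor(depth, max_replicates)
  im <- i_matrix(rar, kept_meta, fl, male = male, female = female)
  S <- ncol(im$i)
  if (is.null(min_species)) min_species <- S
  structure(list(counts_rarefied = rar,
                 exclusion = filt$exclusion,
                 floor = fl,
                 i = im,
                 tally = consistency_tally(im),
                 candidates = candidate_report(im, tax = tax,
                                               min_species = min_species),
                 params = list(depth = as.integer(depth),
                               max_replicates = as.integer(max_replicates),
                               min_species = as.integer(min_species),
                               seed = as.integer(seed),
                               n_species = S)),
            class = "sex_bias_screen")
}

#' @export
print.sex_bias_screen <- function(x, ...) {
  p <- x$params
  cat("Sex-bias screen of", nrow(x$counts_rarefied), "ASVs across",
      ncol(x$counts_rarefied), "samples\n")
  cat("  rarefaction depth:", p$depth, "reads;",
      nrow(x$exclusion), "sample(s) excluded\n")
  cat(sprintf("  pseudocount floor: 1/%d = %.6g\n",
              as.integer(x$floor$denominator), x$floor$floor))
  cat("  consistency tally (k = species with i > 0):\n")
  cat("   ", paste(sprintf("k=%d: %d", x$tally$k, x$tally$n_asvs),
                   collapse = ", "), "\n")
  cat("  candidates at >=", p$min_species, "of", p$n_species, "species:",
      nrow(x$candidates), "\n")
  invisible(x)
}

#' @export
summary.sex_bias_screen <- function(object, ...) {
  print(object)
  if (nrow(object$candidates) > 0) {
    cat("\nTop candidates:\n")
    print(utils::head(object$candidates[
      c("asv", "n_species_positive", "mean_positive_i")], 10))
  }
  invisible(object)
}

#' Run the screen on a simulated dataset
#'
#' Convenience wrapper applying [screen_sex_bias()] to the bundle returned
#' by [simulate_dataset()].
#'
#' @param dataset list with `counts`, `meta` and optionally `tax`.
#' @param ... passed to [screen_sex_bias()].
#' @return a `"sex_bias_screen"` object.
#' @export
run_screen <- function(dataset, ...) {
  screen_sex_bias(dataset$counts, dataset$meta, tax = dataset$tax, ...)
}

#' Score a candidate report against simulation truth
#'
#' Sensitivity is the fraction of the configured shared spikes that appear
#' in the all-species candidate list; false positives are the non-spiked
#' ASVs that appear there.
#'
#' @param truth the `truth` element of [simulate_dataset()].
#' @param report a [candidate_report()] (or the `candidates` element of a
#'   screen) computed at `min_species = S`.
#' @param S number of species screened.
#' @param asv_ids the ASV universe the report was computed over; used to
#'   verify the truth and report refer to the same dataset.
#' @return data.frame with one row: n_spikes, n_detected, sensitivity,
#'   false_positives.
#' @export
evaluate_recovery <- function(truth, report, S, asv_ids) {
  spikes <- truth$shared_spikes$asv
  if (!all(spikes %in% asv_ids))
    stop("truth spike ASVs not in the screened ASV universe: ",
         paste(setdiff(spikes, asv_ids), collapse = ", "))
  if (nrow(report) > 0 && !all(report$asv %in% asv_ids))
    stop("report ASVs not in the screened ASV universe")
  hits <- report$asv[report$n_species_positive >= S]
  detected <- intersect(spikes, hits)
  data.frame(n_spikes = length(spikes),
             n_detected = length(detected),
             sensitivity = if (length(spikes) > 0)
               length(detected) / length(spikes) else NA_real_,
             false_positives = length(setdiff(hits, spikes)))
}

#' Replicated spike-recovery experiment
#'
#' Simulates `n_runs` datasets from `cfg` with sequential derived seeds
#' (`seed + run index`), screens each, and scores recovery of the shared
#' spikes.
#'
#' @param cfg a [simulation_config()] containing shared spikes.
#' @param n_runs number of replicate runs.
#' @param depth rarefaction depth for the screen.
#' @param seed master seed; run r uses seed + r.
#' @return list of class `"recovery_report"`: `per_run` data.frame (run,
#'   seed, sensitivity, false positives, all-species tally count),
#'   `summary` (means and sds), `config` and `seed`.
#' @export
run_recovery <- function(cfg, n_runs = 100, depth = 428, seed = 1L) {
  if (n_runs < 1) stop("n_runs must be >= 1")
  rows <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run_seed <- as.integer(seed) + r
    cfg_r <- cfg
    cfg_r$seed <- run_seed
    ds <- simulate_dataset(cfg_r)
    scr <- run_screen(ds, depth = depth, seed = run_seed)
    S <- scr$params$n_species
    ev <- evaluate_recovery(ds$truth, scr$candidates, S,
                            rownames(scr$counts_rarefied))
    rows[[r]] <- cbind(data.frame(run = r, seed = run_seed), ev,
                       data.frame(k_all_species =
                                    scr$tally$n_asvs[scr$tally$k == S]))
  }
  per_run <- do.call(rbind, rows)
  structure(list(per_run = per_run,
                 summary = data.frame(
                   metric = c("sensitivity", "false_positives",
                              "k_all_species"),
                   mean = c(mean(per_run$sensitivity),
                            mean(per_run$false_positives),
                            mean(per_run$k_all_species)),
                   sd = c(stats::sd(per_run$sensitivity),
                          stats::sd(per_run$false_positives),
                          stats::sd(per_run$k_all_species))),
                 config = cfg, depth = depth, seed = as.integer(seed)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery report over", nrow(x$per_run), "simulated runs\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Null calibration of the all-species tally
#'
#' Under a spike-free (all fold-changes = 1) configuration, distributes the
#' number of ASVs with i > 0 in all S species across replicate runs — the
#' reference distribution for judging how surprising a small all-species
#' candidate count is.
#'
#' @param cfg a null [simulation_config()] (no spikes); anything else is
#'   refused.
#' @param n_runs number of replicate runs (>= 1).
#' @param depth rarefaction depth for the screen.
#' @param seed master seed; run r uses seed + r.
#' @return list with `counts` (per-run all-species tally), `mean`, `sd` and
#'   `quantiles` (2.5/50/97.5%).
#' @export
null_calibration <- function(cfg, n_runs = 20, depth = 428, seed = 1L) {
  if (n_runs < 1) stop("n_runs must be >= 1")
  if (nrow(cfg$shared_spikes) > 0 || nrow(cfg$species_spikes) > 0)
    stop("not a null configuration: remove the spikes")
  ks <- integer(n_runs)
  for (r in seq_len(n_runs)) {
    run_seed <- as.integer(seed) + r
    cfg_r <- cfg
    cfg_r$seed <- run_seed
    ds <- simulate_dataset(cfg_r)
    scr <- run_screen(ds, depth = depth, seed = run_seed)
    S <- scr$params$n_species
    ks[r] <- scr$tally$n_asvs[scr$tally$k == S]
  }
  list(counts = ks, mean = mean(ks), sd = stats::sd(ks),
       quantiles = stats::quantile(ks, c(0.025, 0.5, 0.975)))
}
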