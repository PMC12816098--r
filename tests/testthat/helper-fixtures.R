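# Small in-code fixtures shared across test files.

make_counts <- function(m, asvs = NULL, samples = NULL) {
  m <- as.matrix(m)
  rownames(m) <- asvs %||% paste0("ASV", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("S", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_meta <- function(samples, species, sex, population = "pop1") {
  data.frame(sample = samples, species = species, sex = sex,
             population = population, stringsAsFactors = FALSE)
}

# random integer count table with uniform-ish entries
random_counts <- function(n_asvs, n_samples, max_count = 50, seed = 1) {
  m <- withr_seed(seed, matrix(sample.int(max_count + 1, n_asvs * n_samples,
                                          replace = TRUE) - 1L,
                               n_asvs, n_samples))
  make_counts(m)
}

# run expr under a seed without disturbing the session RNG
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# balanced two-sex, multi-species metadata matching simulate_dataset naming
balanced_meta <- function(n_species, reps) {
  do.call(rbind, lapply(seq_len(n_species), function(s) {
    make_meta(sprintf("species%d_%s_%d", s,
                      rep(c("M", "F"), each = reps), rep(seq_len(reps), 2)),
              species = sprintf("species%d", s),
              sex = rep(c("male", "female"), each = reps))
  }))
}
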