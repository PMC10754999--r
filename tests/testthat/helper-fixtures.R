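# Shared fixtures, all built in code at test time.

# short grid for fast model/training tests
tiny_grid <- function(n = 16) wn_grid(700, 700 + 4 * (n - 1), 4)

# hand-built dataset: counts and values chosen to be easy to reason about
toy_dataset <- function() {
  g <- tiny_grid(4)
  spectra_tbl(
    sample_id = c("s1", "s1", "s1", "s2", "s3"),
    replicate_id = c(1L, 2L, 3L, 1L, 1L),
    class_label = c("AS", "AS", "AS", "RA", "HC"),
    absorbance = rbind(rep(1, 4), rep(2, 4), rep(3, 4),
                       c(0, 2, 4, 6), c(3, 4, 0, 0)),
    grid = g,
    class_names = c("AS", "RA", "HC")
  )
}

# small synthetic config: full band structure on the default grid but a
# reduced cohort, for io/synth tests that need realistic spectra
small_synth <- function(n = 3L, reps = 2L, seed = 11L) {
  synth_config(n_samples_per_class = n, n_replicates = reps, seed = seed)
}

# separable two-band dataset on a short grid for fast training tests
separable_config <- function(n = 10L, seed = 7L, noise_sd = 0.02) {
  g <- tiny_grid(32)
  bands <- tibble::tibble(center = c(740, 780, 812),
                          width = c(12, 12, 12),
                          base_amplitude = c(1, 0.8, 0.6))
  synth_config(
    grid = g, bands = bands, class_names = c("AS", "RA", "OA", "HC"),
    class_amplitude_scale = 1 + 0.5 * rbind(c(1, -1, 0), c(-1, 1, 0),
                                            c(0, 1, -1), c(-1, 0, 1)),
    n_samples_per_class = n, n_replicates = 1L,
    noise_sd = noise_sd, replicate_jitter_sd = 0,
    sample_scale_sd = 0.02, seed = seed
  )
}

brute_force_auc <- function(score, positive) {
  ps <- score[positive]
  ns <- score[!positive]
  conc <- 0
  for (a in ps) conc <- conc + sum(a > ns) + 0.5 * sum(a == ns)
  conc / (length(ps) * length(ns))
}

# random confusion matrix with balanced row sums
random_balanced_cm <- function(k = 4, n_per_class = 25) {
  counts <- t(vapply(seq_len(k), function(i) {
    as.vector(stats::rmultinom(1, n_per_class, prob = runif(k) + (seq_len(k) == i)))
  }, numeric(k)))
  cls <- LETTERS[seq_len(k)]
  dimnames(counts) <- list(true = cls, predicted = cls)
  structure(list(counts = counts, class_names = cls), class = "confusion_matrix")
}
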