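#' Default serum band table
#'
#' The seven major serum absorption bands used by the synthetic generator:
#' amide A (3280), fatty acids/cholesterol (2940), amide I (1641), amide II
#' (1542), proline/tryptophan (1420), amide III (1245) and the carbohydrate
#' region (1078 cm^-1). Widths are Gaussian sigmas: broad for the two
#' high-wavenumber bands, 20 cm^-1 for the fingerprint region. Base
#' amplitudes give the amide I band the largest peak, as in serum spectra.
#'
#' @return A tibble with columns `center`, `width`, `base_amplitude`.
#' @export
serum_bands <- function() {
  tibble::tibble(
    center = c(3280, 2940, 1641, 1542, 1420, 1245, 1078),
    width = c(60, 60, 20, 20, 20, 20, 20),
    base_amplitude = c(0.90, 0.35, 1.00, 0.70, 0.30, 0.25, 0.20)
  )
}

# Per-class band modulation pattern: rows = classes, columns = bands.
# Entries in {-1, 0, +1}; pairwise-distinct rows so every class pair differs
# on at least one band. Scaled by the preset's `delta` to give
# class_amplitude_scale = 1 + delta * pattern.
class_band_pattern <- function() {
  rbind(
    c( 1, 0, 1, -1, 0, 1, -1),
    c(-1, 1, 0, 1, -1, 0, 1),
    c( 0, -1, 1, 0, 1, -1, 0),
    c( 0, 0, -1, 1, 1, 0, -1)
  )
}

#' Synthetic-dataset configuration
#'
#' Describes a labelled synthetic serum-like FTIR dataset: a wavenumber
#' grid, Gaussian bands, per-class band-amplitude multipliers, cohort shape
#' (samples per class, replicate acquisitions per sample), a quadratic
#' baseline, and three noise scales. Every draw is a pure function of
#' `seed`: each sample owns a derived random stream (class, then sample,
#' then its replicates), so enlarging the cohort does not reshuffle
#' existing samples.
#'
#' @param grid A [wn_grid()]; default 700--4000 cm^-1 at 4 cm^-1.
#' @param bands Tibble of `center`, `width` (Gaussian sigma, cm^-1) and
#'   `base_amplitude`; defaults to [serum_bands()].
#' @param class_names Class labels; default `c("AS","RA","OA","HC")`.
#' @param class_amplitude_scale Numeric matrix, one row per class and one
#'   column per band, multiplying `base_amplitude`.
#' @param n_samples_per_class Samples per class (default 80).
#' @param n_replicates Acquisitions per sample (default 3).
#' @param baseline_slope,baseline_curvature Coefficients of the shared
#'   quadratic baseline in absorbance units across the grid span.
#' @param noise_sd SD of i.i.d. additive Gaussian noise per point.
#' @param replicate_jitter_sd SD of the per-replicate additive offset
#'   (repositioning effect); averaged out by [average_replicates()].
#' @param sample_scale_sd SD of the per-sample multiplicative amplitude
#'   perturbation (biological variation), mean 1.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(grid = wn_grid(),
                         bands = serum_bands(),
                         class_names = c("AS", "RA", "OA", "HC"),
                         class_amplitude_scale = NULL,
                         n_samples_per_class = 80L,
                         n_replicates = 3L,
                         baseline_slope = 0.05,
                         baseline_curvature = 0.02,
                         noise_sd = 0.02,
                         replicate_jitter_sd = 0.01,
                         sample_scale_sd = 0.05,
                         seed = 1L) {
  bands <- tibble::as_tibble(bands)
  stopifnot(all(c("center", "width", "base_amplitude") %in% names(bands)))
  if (any(bands$center < grid$start | bands$center > grid$stop)) {
    rlang::abort("band center outside the wavenumber grid",
                 class = "spectranet_config_error")
  }
  if (any(bands$width <= 0) || any(bands$base_amplitude < 0)) {
    rlang::abort("band widths must be positive and amplitudes non-negative",
                 class = "spectranet_config_error")
  }
  k <- length(class_names)
  if (is.null(class_amplitude_scale)) {
    class_amplitude_scale <- matrix(1, k, nrow(bands))
  }
  class_amplitude_scale <- as.matrix(class_amplitude_scale)
  if (!all(dim(class_amplitude_scale) == c(k, nrow(bands)))) {
    rlang::abort("class_amplitude_scale must be n_classes x n_bands",
                 class = "spectranet_config_error")
  }
  if (n_samples_per_class < 1 || n_replicates < 1) {
    rlang::abort("need at least one sample per class and one replicate",
                 class = "spectranet_config_error")
  }
  if (noise_sd < 0 || replicate_jitter_sd < 0 || sample_scale_sd < 0) {
    rlang::abort("noise scales must be non-negative",
                 class = "spectranet_config_error")
  }
  structure(
    list(grid = grid, bands = bands, class_names = class_names,
         class_amplitude_scale = class_amplitude_scale,
         n_samples_per_class = as.integer(n_samples_per_class),
         n_replicates = as.integer(n_replicates),
         baseline_slope = baseline_slope,
         baseline_curvature = baseline_curvature,
         noise_sd = noise_sd,
         replicate_jitter_sd = replicate_jitter_sd,
         sample_scale_sd = sample_scale_sd,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# delta for the hard preset: calibrated by construction so that the
# root-mean-square per-point distance between noiseless class templates is
# about one noise SD (see the methods vignette for the calibration).
hard_preset_delta <- 0.19
hard_preset_noise_sd <- 0.05

#' Preset synthetic configurations
#'
#' Three calibrated-by-construction study conditions, all with the cohort
#' shape of the emulated study (4 classes x 80 samples x 3 replicates):
#'
#' * `easy` — class band multipliers `1 +/- 0.15`, noise SD 0.02: class
#'   templates are separated by many noise SDs, so the Bayes accuracy is
#'   essentially 1 and a nearest-class-mean rule on noiseless templates is
#'   exact.
#' * `hard` — multipliers `1 +/- 0.19`, noise SD 0.05: template RMS
#'   distances sit between 0.5 and 2 noise SDs per point.
#' * `null` — identical multipliers for all classes: no class signal at
#'   all; any classifier's expected accuracy is 1/4.
#'
#' @param name One of `"easy"`, `"hard"`, `"null"`.
#' @param seed Integer seed stored in the returned config.
#' @return A [synth_config()].
#' @export
synth_preset <- function(name = c("easy", "hard", "null"), seed = 1L) {
  name <- rlang::arg_match(name)
  pat <- class_band_pattern()
  delta <- switch(name, easy = 0.15, hard = hard_preset_delta, null = 0)
  noise <- switch(name, easy = 0.02, hard = hard_preset_noise_sd, null = 0.05)
  synth_config(
    class_amplitude_scale = 1 + delta * pat,
    noise_sd = noise,
    seed = seed
  )
}

#' Noiseless class templates
#'
#' The deterministic part of each class's synthetic spectrum: the band sum
#' scaled by the class multipliers plus the shared baseline — what the
#' generator produces with every noise scale at zero and sample scale 1.
#'
#' @param cfg A [synth_config()].
#' @return Matrix of `length(class_names)` rows by `grid$n_points` columns.
#' @export
class_templates <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  x <- cfg$grid$wavenumbers
  base <- synth_baseline(cfg)
  shapes <- band_shapes(cfg) # n_bands x n_points
  amp <- cfg$class_amplitude_scale * rep(cfg$bands$base_amplitude,
                                         each = nrow(cfg$class_amplitude_scale))
  tmpl <- amp %*% shapes
  sweep(tmpl, 2, base, "+")
}

band_shapes <- function(cfg) {
  x <- cfg$grid$wavenumbers
  t(vapply(seq_len(nrow(cfg$bands)), function(b) {
    exp(-(x - cfg$bands$center[b])^2 / (2 * cfg$bands$width[b]^2))
  }, numeric(length(x))))
}

synth_baseline <- function(cfg) {
  x <- cfg$grid$wavenumbers
  u <- (x - cfg$grid$start) / (cfg$grid$stop - cfg$grid$start)
  cfg$baseline_slope * u + cfg$baseline_curvature * (u - 0.5)^2
}

# Derived 31-bit seed for one sample's private random stream.
sample_stream_seed <- function(seed, class_idx, sample_idx) {
  (as.double(seed) + 1000003 * class_idx + 10007 * sample_idx) %% 2147483647
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic labelled dataset
#'
#' Draws `n_classes x n_samples_per_class x n_replicates` spectra. Each
#' replicate spectrum is the class template scaled by a per-sample
#' multiplicative perturbation, plus a per-replicate additive offset and
#' i.i.d. Gaussian noise per point. The generator is a pure function of the
#' config (including its seed); each sample draws from its own derived
#' stream, so extending the cohort leaves existing samples untouched.
#'
#' @param cfg A [synth_config()].
#' @return A [spectra_tbl()] with sample ids `"<class>_<index>"`.
#' @export
generate_spectra <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  g <- cfg$grid
  shapes <- band_shapes(cfg)
  base <- synth_baseline(cfg)
  k <- length(cfg$class_names)
  n_spec <- k * cfg$n_samples_per_class * cfg$n_replicates
  m <- matrix(NA_real_, n_spec, g$n_points)
  sample_id <- character(n_spec)
  replicate_id <- integer(n_spec)
  class_label <- character(n_spec)
  row <- 0L
  for (ci in seq_len(k)) {
    class_amp <- cfg$class_amplitude_scale[ci, ] * cfg$bands$base_amplitude
    signal <- as.vector(class_amp %*% shapes)
    for (j in seq_len(cfg$n_samples_per_class)) {
      sid <- sprintf("%s_%03d", cfg$class_names[ci], j)
      spectra <- with_local_seed(sample_stream_seed(cfg$seed, ci, j), {
        pert <- max(0.2, stats::rnorm(1, 1, cfg$sample_scale_sd))
        vapply(seq_len(cfg$n_replicates), function(r) {
          offset <- stats::rnorm(1, 0, cfg$replicate_jitter_sd)
          pert * signal + base + offset +
            stats::rnorm(g$n_points, 0, cfg$noise_sd)
        }, numeric(g$n_points))
      })
      for (r in seq_len(cfg$n_replicates)) {
        row <- row + 1L
        m[row, ] <- spectra[, r]
        sample_id[row] <- sid
        replicate_id[row] <- r
        class_label[row] <- cfg$class_names[ci]
      }
    }
  }
  spectra_tbl(sample_id, replicate_id, class_label, m,
              grid = g, class_names = cfg$class_names)
}

#' Read and write synth configs as YAML
#'
#' Serialises every scalar field plus the band table and class scale matrix.
#'
#' @param cfg A [synth_config()].
#' @param path File path.
#' @return `read_synth_config()` returns a [synth_config()];
#'   `write_synth_config()` returns `path` invisibly.
#' @export
write_synth_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "synth_config"))
  obj <- list(
    grid = list(start = cfg$grid$start, stop = cfg$grid$stop, step = cfg$grid$step),
    bands = lapply(seq_len(nrow(cfg$bands)), function(i) as.list(cfg$bands[i, ])),
    class_names = as.list(cfg$class_names),
    class_amplitude_scale = lapply(seq_len(nrow(cfg$class_amplitude_scale)),
                                   function(i) as.list(cfg$class_amplitude_scale[i, ])),
    n_samples_per_class = cfg$n_samples_per_class,
    n_replicates = cfg$n_replicates,
    baseline_slope = cfg$baseline_slope,
    baseline_curvature = cfg$baseline_curvature,
    noise_sd = cfg$noise_sd,
    replicate_jitter_sd = cfg$replicate_jitter_sd,
    sample_scale_sd = cfg$sample_scale_sd,
    seed = cfg$seed
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  obj <- tryCatch(yaml::read_yaml(path), error = function(e) {
    rlang::abort(paste0("cannot parse config file: ", conditionMessage(e)),
                 class = "spectranet_config_error")
  })
  need <- c("grid", "class_names", "seed")
  missing_keys <- setdiff(need, names(obj))
  if (length(missing_keys) > 0) {
    rlang::abort(paste0("config is missing key(s): ",
                        paste(missing_keys, collapse = ", ")),
                 class = "spectranet_config_error")
  }
  bands <- if (is.null(obj$bands)) serum_bands() else dplyr::bind_rows(obj$bands)
  scale <- if (is.null(obj$class_amplitude_scale)) NULL else {
    do.call(rbind, lapply(obj$class_amplitude_scale, unlist))
  }
  synth_config(
    grid = wn_grid(obj$grid$start, obj$grid$stop, obj$grid$step),
    bands = bands,
    class_names = unlist(obj$class_names),
    class_amplitude_scale = scale,
    n_samples_per_class = obj$n_samples_per_class %||% 80L,
    n_replicates = obj$n_replicates %||% 3L,
    baseline_slope = obj$baseline_slope %||% 0.05,
    baseline_curvature = obj$baseline_curvature %||% 0.02,
    noise_sd = obj$noise_sd %||% 0.02,
    replicate_jitter_sd = obj$replicate_jitter_sd %||% 0.01,
    sample_scale_sd = obj$sample_scale_sd %||% 0.05,
    seed = obj$seed
  )
}
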