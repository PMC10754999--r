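#' Spectra tables
#'
#' A spectra table (`spectra_tbl`) is a tibble with one row per acquired
#' spectrum and columns `sample_id` (character), `replicate_id` (integer),
#' `class_label` (factor over the dataset's class names) and `absorbance`
#' (a numeric matrix column, one row per spectrum, one column per grid
#' point). The wavenumber grid travels with the table as the `grid`
#' attribute so that downstream stages can refuse silently mismatched axes.
#'
#' @param sample_id Character vector of sample identifiers.
#' @param replicate_id Integer vector of replicate indices within sample.
#' @param class_label Vector of class labels (coerced to factor over
#'   `class_names`).
#' @param absorbance Numeric matrix, `length(sample_id)` rows and
#'   `grid$n_points` columns.
#' @param grid A [wn_grid()].
#' @param class_names Optional explicit class order; defaults to the sorted
#'   unique labels. The first four serum classes are conventionally ordered
#'   AS, RA, OA, HC in reports.
#'
#' @return A `spectra_tbl`.
#' @export
spectra_tbl <- function(sample_id, replicate_id, class_label, absorbance,
                        grid, class_names = NULL) {
  stopifnot(inherits(grid, "wn_grid"))
  absorbance <- as.matrix(absorbance)
  n <- length(sample_id)
  if (n > 0 && nrow(absorbance) != n) {
    rlang::abort("absorbance must have one row per spectrum",
                 class = "spectranet_axis_error")
  }
  if (n > 0 && ncol(absorbance) != grid$n_points) {
    rlang::abort(
      sprintf("absorbance has %d points but the grid has %d",
              ncol(absorbance), grid$n_points),
      class = "spectranet_axis_error"
    )
  }
  if (n > 0 && !all(is.finite(absorbance))) {
    rlang::abort("absorbance values must be finite",
                 class = "spectranet_parse_error")
  }
  if (is.null(class_names)) {
    # order of first appearance, so generated/written datasets keep their
    # reporting order (AS, RA, OA, HC for the serum classes)
    class_names <- if (is.factor(class_label)) levels(class_label)
                   else unique(as.character(class_label))
  }
  lab <- factor(as.character(class_label), levels = class_names)
  if (n > 0 && anyNA(lab)) {
    bad <- setdiff(unique(as.character(class_label)), class_names)
    rlang::abort(paste0("class labels outside class_names: ",
                        paste(bad, collapse = ", ")),
                 class = "spectranet_label_error")
  }
  key <- paste(sample_id, replicate_id, sep = "\r")
  if (anyDuplicated(key)) {
    rlang::abort("sample_id x replicate_id pairs must be unique",
                 class = "spectranet_label_error")
  }
  colnames(absorbance) <- NULL
  out <- tibble::tibble(
    sample_id = as.character(sample_id),
    replicate_id = as.integer(replicate_id),
    class_label = lab
  )
  out$absorbance <- absorbance
  new_spectra_tbl(out, grid, class_names)
}

new_spectra_tbl <- function(tbl, grid, class_names) {
  structure(tbl,
            grid = grid,
            class_names = class_names,
            class = c("spectra_tbl", class(tibble::tibble())))
}

#' Grid and class accessors for spectra tables
#' @param ds A `spectra_tbl`.
#' @return `spectra_grid()` returns the [wn_grid()]; `class_names()` the
#'   ordered class labels; `absorbance_matrix()` the n-spectra x n-points
#'   numeric matrix.
#' @export
spectra_grid <- function(ds) attr(ds, "grid", exact = TRUE)

#' @rdname spectra_grid
#' @export
class_names <- function(ds) attr(ds, "class_names", exact = TRUE)

#' @rdname spectra_grid
#' @export
absorbance_matrix <- function(ds) {
  m <- ds$absorbance
  dimnames(m) <- NULL
  m
}

#' @export
print.spectra_tbl <- function(x, ...) {
  g <- spectra_grid(x)
  cat(sprintf("# spectra_tbl: %d spectra, %d samples, grid %g-%g cm^-1 (%d pts)\n",
              nrow(x), dplyr::n_distinct(x$sample_id), g$start, g$stop, g$n_points))
  cat("# classes:", paste(class_names(x), collapse = ", "), "\n")
  print(tibble::as_tibble(x), ...)
  invisible(x)
}

#' Average replicate acquisitions
#'
#' Serum spectra are acquired several times at different positions on the
#' sample spot; the per-sample spectrum is their unweighted pointwise mean.
#' Averaging an already-averaged table is the identity.
#'
#' @param ds A `spectra_tbl`.
#' @return A `spectra_tbl` with one spectrum per `sample_id`
#'   (`replicate_id = 1`), class labels preserved.
#' @export
average_replicates <- function(ds) {
  stopifnot(inherits(ds, "spectra_tbl"))
  lab_by_sample <- tapply(as.character(ds$class_label), ds$sample_id,
                          function(x) unique(x), simplify = FALSE)
  n_lab <- vapply(lab_by_sample, length, integer(1))
  if (any(n_lab > 1)) {
    rlang::abort(paste0("conflicting class labels within sample(s): ",
                        paste(names(n_lab)[n_lab > 1], collapse = ", ")),
                 class = "spectranet_label_error")
  }
  ids <- unique(ds$sample_id)
  m <- absorbance_matrix(ds)
  grp <- match(ds$sample_id, ids)
  sums <- rowsum(m, grp, reorder = TRUE)
  counts <- tabulate(grp, nbins = length(ids))
  avg <- sums / counts
  spectra_tbl(
    sample_id = ids,
    replicate_id = rep(1L, length(ids)),
    class_label = vapply(lab_by_sample[ids], identity, character(1)),
    absorbance = avg,
    grid = spectra_grid(ds),
    class_names = class_names(ds)
  )
}

#' Per-spectrum normalisation
#'
#' Optional per-spectrum rescaling. The default pipeline applies none:
#' replicate averaging is the only preprocessing step, and absorbance units
#' are treated as arbitrary. `minmax` maps each spectrum onto \[0, 1\];
#' `vector` scales each spectrum to unit Euclidean norm. A constant (or
#' all-zero) spectrum cannot be rescaled and is returned as all zeros with
#' a warning.
#'
#' @param ds A `spectra_tbl`.
#' @param method One of `"none"`, `"minmax"`, `"vector"`.
#' @return A `spectra_tbl` of the same shape.
#' @export
normalize_spectra <- function(ds, method = c("none", "minmax", "vector")) {
  method <- rlang::arg_match(method)
  stopifnot(inherits(ds, "spectra_tbl"))
  if (method == "none" || nrow(ds) == 0) return(ds)
  m <- absorbance_matrix(ds)
  if (method == "minmax") {
    lo <- apply(m, 1, min)
    hi <- apply(m, 1, max)
    rng <- hi - lo
    flat <- rng == 0
    if (any(flat)) {
      rlang::warn(sprintf("%d constant spectrum/spectra mapped to all zeros under minmax",
                          sum(flat)))
      rng[flat] <- 1
    }
    m <- (m - lo) / rng
    m[flat, ] <- 0
  } else {
    nrm <- sqrt(rowSums(m^2))
    zero <- nrm == 0
    if (any(zero)) {
      rlang::warn(sprintf("%d zero spectrum/spectra left as zeros under vector normalisation",
                          sum(zero)))
      nrm[zero] <- 1
    }
    m <- m / nrm
  }
  ds$absorbance <- m
  ds
}

#' Class mean spectra with min--max envelopes
#'
#' Per-class pointwise mean absorbance plus the pointwise minimum and
#' maximum over that class's spectra, in long (tidy) form — the quantities
#' drawn as lines and shaded envelopes in average-spectrum figures.
#'
#' @param ds A `spectra_tbl` with at least one spectrum in every class that
#'   appears in `class_names(ds)` and is present in the data.
#' @return A tibble with columns `class_label`, `wavenumber`, `mean`,
#'   `lower`, `upper`.
#' @export
mean_spectrum_by_class <- function(ds) {
  stopifnot(inherits(ds, "spectra_tbl"))
  if (nrow(ds) == 0) {
    rlang::abort("no spectra to average", class = "spectranet_data_error")
  }
  g <- spectra_grid(ds)
  m <- absorbance_matrix(ds)
  missing_cl <- setdiff(class_names(ds), as.character(ds$class_label))
  if (length(missing_cl) > 0) {
    rlang::abort(paste0("class(es) with no spectra: ",
                        paste(missing_cl, collapse = ", ")),
                 class = "spectranet_data_error")
  }
  purrr::map_dfr(class_names(ds), function(cl) {
    rows <- which(as.character(ds$class_label) == cl)
    sub <- m[rows, , drop = FALSE]
    tibble::tibble(
      class_label = factor(cl, levels = class_names(ds)),
      wavenumber = g$wavenumbers,
      mean = colMeans(sub),
      lower = apply(sub, 2, min),
      upper = apply(sub, 2, max)
    )
  })
}
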