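#' Read spectra from disk
#'
#' Three plain-text dialects are supported:
#'
#' * `csv_wide` — header `sample_id,replicate_id,class_label` followed by one
#'   column per wavenumber (the column name is the wavenumber); one row per
#'   spectrum.
#' * `csv_long` — columns `sample_id,replicate_id,class_label,wavenumber,absorbance`.
#' * `jcampdx` — a minimal single-spectrum JCAMP-DX reader honouring
#'   `##XUNITS`, `##NPOINTS`, `##FIRSTX`, `##LASTX`, `##XFACTOR`, `##YFACTOR`
#'   and `##XYDATA=(X++(Y..Y))` tables; any other data-table form is an
#'   unsupported-record error.
#'
#' The wavenumber axis is inferred from the file. Files with a descending
#' axis are reversed on read (a message notes the flip); internally the axis
#' is always stored ascending. Spectra whose axis length disagrees with the
#' file's declared axis are an error — never silently resampled.
#'
#' @param path File path.
#' @param format One of `"csv_wide"`, `"csv_long"`, `"jcampdx"`.
#' @param class_names Optional explicit class order.
#' @return A [spectra_tbl()].
#' @export
read_spectra <- function(path, format = c("csv_wide", "csv_long", "jcampdx"),
                         class_names = NULL) {
  format <- rlang::arg_match(format)
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "spectranet_io_error")
  }
  switch(format,
    csv_wide = read_csv_wide(path, class_names),
    csv_long = read_csv_long(path, class_names),
    jcampdx  = read_jcampdx(path, class_names)
  )
}

id_cols <- c("sample_id", "replicate_id", "class_label")

read_csv_wide <- function(path, class_names) {
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (length(hdr) < 5 || !identical(hdr[1:3], id_cols)) {
    rlang::abort("csv_wide header must start with sample_id,replicate_id,class_label",
                 class = "spectranet_parse_error")
  }
  wn <- suppressWarnings(as.numeric(hdr[-(1:3)]))
  if (anyNA(wn)) {
    rlang::abort("csv_wide wavenumber columns must be numeric",
                 class = "spectranet_parse_error")
  }
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = c(
    sample_id = "character", replicate_id = "integer", class_label = "character"
  ))
  if (ncol(raw) != length(hdr)) {
    rlang::abort("csv_wide rows do not match the declared axis length",
                 class = "spectranet_axis_error")
  }
  g <- grid_from_axis(wn)
  m <- as.matrix(raw[, -(1:3), drop = FALSE])
  if (nrow(raw) > 0) {
    if (!is.numeric(m)) {
      bad <- which(!apply(raw[, -(1:3), drop = FALSE], 1,
                          function(r) all(!is.na(suppressWarnings(as.numeric(r))))))
      rlang::abort(paste0("non-numeric absorbance in data row(s): ",
                          paste(utils::head(bad, 5), collapse = ", ")),
                   class = "spectranet_parse_error")
    }
    if (anyNA(m)) {
      rlang::abort(paste0("axis mismatch: row(s) shorter than the declared axis: ",
                          paste(utils::head(which(rowSums(is.na(m)) > 0), 5),
                                collapse = ", ")),
                   class = "spectranet_axis_error")
    }
  }
  if (isTRUE(attr(g, "was_descending"))) {
    message("wavenumber axis was descending; reversed to ascending on read")
    m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  }
  spectra_tbl(raw$sample_id, raw$replicate_id, raw$class_label, m,
              grid = g, class_names = class_names)
}

read_csv_long <- function(path, class_names) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           sample_id = readr::col_character(),
                           replicate_id = readr::col_integer(),
                           class_label = readr::col_character(),
                           wavenumber = readr::col_double(),
                           absorbance = readr::col_double()
                         ))
  need <- c(id_cols, "wavenumber", "absorbance")
  if (!all(need %in% names(raw))) {
    rlang::abort(paste0("csv_long must have columns ", paste(need, collapse = ", ")),
                 class = "spectranet_parse_error")
  }
  if (anyNA(raw$absorbance)) {
    rlang::abort("non-numeric absorbance in csv_long file",
                 class = "spectranet_parse_error")
  }
  if (nrow(raw) == 0) {
    rlang::abort("csv_long file has no data rows; an empty dataset needs csv_wide",
                 class = "spectranet_parse_error")
  }
  key <- paste(raw$sample_id, raw$replicate_id, sep = "\r")
  ids <- unique(key)
  first_axis <- sort(raw$wavenumber[key == ids[1]])
  per <- split(seq_len(nrow(raw)), factor(key, levels = ids))
  lens <- vapply(per, length, integer(1))
  if (any(lens != length(first_axis))) {
    rlang::abort("spectra in csv_long file have differing axis lengths",
                 class = "spectranet_axis_error")
  }
  g <- grid_from_axis(first_axis)
  m <- matrix(NA_real_, length(ids), g$n_points)
  meta <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    rows <- per[[i]]
    o <- order(raw$wavenumber[rows])
    wn_i <- raw$wavenumber[rows][o]
    if (max(abs(wn_i - g$wavenumbers)) > 1e-6 * max(abs(g$wavenumbers))) {
      rlang::abort("spectra in csv_long file are on different wavenumber axes",
                   class = "spectranet_axis_error")
    }
    m[i, ] <- raw$absorbance[rows][o]
    meta[[i]] <- raw[rows[1], id_cols]
  }
  meta <- dplyr::bind_rows(meta)
  spectra_tbl(meta$sample_id, meta$replicate_id, meta$class_label, m,
              grid = g, class_names = class_names)
}

jdx_field <- function(lines, key) {
  # literal prefix match: JCAMP keys may contain regex metacharacters ($)
  hit <- lines[startsWith(lines, paste0("##", key, "="))]
  if (length(hit) == 0) return(NULL)
  trimws(sub("^##[^=]+=", "", hit[1]))
}

read_jcampdx <- function(path, class_names) {
  lines <- readLines(path)
  xy_at <- grep("^##XYDATA\\s*=", lines)
  if (length(xy_at) != 1) {
    rlang::abort("expected exactly one ##XYDATA record",
                 class = "spectranet_parse_error")
  }
  form <- trimws(sub("^##XYDATA\\s*=", "", lines[xy_at]))
  if (gsub("\\s", "", form) != "(X++(Y..Y))") {
    rlang::abort(paste0("unsupported JCAMP-DX data form: ", form),
                 class = "spectranet_parse_error")
  }
  npoints <- as.integer(jdx_field(lines, "NPOINTS"))
  xfactor <- as.numeric(jdx_field(lines, "XFACTOR") %||% "1")
  yfactor <- as.numeric(jdx_field(lines, "YFACTOR") %||% "1")
  firstx <- as.numeric(jdx_field(lines, "FIRSTX"))
  lastx <- as.numeric(jdx_field(lines, "LASTX"))
  title <- jdx_field(lines, "TITLE") %||% "jcampdx"
  label <- jdx_field(lines, "$CLASSLABEL") %||% "unlabelled"
  if (is.na(npoints) || is.null(npoints)) {
    rlang::abort("##NPOINTS is required", class = "spectranet_parse_error")
  }
  body <- lines[(xy_at + 1):length(lines)]
  end_at <- grep("^##", body)
  if (length(end_at) > 0) body <- body[seq_len(end_at[1] - 1L)]
  y <- numeric(0)
  for (ln in body) {
    tok <- strsplit(trimws(ln), "[,[:space:]]+")[[1]]
    tok <- tok[nzchar(tok)]
    if (length(tok) < 2) next
    vals <- suppressWarnings(as.numeric(tok))
    if (anyNA(vals)) {
      rlang::abort(paste0("non-numeric value in XYDATA line: ", ln),
                   class = "spectranet_parse_error")
    }
    y <- c(y, vals[-1]) # first token is the line's X; rest are ordinates
  }
  if (length(y) != npoints) {
    rlang::abort(sprintf("XYDATA has %d ordinates but ##NPOINTS=%d",
                         length(y), npoints),
                 class = "spectranet_axis_error")
  }
  wn <- seq(firstx * xfactor, lastx * xfactor, length.out = npoints)
  g <- grid_from_axis(wn)
  absorb <- matrix(y * yfactor, nrow = 1)
  if (isTRUE(attr(g, "was_descending"))) {
    message("wavenumber axis was descending; reversed to ascending on read")
    absorb <- absorb[, rev(seq_len(ncol(absorb))), drop = FALSE]
  }
  spectra_tbl(title, 1L, label, absorb, grid = g, class_names = class_names)
}

#' Write spectra to disk
#'
#' Inverse of [read_spectra()]: `read_spectra(write_spectra(ds))` reproduces
#' absorbance to better than 1e-9 relative error and identifiers exactly
#' (values are written with 12 significant digits). The `jcampdx` dialect is
#' single-spectrum, so it only accepts a one-row table.
#'
#' @param ds A [spectra_tbl()].
#' @param path Output file path.
#' @param format One of `"csv_wide"`, `"csv_long"`, `"jcampdx"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(ds, path, format = c("csv_wide", "csv_long", "jcampdx")) {
  format <- rlang::arg_match(format)
  stopifnot(inherits(ds, "spectra_tbl"))
  if (!dir.exists(dirname(path))) {
    rlang::abort(paste0("directory does not exist: ", dirname(path)),
                 class = "spectranet_io_error")
  }
  g <- spectra_grid(ds)
  m <- absorbance_matrix(ds)
  if (format == "csv_wide") {
    hdr <- paste(c(id_cols, format(g$wavenumbers, trim = TRUE, digits = 12,
                                   scientific = FALSE)), collapse = ",")
    rows <- character(nrow(ds))
    for (i in seq_len(nrow(ds))) {
      rows[i] <- paste(c(ds$sample_id[i], ds$replicate_id[i],
                         as.character(ds$class_label[i]),
                         format(m[i, ], trim = TRUE, digits = 12)), collapse = ",")
    }
    writeLines(c(hdr, rows), path)
  } else if (format == "csv_long") {
    if (nrow(ds) == 0) {
      rlang::abort("csv_long cannot represent an empty dataset; use csv_wide",
                   class = "spectranet_io_error")
    }
    long <- tibble::tibble(
      sample_id = rep(ds$sample_id, each = g$n_points),
      replicate_id = rep(ds$replicate_id, each = g$n_points),
      class_label = rep(as.character(ds$class_label), each = g$n_points),
      wavenumber = rep(g$wavenumbers, nrow(ds)),
      absorbance = as.vector(t(m))
    )
    readr::write_csv(long, path)
  } else {
    if (nrow(ds) != 1) {
      rlang::abort("jcampdx files hold exactly one spectrum",
                   class = "spectranet_io_error")
    }
    lines <- c(
      paste0("##TITLE=", ds$sample_id[1]),
      "##JCAMP-DX=4.24",
      "##DATA TYPE=INFRARED SPECTRUM",
      "##XUNITS=1/CM",
      "##YUNITS=ABSORBANCE",
      paste0("##$CLASSLABEL=", as.character(ds$class_label[1])),
      paste0("##FIRSTX=", format(g$wavenumbers[1], digits = 12)),
      paste0("##LASTX=", format(g$wavenumbers[g$n_points], digits = 12)),
      "##XFACTOR=1",
      "##YFACTOR=1",
      paste0("##NPOINTS=", g$n_points),
      "##XYDATA=(X++(Y..Y))"
    )
    y <- m[1, ]
    per_line <- 6L
    starts <- seq(1, g$n_points, by = per_line)
    data_lines <- vapply(starts, function(s) {
      e <- min(s + per_line - 1L, g$n_points)
      paste(c(format(g$wavenumbers[s], trim = TRUE, digits = 12),
              format(y[s:e], trim = TRUE, digits = 12)), collapse = " ")
    }, character(1))
    writeLines(c(lines, data_lines, "##END="), path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
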