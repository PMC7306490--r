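# Plain-text recording and manifest formats.
#
# A recording file is a comma-delimited numeric table, one column per
# (site, wavelength) pair named e.g. "LE_660", one row per sample,
# preceded by a commented header block:
#
#   # subject_id: S001
#   # group: healthy
#   # fs: 31.25
#   # sites: LE,RE,LF,RF,LT,RT
#   # wavelengths: 660,920
#
# A cohort manifest is a YAML file with free-form `metadata` and an
# `entries` list of (subject_id, group, file) records; file paths are
# resolved relative to the manifest location.

#' Construct a raw oximetry recording
#'
#' Bundles per-site dual-wavelength light-intensity traces with their
#' sampling metadata and validates the container invariants: equal trace
#' lengths across all site/wavelength channels, strictly positive
#' samples (a logarithm is taken downstream by the Beer-Lambert
#' conversion), and a positive sampling rate.
#'
#' @param subject_id character scalar.
#' @param group_label one of `"healthy"`, `"stroke"`, `"unknown"`.
#' @param fs sampling rate in Hz (default 31.25, the acquisition rate of
#'   the multichannel oximeter).
#' @param intensity named list, one element per site (in `SLFO_SITES`
#'   order), each a numeric matrix with columns `"660"` and `"920"`
#'   holding the light-intensity samples in device units.
#' @return object of class `raw_recording` with fields `subject_id`,
#'   `group_label`, `fs`, `sites`, `intensity`, `duration` (seconds).
#' @export
raw_recording <- function(subject_id, group_label = "unknown", fs = 31.25,
                          intensity = list()) {
  group_label <- match.arg(group_label, c("healthy", "stroke", "unknown"))
  if (!is.character(subject_id) || length(subject_id) != 1L || !nzchar(subject_id))
    stop_param("subject_id must be a non-empty string")
  if (!is.numeric(fs) || fs <= 0) stop_param("fs must be > 0")
  if (length(intensity) == 0L) stop_param("intensity must contain at least one site")
  sites <- names(intensity)
  if (is.null(sites) || !all(sites %in% SLFO_SITES))
    stop_param("intensity must be named with sites among: %s",
               paste(SLFO_SITES, collapse = ", "))
  if (anyDuplicated(sites)) stop_param("duplicate site in intensity")
  lens <- integer(0)
  for (s in sites) {
    m <- intensity[[s]]
    if (!is.matrix(m) || !all(c("660", "920") %in% colnames(m)))
      stop_param("intensity[['%s']] must be a matrix with columns '660' and '920'", s)
    intensity[[s]] <- m[, c("660", "920"), drop = FALSE]
    lens <- c(lens, nrow(m))
    bad <- which(!(is.finite(m) & m > 0))
    if (length(bad))
      stop_param("non-positive or non-finite intensity in site %s at sample index %d",
                 s, ((bad[1] - 1L) %% nrow(m)) + 1L)
  }
  if (length(unique(lens)) != 1L)
    stop_param("all site/wavelength traces must have equal length (got %s)",
               paste(unique(lens), collapse = ", "))
  structure(
    list(subject_id = subject_id, group_label = group_label, fs = fs,
         sites = sites, intensity = intensity, duration = lens[1] / fs),
    class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> subject %s (%s): %d sites, %.4g s at %g Hz\n",
              x$subject_id, x$group_label, length(x$sites), x$duration, x$fs))
  invisible(x)
}

#' Write a recording to a delimited text file
#'
#' Emits the commented header block followed by one CSV row per sample,
#' 12 significant digits per value. Output bytes are deterministic for
#' identical input.
#'
#' @param rec a `raw_recording`.
#' @param path output file path.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  if (length(rec$sites) == 0L) stop_param("recording has an empty sites list")
  cols <- unlist(lapply(rec$sites, function(s) paste(s, c("660", "920"), sep = "_")))
  mat <- do.call(cbind, lapply(rec$sites, function(s) rec$intensity[[s]]))
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- c(sprintf("# subject_id: %s", rec$subject_id),
           sprintf("# group: %s", rec$group_label),
           sprintf("# fs: %.12g", rec$fs),
           sprintf("# sites: %s", paste(rec$sites, collapse = ",")),
           "# wavelengths: 660,920",
           paste(cols, collapse = ","))
  writeLines(hdr, con, sep = "\n")
  body <- apply(mat, 1L, function(r) paste(sprintf("%.12g", r), collapse = ","))
  writeLines(body, con, sep = "\n")
  invisible(path)
}

#' Read a recording file
#'
#' Parses the header block and numeric body written by
#' [write_recording()]. Malformed headers, ragged rows and non-positive
#' samples are rejected with errors naming the offending line or row.
#'
#' @param path file path.
#' @return a validated `raw_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop_param("recording file not found: %s", path)
  lines <- readLines(path)
  is_hdr <- grepl("^#", lines)
  n_hdr <- match(FALSE, is_hdr) - 1L
  if (is.na(n_hdr) || n_hdr < 1L)
    stop_param("malformed header in %s: no commented header block", path)
  hdr <- lines[seq_len(n_hdr)]
  get_field <- function(key) {
    ln <- grep(sprintf("^#\\s*%s\\s*:", key), hdr)
    if (length(ln) != 1L)
      stop_param("malformed header in %s: field '%s' missing or duplicated (header line %s)",
                 path, key, paste(ln, collapse = ","))
    sub(sprintf("^#\\s*%s\\s*:\\s*", key), "", hdr[ln])
  }
  fs <- suppressWarnings(as.numeric(get_field("fs")))
  if (!is.finite(fs) || fs <= 0)
    stop_param("malformed header in %s: fs is not a positive number", path)
  sites <- strsplit(get_field("sites"), ",")[[1]]
  wls <- strsplit(get_field("wavelengths"), ",")[[1]]
  if (!identical(sort(wls), c("660", "920")))
    stop_param("malformed header in %s: wavelengths must be 660,920", path)
  col_names <- strsplit(lines[n_hdr + 1L], ",")[[1]]
  expected <- unlist(lapply(sites, function(s) paste(s, wls, sep = "_")))
  if (!identical(col_names, expected))
    stop_param("malformed header in %s: column header (line %d) does not match sites/wavelengths",
               path, n_hdr + 1L)
  body <- lines[-seq_len(n_hdr + 1L)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != length(col_names)))
    stop_param("ragged row in %s: data row %d has %d fields, expected %d",
               path, which(nf != length(col_names))[1], nf[nf != length(col_names)][1],
               length(col_names))
  mat <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                nrow = length(body), byrow = TRUE,
                dimnames = list(NULL, col_names))
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop_param("non-numeric value in %s at data row %d, column %s",
               path, bad[1], col_names[bad[2]])
  }
  bad <- which(mat <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop_param("validation error in %s: non-positive intensity at data row %d, column %s",
               path, bad[1, 1], col_names[bad[1, 2]])
  intensity <- setNames(lapply(sites, function(s) {
    m <- mat[, paste(s, wls, sep = "_"), drop = FALSE]
    colnames(m) <- wls
    m
  }), sites)
  raw_recording(subject_id = get_field("subject_id"),
                group_label = get_field("group"),
                fs = fs, intensity = intensity)
}

#' Construct a cohort manifest
#'
#' @param entries data.frame with columns `subject_id`, `group`, `file`.
#' @param metadata named list of free-form key/value metadata.
#' @export
cohort_manifest <- function(entries, metadata = list()) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (nrow(entries)) {
    stopifnot(all(c("subject_id", "group", "file") %in% names(entries)))
    dup <- entries$subject_id[duplicated(entries$subject_id)]
    if (length(dup))
      stop_param("duplicate subject_id in manifest: %s", dup[1])
    if (!all(entries$group %in% c("healthy", "stroke", "unknown")))
      stop_param("manifest group labels must be healthy/stroke/unknown")
  } else {
    entries <- data.frame(subject_id = character(), group = character(),
                          file = character(), stringsAsFactors = FALSE)
  }
  structure(list(entries = entries, metadata = metadata),
            class = "cohort_manifest")
}

#' Write a cohort manifest as YAML
#' @param manifest a `cohort_manifest`.
#' @param path output path; entry file paths are stored as given.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  obj <- list(
    metadata = manifest$metadata,
    entries = lapply(seq_len(nrow(manifest$entries)), function(i) {
      as.list(manifest$entries[i, c("subject_id", "group", "file")])
    }))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a cohort manifest
#'
#' Duplicate subject ids are rejected; each referenced recording file is
#' resolved relative to the manifest directory and must exist.
#'
#' @param path manifest path.
#' @param check_files verify that referenced recordings exist (default
#'   TRUE).
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop_param("manifest not found: %s", path)
  obj <- yaml::read_yaml(path)
  entries <- obj$entries %||% list()
  df <- if (length(entries)) {
    data.frame(
      subject_id = vapply(entries, function(e) as.character(e$subject_id), ""),
      group = vapply(entries, function(e) as.character(e$group %||% "unknown"), ""),
      file = vapply(entries, function(e) as.character(e$file), ""),
      stringsAsFactors = FALSE)
  } else {
    data.frame(subject_id = character(), group = character(),
               file = character(), stringsAsFactors = FALSE)
  }
  if (nrow(df)) {
    resolved <- ifelse(grepl("^(/|[A-Za-z]:)", df$file), df$file,
                       file.path(dirname(path), df$file))
    if (check_files) {
      missing <- resolved[!file.exists(resolved)]
      if (length(missing))
        stop_param("manifest references missing file(s): %s",
                   paste(missing, collapse = ", "))
    }
    df$file <- resolved
  }
  cohort_manifest(df, metadata = obj$metadata %||% list())
}
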