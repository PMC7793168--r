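# Delimited-text I/O. Doubles are written as "%.17g" so that write/read
# round trips are bit-exact.

write_numeric_tsv <- function(m, path) {
  m <- as.matrix(m)
  lines <- apply(m, 1, function(r) paste(fmt_double(r), collapse = "\t"))
  writeLines(lines, path)
}

read_numeric_tsv <- function(path) {
  lines <- readLines(path)
  rows <- strsplit(lines, "\t", fixed = TRUE)
  nc <- unique(lengths(rows))
  if (length(nc) != 1L) stop_format("ragged rows in %s", path)
  matrix(as.numeric(unlist(rows)), nrow = length(rows), ncol = nc, byrow = TRUE)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a gain matrix
#'
#' The matrix is stored as tab-delimited numeric text (one row per sensor,
#' full precision) with a JSON sidecar (`<path>.json`) holding the
#' per-row modality labels. The round trip is bit-exact.
#'
#' @param gain A `gain_matrix`.
#' @param path File path for the numeric text.
#' @return `write_gain` returns `path` invisibly; `read_gain` a
#'   `gain_matrix`.
#' @export
write_gain <- function(gain, path) {
  write_numeric_tsv(gain$values, path)
  jsonlite::write_json(list(modality = gain$modality), sidecar_path(path),
                       auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_gain
#' @param n_sources If given, the expected number of columns; a mismatch is
#'   a format error.
#' @export
read_gain <- function(path, n_sources = NULL) {
  values <- read_numeric_tsv(path)
  if (anyNA(values)) stop_format("non-numeric entries in %s", path)
  if (!is.null(n_sources) && ncol(values) != n_sources) {
    stop_format("gain matrix in %s has %d columns, expected %d",
                path, ncol(values), n_sources)
  }
  modality <- rep("mag", nrow(values))
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    modality <- unlist(jsonlite::read_json(sc, simplifyVector = TRUE)$modality)
    if (length(modality) != nrow(values)) {
      stop_format("modality sidecar of %s does not match row count", path)
    }
  }
  gain_matrix(values, modality)
}

#' Write / read a source space (with parcellation) as TSV
#'
#' One row per dipole with a header line; columns `x,y,z` (position),
#' `nx,ny,nz` (orientation), `sx,sy,sz` (spherical reference position), and
#' `patch` (0-based patch id). Doubles are written at full precision, so
#' the round trip is bit-exact.
#'
#' @param space A `source_space`.
#' @param parc A `parcellation` of the space.
#' @param path Output path.
#' @return `write_source_space` returns `path` invisibly;
#'   `read_source_space` a list with `space` and `parc`.
#' @export
write_source_space <- function(space, parc, path) {
  validate_parcellation(parc, space)
  m <- cbind(space$positions, space$orientations, space$surface_positions)
  lines <- vapply(seq_len(space$n_sources), function(k) {
    paste(c(fmt_double(m[k, ]), as.character(parc$patch_of_source[k] - 1L)),
          collapse = "\t")
  }, character(1))
  writeLines(c("x\ty\tz\tnx\tny\tnz\tsx\tsy\tsz\tpatch", lines), path)
  invisible(path)
}

#' @rdname write_source_space
#' @export
read_source_space <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, c("x", "y", "z", "nx", "ny", "nz",
                           "sx", "sy", "sz", "patch"))) {
    stop_format("unexpected header in %s", path)
  }
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  if (any(lengths(rows) != 10L)) stop_format("wrong column count in %s", path)
  m <- matrix(as.numeric(unlist(rows)), ncol = 10L, byrow = TRUE)
  n <- nrow(m)
  radius <- mean(sqrt(rowSums(m[, 7:9, drop = FALSE]^2)))
  space <- structure(
    list(positions = m[, 1:3, drop = FALSE],
         orientations = m[, 4:6, drop = FALSE],
         surface_positions = m[, 7:9, drop = FALSE],
         n_sources = n, radius = radius, bumpiness = NA_real_, seed = NA_integer_),
    class = "source_space")
  validate_source_space(space)
  assign <- as.integer(m[, 10]) + 1L
  parc <- structure(
    list(patch_of_source = assign,
         patches = unname(split(seq_len(n), assign)),
         n_patches = length(unique(assign)),
         n_requested = length(unique(assign)), seed = NA_integer_),
    class = "parcellation")
  validate_parcellation(parc, space)
  list(space = space, parc = parc)
}

#' Write / read a noise covariance as delimited text
#'
#' @param cov A `noise_covariance`.
#' @param path File path.
#' @return `write_covariance` returns `path` invisibly; `read_covariance`
#'   a `noise_covariance`.
#' @export
write_covariance <- function(cov, path) {
  write_numeric_tsv(cov$C, path)
  jsonlite::write_json(list(n_epochs_used = cov$n_epochs_used,
                            loading = cov$loading),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_covariance
#' @export
read_covariance <- function(path) {
  C <- read_numeric_tsv(path)
  if (nrow(C) != ncol(C)) stop_format("covariance in %s is not square", path)
  meta <- list(n_epochs_used = NA_integer_, loading = NA_real_)
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  }
  structure(list(C = C, n_epochs_used = meta$n_epochs_used,
                 loading = meta$loading),
            class = "noise_covariance")
}

#' Write / read an empirical resolution matrix
#'
#' Values as delimited text plus a JSON sidecar recording method, SNR,
#' seed and size.
#'
#' @param er An `empirical_resolution`.
#' @param path File path.
#' @return `write_resolution` returns `path` invisibly; `read_resolution`
#'   an `empirical_resolution` (without source-level spread profiles).
#' @export
write_resolution <- function(er, path) {
  write_numeric_tsv(er$values, path)
  jsonlite::write_json(list(method = er$method, snr = er$snr,
                            lambda2 = er$lambda2, alpha = er$alpha,
                            seed = er$seed, n_patches = nrow(er$values)),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_resolution
#' @export
read_resolution <- function(path) {
  values <- read_numeric_tsv(path)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  structure(list(values = values, spread = NULL, method = meta$method,
                 snr = as.numeric(meta$snr), lambda2 = meta$lambda2,
                 alpha = meta$alpha, seed = meta$seed, failed = integer(0)),
            class = "empirical_resolution")
}
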