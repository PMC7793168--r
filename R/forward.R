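MU0_OVER_4PI <- 1e-7 # T m / A

#' Construct a sensor array
#'
#' @param positions `n x 3` matrix of sensor positions (meters).
#' @param orientations `n x 3` matrix of unit measurement axes.
#' @param modality Character vector per sensor, from `"mag"`, `"grad"`,
#'   `"eeg"`: magnetometer (field along axis), planar-gradiometer-like
#'   (field difference over a fixed tangential baseline), or electric
#'   potential in an unbounded homogeneous medium.
#' @return A `sensor_array`.
#' @export
sensor_array <- function(positions, orientations, modality) {
  positions <- as.matrix(positions)
  orientations <- as.matrix(orientations)
  if (ncol(positions) != 3L || ncol(orientations) != 3L ||
      nrow(positions) != nrow(orientations)) {
    stop_invalid("positions and orientations must be matching n x 3 matrices")
  }
  modality <- as.character(modality)
  if (length(modality) == 1L) modality <- rep(modality, nrow(positions))
  if (!all(modality %in% c("mag", "grad", "eeg"))) {
    stop_invalid("modality must be 'mag', 'grad' or 'eeg'")
  }
  nrm <- sqrt(rowSums(orientations^2))
  if (any(abs(nrm - 1) > 1e-9)) stop_invalid("sensor orientations must be unit vectors")
  structure(list(positions = positions, orientations = orientations,
                 modality = modality, n_sensors = nrow(positions)),
            class = "sensor_array")
}

#' Quasi-uniform spherical sensor array
#'
#' Sensors on a Fibonacci lattice at `radius`, measurement axes radial.
#'
#' @param n_sensors Number of sensors.
#' @param radius Sensor shell radius in meters (must exceed the source radii).
#' @param modality Single label or per-sensor vector (see [sensor_array()]).
#' @param seed Seed for a small tangential jitter of the lattice.
#' @param jitter Jitter as a fraction of the mean sensor spacing.
#' @return A `sensor_array`.
#' @export
sphere_sensor_array <- function(n_sensors, radius = 0.12, modality = "mag",
                                seed = 1L, jitter = 0.1) {
  n_sensors <- check_count(n_sensors, "n_sensors", min = 1L)
  u <- fibonacci_sphere(n_sensors)
  if (jitter > 0) {
    spacing <- sqrt(4 * pi / n_sensors)
    u <- with_seed(derive_seed(seed, 3L), {
      d <- matrix(stats::rnorm(3 * n_sensors, sd = jitter * spacing), ncol = 3)
      unit_rows(u + d - u * rowSums(u * d))
    })
  }
  sensor_array(radius * u, u, modality)
}

#' Magnetic field of a current dipole in free space
#'
#' `B = (mu0 / 4 pi) (q x d) / |d|^3` with `d = sensor_pos - source_pos`:
#' the primary (free-space) field of a current dipole, volume currents
#' neglected.
#'
#' @param source_pos,sensor_pos 3-vectors, meters.
#' @param moment Dipole moment 3-vector, A m.
#' @return Magnetic field 3-vector in tesla.
#' @export
dipole_field <- function(source_pos, moment, sensor_pos) {
  d <- sensor_pos - source_pos
  nd <- sqrt(sum(d^2))
  if (nd < 1e-12) stop_singular("sensor coincides with source (singular geometry)")
  MU0_OVER_4PI * cross3(moment, d) / nd^3
}

#' Electric potential of a current dipole in an unbounded homogeneous medium
#'
#' `V = (1 / 4 pi sigma) (q . d) / |d|^3`.
#'
#' @inheritParams dipole_field
#' @param sigma Conductivity, S/m.
#' @return Potential in volts.
#' @export
dipole_potential <- function(source_pos, moment, sensor_pos, sigma = 0.3) {
  d <- sensor_pos - source_pos
  nd <- sqrt(sum(d^2))
  if (nd < 1e-12) stop_singular("sensor coincides with source (singular geometry)")
  sum(moment * d) / (4 * pi * sigma * nd^3)
}

# Fields of all dipoles (rows) at one point p: n x 3 matrix.
fields_at <- function(positions, moments, p) {
  d <- matrix(p, nrow(positions), 3, byrow = TRUE) - positions
  nd3 <- (rowSums(d^2))^(3 / 2)
  if (any(nd3 < 1e-36)) stop_singular("sensor coincides with source (singular geometry)")
  MU0_OVER_4PI * cross_rows(moments, d) / nd3
}

# Deterministic tangential axis at direction u.
tangential_axis <- function(u) {
  a <- cross3(u, c(0, 0, 1))
  if (sqrt(sum(a^2)) < 1e-6) a <- cross3(u, c(1, 0, 0))
  a / sqrt(sum(a^2))
}

#' Build the gain (lead-field) matrix
#'
#' One row per sensor, one column per dipole; entry = sensor output for a
#' unit (1 A m) dipole along the dipole's orientation. Magnetometer rows
#' project the free-space dipole field on the sensor axis; gradiometer rows
#' take the field difference across a fixed tangential baseline divided by
#' the baseline (T/m); EEG-like rows use the potential of a dipole in an
#' unbounded homogeneous medium.
#'
#' @param space A `source_space`.
#' @param sensors A `sensor_array`; all sensors must lie outside the source
#'   surface.
#' @param grad_baseline Planar gradiometer baseline in meters.
#' @param sigma Conductivity for EEG-like rows, S/m.
#' @return A `gain_matrix` with fields `values` (`n_sensors x n_sources`)
#'   and `modality` (label per row).
#' @export
build_gain <- function(space, sensors, grad_baseline = 0.0168, sigma = 0.3) {
  validate_source_space(space)
  if (!inherits(sensors, "sensor_array")) stop_invalid("not a sensor_array")
  if (min(sqrt(rowSums(sensors$positions^2))) <=
      max(sqrt(rowSums(space$positions^2)))) {
    stop_invalid("sensors must lie strictly outside the source surface")
  }
  G <- matrix(0, sensors$n_sensors, space$n_sources)
  for (s in seq_len(sensors$n_sensors)) {
    p <- sensors$positions[s, ]
    o <- sensors$orientations[s, ]
    G[s, ] <- switch(
      sensors$modality[s],
      mag = fields_at(space$positions, space$orientations, p) %*% o,
      grad = {
        a <- tangential_axis(p / sqrt(sum(p^2)))
        bp <- fields_at(space$positions, space$orientations, p + a * grad_baseline / 2)
        bm <- fields_at(space$positions, space$orientations, p - a * grad_baseline / 2)
        ((bp - bm) %*% o) / grad_baseline
      },
      eeg = {
        d <- matrix(p, space$n_sources, 3, byrow = TRUE) - space$positions
        nd3 <- (rowSums(d^2))^(3 / 2)
        rowSums(space$orientations * d) / (4 * pi * sigma * nd3)
      }
    )
  }
  gain_matrix(G, sensors$modality)
}

#' Construct / validate a gain matrix container
#'
#' @param values Numeric `n_sensors x n_sources` matrix.
#' @param modality Modality label per row.
#' @return A `gain_matrix`.
#' @export
gain_matrix <- function(values, modality = rep("mag", nrow(values))) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop_invalid("gain matrix has non-finite entries")
  if (length(modality) != nrow(values)) {
    stop_invalid("modality labels must match the number of rows")
  }
  colmax <- apply(abs(values), 2, max)
  if (any(colmax <= 1e-30 * max(colmax))) {
    stop_invalid("gain matrix has an (effectively) all-zero column")
  }
  structure(list(values = values, modality = as.character(modality)),
            class = "gain_matrix")
}

#' @export
print.gain_matrix <- function(x, ...) {
  cat(sprintf("<gain_matrix> %d sensors x %d sources (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s:%d", names(table(x$modality)), table(x$modality)),
                    collapse = ", ")))
  invisible(x)
}

#' Row-index sets per sensor modality
#'
#' @param gain A `gain_matrix`.
#' @return Named list of integer row indices, one entry per present modality.
#' @export
modality_sets <- function(gain) {
  split(seq_along(gain$modality), gain$modality)
}
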