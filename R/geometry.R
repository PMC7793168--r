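#' Spherical Fibonacci lattice
#'
#' Quasi-uniform unit vectors on the sphere from the golden-angle lattice.
#' Deterministic; used both for dipole placement and sensor placement.
#'
#' @param n Number of points.
#' @return An `n x 3` matrix of unit vectors.
#' @keywords internal
fibonacci_sphere <- function(n) {
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  phi <- acos(pmin(pmax(z, -1), 1))
  theta <- pi * (1 + sqrt(5)) * (i - 1)
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Smooth scalar random field on the unit sphere: a seeded superposition of a
# few long-wavelength cosine waves, normalized to max |f| = 1.
smooth_sphere_field <- function(seed, n_components = 6L) {
  with_seed(derive_seed(seed, 11L), {
    dirs <- unit_rows(matrix(stats::rnorm(3 * n_components), ncol = 3))
    amps <- stats::rnorm(n_components)
    freqs <- stats::runif(n_components, 1, 3)
    phases <- stats::runif(n_components, 0, 2 * pi)
    list(dirs = dirs, amps = amps, freqs = freqs, phases = phases)
  })
}

eval_sphere_field <- function(field, u) {
  proj <- u %*% t(field$dirs) # n x m
  f <- rep(0, nrow(u))
  g <- matrix(0, nrow(u), 3)
  for (m in seq_along(field$amps)) {
    arg <- field$freqs[m] * pi * proj[, m] + field$phases[m]
    f <- f + field$amps[m] * cos(arg)
    g <- g - outer(field$amps[m] * field$freqs[m] * pi * sin(arg), field$dirs[m, ])
  }
  list(f = f, grad = g)
}

#' Build a synthetic spherical source space
#'
#' Places `n_sources` current dipoles quasi-uniformly on a radially perturbed
#' sphere. The unperturbed sphere plays the role of an inflated reference
#' surface: `surface_positions` are the spherical projections used for patch
#' center-of-gravity computations, while `positions` live on the bumpy
#' surface. Dipole orientations are the outward surface normals of the
#' perturbed surface, so with `bumpiness > 0` they are not purely radial
#' (radial dipoles are magnetically silent in spherically symmetric
#' geometries, which would confound fidelity scores).
#'
#' @param n_sources Number of dipoles (>= 4).
#' @param radius Reference sphere radius in meters.
#' @param bumpiness Relative amplitude of the radial perturbation, in
#'   `[0, 0.5)`. The realized radii lie in `radius * (1 +/- bumpiness)`.
#' @param seed Integer seed; output is deterministic per seed.
#' @param jitter Tangential jitter of the lattice points as a fraction of the
#'   mean inter-dipole spacing.
#' @return A `source_space` object with fields `positions`, `orientations`,
#'   `surface_positions` (all `n x 3` matrices, meters) and `n_sources`.
#' @examples
#' ss <- build_sphere_source_space(200, radius = 0.08, bumpiness = 0.1, seed = 1)
#' range(sqrt(rowSums(ss$positions^2)))
#' @export
build_sphere_source_space <- function(n_sources, radius = 0.08, bumpiness = 0.1,
                                      seed = 1L, jitter = 0.25) {
  n_sources <- check_count(n_sources, "n_sources", min = 4L)
  radius <- check_scalar(radius, "radius")
  if (radius <= 0) stop_invalid("`radius` must be positive")
  bumpiness <- check_scalar(bumpiness, "bumpiness", min = 0)
  if (bumpiness >= 0.5) stop_invalid("`bumpiness` must be < 0.5")

  u <- fibonacci_sphere(n_sources)
  spacing <- sqrt(4 * pi / n_sources) # mean angular spacing, radians
  if (jitter > 0) {
    u <- with_seed(derive_seed(seed, 1L), {
      d <- matrix(stats::rnorm(3 * n_sources, sd = jitter * spacing), ncol = 3)
      unit_rows(u + d - u * rowSums(u * d)) # tangential displacement
    })
  }

  if (bumpiness > 0) {
    field <- smooth_sphere_field(seed)
    ev <- eval_sphere_field(field, u)
    scale <- max(abs(ev$f), 1e-12)
    f <- ev$f / scale
    grad <- ev$grad / scale
    grad_t <- grad - u * rowSums(u * grad) # tangential gradient
    rho <- radius * (1 + bumpiness * f)
    normals <- unit_rows((1 + bumpiness * f) * u - bumpiness * grad_t)
  } else {
    rho <- rep(radius, n_sources)
    normals <- u
  }

  structure(
    list(positions = rho * u,
         orientations = normals,
         surface_positions = radius * u,
         n_sources = n_sources,
         radius = radius, bumpiness = bumpiness, seed = as.integer(seed)),
    class = "source_space"
  )
}

#' Validate a source space
#'
#' Checks the structural invariants: finite positions, unit-norm
#' orientations, and surface positions lying on a common sphere.
#'
#' @param space A `source_space`.
#' @return `space`, invisibly; errors on violation.
#' @export
validate_source_space <- function(space) {
  if (!inherits(space, "source_space")) stop_invalid("not a source_space")
  if (!all(is.finite(space$positions))) stop_invalid("non-finite dipole positions")
  n <- sqrt(rowSums(space$orientations^2))
  if (any(abs(n - 1) > 1e-9)) stop_invalid("orientations are not unit vectors")
  r <- sqrt(rowSums(space$surface_positions^2))
  if (diff(range(r)) > 1e-6 * mean(r)) {
    stop_invalid("surface positions do not lie on a common sphere")
  }
  invisible(space)
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("<source_space> %d dipoles, radius %.3g m, bumpiness %.3g, seed %d\n",
              x$n_sources, x$radius, x$bumpiness, x$seed))
  invisible(x)
}

# Farthest-point sampling of dipole directions; returns indices of seeds.
farthest_point_seeds <- function(u, n_seeds, seed) {
  n <- nrow(u)
  first <- with_seed(derive_seed(seed, 2L), sample.int(n, 1L))
  seeds <- integer(n_seeds)
  seeds[1] <- first
  # track max dot product (= min angular distance) to the chosen seed set
  best <- as.vector(u %*% u[first, ])
  if (n_seeds > 1L) {
    for (s in 2:n_seeds) {
      nxt <- which.min(best)
      seeds[s] <- nxt
      best <- pmax(best, as.vector(u %*% u[nxt, ]))
    }
  }
  sort(seeds)
}

#' Parcellate a source space into disjoint patches
#'
#' Tiles the reference sphere with `n_patches` quasi-uniform seed directions
#' (farthest-point sampling of the dipole directions themselves, seeded
#' start) and assigns every dipole to its nearest seed, ties broken by lowest
#' patch index. Patches smaller than the effective minimum size are merged
#' into neighboring patches ("rebalancing"), so the returned number of
#' patches can be smaller than requested; the result records both.
#'
#' @param space A `source_space`.
#' @param n_patches Requested number of patches (1..n_sources).
#' @param seed Integer seed for the farthest-point start.
#' @param min_size Minimum patch size before rebalancing merges a patch; the
#'   effective minimum is `min(min_size, floor(n_sources / n_patches))`.
#' @return A `parcellation` with `patch_of_source` (1-based patch index per
#'   dipole), `patches` (list of dipole-index vectors), `n_patches`.
#' @examples
#' ss <- build_sphere_source_space(200, seed = 1)
#' pc <- parcellate(ss, 20, seed = 3)
#' lengths(pc$patches)
#' @export
parcellate <- function(space, n_patches, seed = 1L, min_size = 4L) {
  validate_source_space(space)
  n_patches <- check_count(n_patches, "n_patches", min = 1L)
  if (n_patches > space$n_sources) {
    stop_invalid("`n_patches` (%d) exceeds number of dipoles (%d)",
                 n_patches, space$n_sources)
  }
  n <- space$n_sources
  u <- unit_rows(space$surface_positions)
  eff_min <- max(1L, min(check_count(min_size, "min_size", 1L),
                         floor(n / n_patches)))

  seeds <- farthest_point_seeds(u, n_patches, seed)
  repeat {
    dots <- u %*% t(u[seeds, , drop = FALSE])
    assign <- max.col(dots, ties.method = "first")
    sizes <- tabulate(assign, nbins = length(seeds))
    if (all(sizes >= eff_min) || length(seeds) <= 1L) break
    # merge the smallest undersized patch into its neighbors
    drop <- which(sizes < eff_min)
    drop <- drop[which.min(sizes[drop])]
    seeds <- seeds[-drop]
  }
  keep <- sort(unique(assign))
  assign <- match(assign, keep)

  structure(
    list(patch_of_source = assign,
         patches = unname(split(seq_len(n), assign)),
         n_patches = length(keep),
         n_requested = n_patches,
         seed = as.integer(seed)),
    class = "parcellation"
  )
}

#' Validate a parcellation against a source space
#'
#' Asserts disjointness and coverage (every dipole in exactly one patch) and
#' that all patches are non-empty.
#'
#' @param parc A `parcellation`.
#' @param space The `source_space` it partitions.
#' @return `parc`, invisibly.
#' @export
validate_parcellation <- function(parc, space) {
  if (!inherits(parc, "parcellation")) stop_invalid("not a parcellation")
  all_members <- sort(unlist(parc$patches))
  if (!identical(all_members, seq_len(space$n_sources))) {
    stop_invalid("patches are not a disjoint, exhaustive partition")
  }
  if (any(lengths(parc$patches) == 0L)) stop_invalid("empty patch present")
  invisible(parc)
}

#' @export
print.parcellation <- function(x, ...) {
  s <- lengths(x$patches)
  cat(sprintf("<parcellation> %d patches (requested %d), sizes %d-%d (median %g)\n",
              x$n_patches, x$n_requested, min(s), max(s), stats::median(s)))
  invisible(x)
}

#' Center dipole of a patch
#'
#' The patch center is the member dipole closest (Euclidean) to the patch's
#' center of gravity computed on the spherical reference surface; ties are
#' broken by lowest dipole index.
#'
#' @param patch Integer vector of dipole indices (non-empty).
#' @param space A `source_space`.
#' @return A single dipole index, member of `patch`.
#' @export
patch_center <- function(patch, space) {
  validate_source_space(space)
  if (length(patch) == 0L) stop_invalid("empty patch")
  patch <- sort(as.integer(patch))
  if (any(patch < 1L | patch > space$n_sources)) stop_invalid("patch index out of range")
  sp <- space$surface_positions[patch, , drop = FALSE]
  cg <- colMeans(sp)
  d2 <- rowSums((sp - matrix(cg, nrow(sp), 3, byrow = TRUE))^2)
  patch[which.min(d2)]
}

#' Patch center dipoles for a whole parcellation
#'
#' @param parc A `parcellation`.
#' @param space The matching `source_space`.
#' @return Integer vector of length `n_patches`.
#' @export
patch_centers <- function(parc, space) {
  vapply(parc$patches, patch_center, integer(1), space = space)
}
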