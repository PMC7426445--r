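#' Voxel grid geometry
#'
#' @param origin length-3 corner of voxel (1,1,1) in Angstrom.
#' @param spacing isotropic voxel edge length (A, > 0).
#' @param dims three positive integers.
#' @param padding margin (A) the spec was built with (bookkeeping only).
#' @return object of class `"grid_spec"`. Voxel center (i,j,k) is at
#'   `origin + (c(i,j,k) - 0.5) * spacing` (1-based indices).
#' @export
grid_spec <- function(origin, spacing, dims, padding = NA_real_) {
  if (spacing <= 0) stop("spacing must be positive")
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) stop("dims must be 3 positive integers")
  if (length(origin) != 3L || !all(is.finite(origin))) stop("bad origin")
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dims = dims, padding = padding),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("Grid: %d x %d x %d voxels, spacing %.2f A, origin (%.2f, %.2f, %.2f)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

same_spec <- function(a, b) {
  identical(a$dims, b$dims) && a$spacing == b$spacing &&
    all(a$origin == b$origin)
}

#' Scalar occupancy grid
#'
#' @param spec a [grid_spec()].
#' @param values numeric array matching `spec$dims`.
#' @param kind one of `"mean"`, `"sd"`, `"mean_smoothed"`, `"sd_smoothed"`,
#'   `"difference"`.
#' @param n_frames number of frames the statistics were computed over.
#' @return object of class `"occupancy_grid"`.
#' @export
occupancy_grid <- function(spec, values, kind, n_frames = 0L) {
  stopifnot(inherits(spec, "grid_spec"))
  kinds <- c("mean", "sd", "mean_smoothed", "sd_smoothed", "difference")
  if (!kind %in% kinds) stop("kind must be one of ", paste(kinds, collapse = ", "))
  if (!identical(dim(values), as.integer(spec$dims)))
    stop("values dimensions do not match the grid spec")
  structure(list(spec = spec, values = values, kind = kind,
                 n_frames = as.integer(n_frames)),
            class = "occupancy_grid")
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat(sprintf("Occupancy grid (%s): %d x %d x %d, range [%.4g, %.4g], %d frames\n",
              x$kind, x$spec$dims[1], x$spec$dims[2], x$spec$dims[3],
              min(x$values), max(x$values), x$n_frames))
  invisible(x)
}

#' Build a grid spec covering one or two aligned ensembles
#'
#' The bounding box of all heavy atoms over all frames of all inputs is
#' inflated by `padding` plus the largest van der Waals radius on each side,
#' so the occupied volume never touches the grid boundary (required for
#' mass-preserving reflect smoothing).
#'
#' @param ensembles a single [ensemble()] or a list of ensembles already in a
#'   common frame (see [pair_align()]).
#' @param spacing voxel edge (A), default 1.0.
#' @param padding extra margin (A), default 4.0.
#' @return a [grid_spec()].
#' @export
make_grid_spec <- function(ensembles, spacing = 1.0, padding = 4.0) {
  if (spacing <= 0) stop("spacing must be positive")
  if (inherits(ensembles, "ensemble")) ensembles <- list(ensembles)
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3); maxr <- 0
  for (e in ensembles) {
    heavy <- e$topology$atoms$heavy
    if (!any(heavy)) stop("ensemble has no heavy atoms")
    co <- e$coords[heavy, , , drop = FALSE]
    lo <- pmin(lo, apply(co, 2, min))
    hi <- pmax(hi, apply(co, 2, max))
    maxr <- max(maxr, max(e$topology$atoms$vdw[heavy]))
  }
  margin <- padding + maxr
  origin <- lo - margin
  extent <- (hi + margin) - origin
  dims <- pmax(as.integer(ceiling(extent / spacing)), 1L)
  grid_spec(origin, spacing, dims, padding = padding)
}

# logical occupancy of one frame: voxel center within vdw+probe of any atom
.frame_occupancy <- function(xyz, radii, spec, frame, probe = 0) {
  dims <- spec$dims; h <- spec$spacing; o <- spec$origin
  occ <- array(FALSE, dim = dims)
  box_hi <- o + dims * h
  for (a in seq_len(nrow(xyz))) {
    p <- xyz[a, ]
    if (any(p < o) || any(p > box_hi))
      stop(sprintf("frame %d: atom %d at (%.2f, %.2f, %.2f) lies outside the grid",
                   frame, a, p[1], p[2], p[3]))
    r <- radii[a] + probe
    ilo <- pmax(ceiling((p - r - o) / h + 0.5), 1)
    ihi <- pmin(floor((p + r - o) / h + 0.5), dims)
    if (any(ilo > ihi)) next
    ix <- ilo[1]:ihi[1]; iy <- ilo[2]:ihi[2]; iz <- ilo[3]:ihi[3]
    dx2 <- (o[1] + (ix - 0.5) * h - p[1])^2
    dy2 <- (o[2] + (iy - 0.5) * h - p[2])^2
    dz2 <- (o[3] + (iz - 0.5) * h - p[3])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
    occ[ix, iy, iz] <- occ[ix, iy, iz] | inside
  }
  occ
}

#' Per-voxel occupancy mean and standard deviation over an ensemble
#'
#' For every frame, a voxel is occupied (1) iff its center lies within
#' `vdw_radius + probe` of any selected atom, otherwise unoccupied (0). The
#' mean grid is the occupancy probability p per voxel; the SD grid is the
#' population standard deviation over frames, which for binary occupancy is
#' exactly sqrt(p (1 - p)). Voxels that are sometimes inside the protein and
#' sometimes solvent-exposed (p near 0.5) carry the highest SD — these are
#' the plastic regions.
#'
#' @param ens an aligned [ensemble()].
#' @param spec a [grid_spec()] covering all selected atoms in all frames.
#' @param selection `"heavy"` (default: all non-hydrogen atoms), or a
#'   selection object/expression.
#' @param probe probe radius added to each vdW radius (A, default 0).
#' @return list with `mean` and `sd`, both [occupancy_grid()]s.
#' @export
occupancy_stats <- function(ens, spec, selection = "heavy", probe = 0) {
  if (identical(selection, "heavy")) {
    idx <- which(ens$topology$atoms$heavy)
  } else {
    idx <- as_selection(ens$topology, selection)$indices
  }
  if (!length(idx)) stop("occupancy selection is empty")
  radii <- ens$topology$atoms$vdw[idx]
  f <- n_frames(ens)
  acc <- array(0, dim = spec$dims)
  for (fr in seq_len(f)) {
    xyz <- frame_coords(ens, fr)[idx, , drop = FALSE]
    acc <- acc + .frame_occupancy(xyz, radii, spec, fr, probe)
  }
  p <- acc / f
  list(mean = occupancy_grid(spec, p, "mean", f),
       sd = occupancy_grid(spec, sqrt(p * (1 - p)), "sd", f))
}

#' Gaussian smoothing of a grid
#'
#' Separable 3-D Gaussian convolution with a kernel truncated at 4 sigma,
#' normalized to unit sum, and reflect padding at the boundaries. Smoothing
#' suppresses the isolated partially-occupied voxels that even rigid regions
#' produce, so that only extended plastic regions survive. `sigma = 0`
#' returns the input unchanged.
#'
#' @param grid an [occupancy_grid()].
#' @param sigma kernel width in Angstrom (default 1.5).
#' @return smoothed [occupancy_grid()]; `kind` gains a `"_smoothed"` suffix.
#' @export
gauss_filter <- function(grid, sigma = 1.5) {
  stopifnot(inherits(grid, "occupancy_grid"))
  if (sigma < 0) stop("sigma must be non-negative")
  newkind <- if (grid$kind %in% c("mean", "sd"))
    paste0(grid$kind, "_smoothed") else grid$kind
  if (sigma == 0) return(occupancy_grid(grid$spec, grid$values, newkind, grid$n_frames))
  h <- grid$spec$spacing
  half <- max(1L, as.integer(ceiling(4 * sigma / h)))
  k <- exp(-((-half:half) * h)^2 / (2 * sigma^2))
  k <- k / sum(k)
  v <- grid$values
  for (axis in 1:3) v <- .convolve_axis(v, k, axis)
  occupancy_grid(grid$spec, v, newkind, grid$n_frames)
}

# 1-D convolution of a 3-D array along one axis with symmetric reflect
# padding (edge value repeated: d c b a | a b c d | d c b a).
.convolve_axis <- function(v, k, axis) {
  half <- (length(k) - 1L) %/% 2L
  n <- dim(v)[axis]
  idx <- seq_len(n + 2L * half) - half           # positions -half+1 .. n+half
  refl <- ifelse(idx < 1L, 1L - idx, ifelse(idx > n, 2L * n + 1L - idx, idx))
  refl <- pmin(pmax(refl, 1L), n)                # guard tiny n
  padded <- switch(axis,
                   v[refl, , , drop = FALSE],
                   v[, refl, , drop = FALSE],
                   v[, , refl, drop = FALSE])
  out <- array(0, dim = dim(v))
  for (t in seq_along(k)) {
    sl <- seq_len(n) + (t - 1L)
    piece <- switch(axis,
                    padded[sl, , , drop = FALSE],
                    padded[, sl, , drop = FALSE],
                    padded[, , sl, drop = FALSE])
    out <- out + k[t] * piece
  }
  out
}

#' Global surface plasticity
#'
#' Volume-weighted integral of the (smoothed) SD grid over supra-threshold
#' voxels: `sum(value * spacing^3)` over voxels with value > threshold, in
#' cubic Angstrom. Flexible regions contribute large volumes of high SD;
#' rigid ensembles score near zero.
#'
#' @param sd_grid an [occupancy_grid()] of kind `"sd"` or `"sd_smoothed"`.
#' @param threshold SD threshold in [0, 0.5] (default 0.05) removing the
#'   near-zero background.
#' @return plasticity score in A^3.
#' @export
global_plasticity <- function(sd_grid, threshold = 0.05) {
  stopifnot(inherits(sd_grid, "occupancy_grid"))
  if (!sd_grid$kind %in% c("sd", "sd_smoothed"))
    stop("global_plasticity expects an SD grid, got kind '", sd_grid$kind, "'")
  if (threshold < 0 || threshold > 0.5) stop("threshold must lie in [0, 0.5]")
  v <- sd_grid$values
  sum(v[v > threshold]) * sd_grid$spec$spacing^3
}

#' Localize plasticity onto residues
#'
#' Assigns every supra-threshold voxel of the SD grid to the residue of its
#' nearest heavy atom in a reference (mean) structure, if that atom lies
#' within `max_dist`; remaining voxels are pooled as `"unassigned"`. The
#' per-residue score is the summed voxel value times the voxel volume, so the
#' per-residue scores plus the unassigned remainder reproduce the global
#' plasticity integral exactly.
#'
#' @param sd_grid an SD [occupancy_grid()] (typically smoothed).
#' @param ens the ensemble whose mean structure anchors the attribution (must
#'   be in the grid's coordinate frame).
#' @param max_dist attribution radius in Angstrom (default 4.0).
#' @param threshold SD threshold (default 0.05), as in [global_plasticity()].
#' @return object of class `"plasticity_profile"`: list with `per_residue`
#'   (named numeric, A^3), `unassigned` (A^3), `global_score` (A^3),
#'   `sigma_used` (NA here; recorded by callers), `threshold_used`,
#'   `max_dist`.
#' @export
localize_plasticity <- function(sd_grid, ens, max_dist = 4.0, threshold = 0.05) {
  stopifnot(inherits(sd_grid, "occupancy_grid"), inherits(ens, "ensemble"))
  if (!sd_grid$kind %in% c("sd", "sd_smoothed"))
    stop("localize_plasticity expects an SD grid, got kind '", sd_grid$kind, "'")
  if (threshold < 0 || threshold > 0.5) stop("threshold must lie in [0, 0.5]")
  top <- ens$topology
  heavy <- which(top$atoms$heavy)
  mean_xyz <- apply(ens$coords[heavy, , , drop = FALSE], c(1, 2), mean)
  res_of_atom <- top$residues$key[top$atoms$resindex[heavy]]

  sp <- sd_grid$spec
  supra <- which(sd_grid$values > threshold, arr.ind = TRUE)
  keys <- top$residues$key
  scores <- stats::setNames(numeric(length(keys)), keys)
  unassigned <- 0
  if (nrow(supra)) {
    centers <- sweep(supra - 0.5, 2, rep(sp$spacing, 3), "*")
    centers <- sweep(centers, 2, sp$origin, "+")
    vals <- sd_grid$values[supra] * sp$spacing^3
    # nearest heavy atom per voxel (block over voxels to bound memory)
    nvox <- nrow(centers)
    blk <- 2048L
    for (s in seq(1L, nvox, by = blk)) {
      e <- min(s + blk - 1L, nvox)
      cb <- centers[s:e, , drop = FALSE]
      d2 <- outer(rowSums(cb^2), rowSums(mean_xyz^2), "+") -
        2 * cb %*% t(mean_xyz)
      nearest <- max.col(-d2, ties.method = "first")
      mind <- sqrt(pmax(d2[cbind(seq_len(nrow(d2)), nearest)], 0))
      ok <- mind <= max_dist
      if (any(ok)) {
        contrib <- tapply(vals[s:e][ok], res_of_atom[nearest[ok]], sum)
        scores[names(contrib)] <- scores[names(contrib)] + contrib
      }
      unassigned <- unassigned + sum(vals[s:e][!ok])
    }
  }
  structure(list(per_residue = scores, unassigned = unassigned,
                 global_score = sum(scores) + unassigned,
                 sigma_used = NA_real_, threshold_used = threshold,
                 max_dist = max_dist),
            class = "plasticity_profile")
}

#' @export
print.plasticity_profile <- function(x, ...) {
  cat(sprintf("Plasticity profile: global %.2f A^3 over %d residues (unassigned %.2f)\n",
              x$global_score, length(x$per_residue), x$unassigned))
  top <- utils::head(sort(x$per_residue, decreasing = TRUE), 5)
  for (i in seq_along(top))
    cat(sprintf("  %-10s %8.3f A^3\n", names(top)[i], top[i]))
  invisible(x)
}

#' Difference of two grids on the same lattice
#'
#' Elementwise A - B; positive values mark voxels where ensemble A (e.g. the
#' naive antibody) is more plastic than B (the matured one).
#'
#' @param grid_a,grid_b [occupancy_grid()]s with identical specs and kinds.
#' @return [occupancy_grid()] of kind `"difference"`.
#' @export
plasticity_difference <- function(grid_a, grid_b) {
  stopifnot(inherits(grid_a, "occupancy_grid"), inherits(grid_b, "occupancy_grid"))
  if (!same_spec(grid_a$spec, grid_b$spec))
    stop("grid specs differ: A is ", paste(grid_a$spec$dims, collapse = "x"),
         " @ (", paste(sprintf("%.3f", grid_a$spec$origin), collapse = ", "),
         ") spacing ", grid_a$spec$spacing,
         "; B is ", paste(grid_b$spec$dims, collapse = "x"),
         " @ (", paste(sprintf("%.3f", grid_b$spec$origin), collapse = ", "),
         ") spacing ", grid_b$spec$spacing)
  if (grid_a$kind != grid_b$kind)
    stop("grid kinds differ: ", grid_a$kind, " vs ", grid_b$kind)
  occupancy_grid(grid_a$spec, grid_a$values - grid_b$values, "difference",
                 max(grid_a$n_frames, grid_b$n_frames))
}
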