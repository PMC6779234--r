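#' Parallel-beam scan geometry
#'
#' A 2D parallel-beam geometry applied independently to each axial slice:
#' `n_angles` projection angles uniformly covering `[0, pi)` and
#' `n_radial` detector bins spaced `bin_spacing_mm` apart, centred on the
#' rotation axis. The radial span must cover the in-plane grid diagonal.
#'
#' @param n_angles number of projection angles.
#' @param n_radial number of radial bins.
#' @param bin_spacing_mm radial bin spacing (mm).
#' @return a `scan_geometry`.
#' @export
scan_geometry <- function(n_angles, n_radial, bin_spacing_mm) {
  if (n_angles < 1 || n_radial < 1) stop("n_angles and n_radial must be >= 1")
  if (bin_spacing_mm <= 0) stop("bin_spacing_mm must be positive")
  structure(list(n_angles = as.integer(n_angles),
                 n_radial = as.integer(n_radial),
                 bin_spacing_mm = bin_spacing_mm,
                 angles = seq(0, pi, length.out = n_angles + 1)[1:n_angles],
                 offsets = (seq_len(n_radial) - (n_radial + 1) / 2) *
                   bin_spacing_mm),
            class = "scan_geometry")
}

#' Default geometry covering a volume
#'
#' Bin spacing equal to the in-plane voxel size and enough bins to cover
#' the grid diagonal; by default as many angles as in-plane voxels per
#' side.
#'
#' @param vol a `zteac_volume`.
#' @param n_angles number of angles (default `max(nx, ny)`).
#' @return a `scan_geometry`.
#' @export
default_geometry <- function(vol, n_angles = NULL) {
  d <- dim(vol$data)
  diag_mm <- sqrt(sum((d[1:2] * vol$spacing[1:2])^2))
  bs <- min(vol$spacing[1:2])
  nr <- 2L * as.integer(ceiling(diag_mm / bs / 2)) + 1L
  if (is.null(n_angles)) n_angles <- max(d[1:2])
  scan_geometry(n_angles, nr, bs)
}

check_coverage <- function(vol, g) {
  d <- dim(vol$data)
  diag_mm <- sqrt(sum((d[1:2] * vol$spacing[1:2])^2))
  span <- g$n_radial * g$bin_spacing_mm
  if (span < diag_mm)
    stop(sprintf(
      "radial span %.1f mm does not cover the grid diagonal %.1f mm",
      span, diag_mm))
  invisible(TRUE)
}

new_sinogram <- function(data, geometry, semantic) {
  structure(list(data = data, geometry = geometry, semantic = semantic),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<sinogram> %d angles x %d radial x %d slices, semantic '%s'\n",
              d[1], d[2], d[3], x$semantic))
  invisible(x)
}

#' Forward-project a volume into a sinogram
#'
#' Exact ray-grid intersection-length weighting (Siddon-style traversal)
#' per (angle, radial bin, slice); linear in the input. Line integrals are
#' in mm times the voxel unit.
#'
#' @param vol a `zteac_volume`.
#' @param g a [scan_geometry()].
#' @return a `sinogram` with semantic `"line-integral"`.
#' @export
project <- function(vol, g) {
  stopifnot_volume(vol)
  if (!inherits(g, "scan_geometry")) stop("g must be a scan_geometry")
  if (any(!is.finite(vol$data))) stop("volume contains non-finite values")
  check_coverage(vol, g)
  s <- .proj_forward(vol$data, dim(vol$data), vol$spacing, g$angles,
                     g$offsets)
  new_sinogram(s, g, "line-integral")
}

#' Backproject a sinogram (adjoint of [project()])
#'
#' @param sino a `sinogram`.
#' @param dim grid shape of the target volume.
#' @param spacing voxel spacing (mm).
#' @return a `zteac_volume`.
#' @export
backproject <- function(sino, dim, spacing) {
  if (!inherits(sino, "sinogram")) stop("sino must be a sinogram")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  v <- .proj_back(sino$data, as.integer(dim), spacing, sino$geometry$angles,
                  sino$geometry$offsets)
  volume(v, spacing, "other")
}

#' Attenuation correction factors of an attenuation map
#'
#' ACF = exp(integral of mu along the line of response); mu is in cm^-1 and
#' projector path lengths in mm, so the line integral is scaled by 0.1.
#' ACF >= 1 everywhere; the photon-pair survival probability is 1/ACF.
#'
#' @param mu an `ac_map` (or `zteac_volume` in cm^-1).
#' @param g a [scan_geometry()].
#' @return a `sinogram` with semantic `"acf"`.
#' @export
attenuation_factors <- function(mu, g) {
  v <- if (inherits(mu, "ac_map")) mu$mu else mu
  stopifnot_volume(v)
  if (any(v$data < 0)) stop("attenuation coefficients must be >= 0")
  li <- project(v, g)
  new_sinogram(exp(li$data * 0.1), g, "acf")
}

#' Simulate an emission scan
#'
#' The expected sinogram is `project(activity) / acf` rescaled to
#' `total_counts` events, then Poisson-sampled per bin (deterministic given
#' `seed`). `total_counts = Inf` gives the noiseless mean (unscaled).
#'
#' @param activity a `zteac_volume` (>= 0).
#' @param mu an `ac_map` or `NULL` for no attenuation.
#' @param g a [scan_geometry()].
#' @param total_counts expected total events, or `Inf` for noiseless.
#' @param seed RNG seed.
#' @return a `sinogram` with semantic `"counts"`.
#' @export
simulate_counts <- function(activity, mu, g, total_counts = 1e6, seed = 1L) {
  stopifnot_volume(activity)
  if (any(activity$data < 0)) stop("activity must be >= 0")
  if (all(activity$data == 0)) stop("activity volume is all zero")
  if (total_counts <= 0) stop("total_counts must be positive")
  li <- project(activity, g)
  mean_s <- li$data
  if (!is.null(mu)) {
    acf <- attenuation_factors(mu, g)
    mean_s <- mean_s / acf$data
  }
  if (is.infinite(total_counts))
    return(new_sinogram(mean_s, g, "counts"))
  mean_s <- mean_s * (total_counts / sum(mean_s))
  counts <- with_seed(seed, stats::rpois(length(mean_s), mean_s))
  dim(counts) <- dim(mean_s)
  new_sinogram(counts, g, "counts")
}

#' OSEM reconstruction configuration
#'
#' @param iterations full passes over all subsets.
#' @param subsets number of angle-interleaved subsets (angle `i` belongs to
#'   subset `i mod subsets`); 1 gives plain MLEM.
#' @param init uniform positive initial activity value.
#' @return a `recon_config`.
#' @export
recon_config <- function(iterations = 4L, subsets = 8L, init = 1) {
  if (iterations < 1) stop("iterations must be >= 1")
  if (subsets < 1) stop("subsets must be >= 1")
  if (init <= 0) stop("init must be positive")
  structure(list(iterations = as.integer(iterations),
                 subsets = as.integer(subsets), init = init),
            class = "recon_config")
}

subset_geometry <- function(g, idx) {
  gs <- g
  gs$angles <- g$angles[idx]
  gs$n_angles <- length(idx)
  gs
}

#' Ordered-subsets EM reconstruction with attenuation correction
#'
#' Multiplicative EM updates over angle-interleaved subsets, with the
#' attenuation folded into the system model as survival weights (1/ACF) on
#' the forward and adjoint operators. The output is non-negative; voxels
#' with zero sensitivity are excluded from updates (left at zero) and
#' reported in the `zero_sensitivity` attribute.
#'
#' @param counts a `"counts"` `sinogram`.
#' @param acf an `"acf"` `sinogram` on the same geometry (or `NULL`).
#' @param dim,spacing target grid.
#' @param cfg a [recon_config()].
#' @return activity `zteac_volume`; attribute `zero_sensitivity` gives the
#'   number of excluded voxels.
#' @export
osem <- function(counts, acf, dim, spacing, cfg = recon_config()) {
  if (!inherits(counts, "sinogram")) stop("counts must be a sinogram")
  g <- counts$geometry
  if (!is.null(acf)) {
    if (!identical(base::dim(acf$data), base::dim(counts$data)))
      stop("counts and acf sinograms have different shapes")
    surv <- 1 / acf$data
  } else surv <- array(1, base::dim(counts$data))
  d <- as.integer(dim)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  x <- array(cfg$init, d)
  subsets <- lapply(seq_len(cfg$subsets) - 1L,
                    function(s) which((seq_len(g$n_angles) - 1L) %%
                                        cfg$subsets == s))
  subsets <- Filter(length, subsets)
  eps <- 1e-12
  # per-subset sensitivity: adjoint of survival-weighted unit sinogram
  sens <- lapply(subsets, function(idx) {
    gs <- subset_geometry(g, idx)
    .proj_back(surv[idx, , , drop = FALSE], d, spacing, gs$angles, gs$offsets)
  })
  total_sens <- Reduce(`+`, sens)
  dead <- total_sens <= 0
  for (it in seq_len(cfg$iterations)) {
    for (s in seq_along(subsets)) {
      idx <- subsets[[s]]
      gs <- subset_geometry(g, idx)
      yhat <- .proj_forward(x, d, spacing, gs$angles, gs$offsets) *
        surv[idx, , , drop = FALSE]
      ratio <- counts$data[idx, , , drop = FALSE] / pmax(yhat, eps)
      bp <- .proj_back(ratio * surv[idx, , , drop = FALSE], d, spacing,
                       gs$angles, gs$offsets)
      upd <- bp / pmax(sens[[s]], eps)
      upd[sens[[s]] <= 0] <- 0
      x <- x * upd
    }
  }
  x[dead] <- 0
  out <- volume(x, spacing, "activity")
  attr(out, "zero_sensitivity") <- sum(dead)
  out
}

#' Poisson log-likelihood of a reconstruction
#'
#' `sum(y * log(yhat) - yhat)` over sinogram bins, with the survival-
#' weighted forward model; bins with `yhat = 0, y = 0` contribute 0.
#'
#' @param x activity `zteac_volume`.
#' @param counts counts `sinogram`.
#' @param acf acf `sinogram` or `NULL`.
#' @return scalar log-likelihood (up to the `log(y!)` constant).
#' @export
poisson_loglik <- function(x, counts, acf = NULL) {
  g <- counts$geometry
  yhat <- .proj_forward(x$data, dim(x$data), x$spacing, g$angles, g$offsets)
  if (!is.null(acf)) yhat <- yhat / acf$data
  y <- counts$data
  ok <- yhat > 0
  ll <- sum(y[ok] * log(yhat[ok]) - yhat[ok])
  if (any(!ok & y > 0)) ll <- -Inf
  ll
}
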