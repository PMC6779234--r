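#' Specification of a synthetic head phantom
#'
#' Describes an ellipsoidal head with a skull shell of spatially varying
#' bone density, nested grey/white-matter ellipsoids, interior air pockets
#' (paranasal-sinus and mastoid analogues) and a paired ZTE-like intensity
#' volume. The ZTE ground truth is built as the exact inverse of the
#' continuous bone-density model (bone CT = 42 + 2400 (1 - IZTE) HU), so a
#' perfect segmentation pipeline recovers the CT exactly on noiseless
#' phantoms.
#'
#' All lengths are in mm and all positions are world coordinates with the
#' origin at the volume centre. Default grid: 96 x 96 x 48 voxels at
#' 2.4 mm isotropic.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing_mm voxel size, scalar or length-3 (mm).
#' @param skull list with `outer`, `inner` (length-3 ellipsoid semi-axes,
#'   mm) and `hu_range` (`c(hu_min, hu_max)` of the bone-density profile).
#' @param scalp_mm thickness of the soft-tissue scalp layer outside the
#'   skull (mm); gives the head the soft/bone/soft sandwich of a real
#'   head, which the mask construction in the segmentation method relies
#'   on.
#' @param brain list with `grey`, `white` (semi-axes, mm) and
#'   `activity` (`c(grey, white)` levels, arbitrary units).
#' @param cavities list of `list(center = c(x, y, z), radius = r)` air
#'   pockets; must lie inside the head.
#' @param soft_hu CT value of soft tissue (HU).
#' @param zte_soft_level raw ZTE intensity of soft tissue (a.u.); the
#'   normalization step must rediscover this level rather than assume it.
#' @param zte_noise_sd additive Gaussian noise sd on the *normalized* ZTE
#'   scale (soft tissue = 1).
#' @param bias_amplitude peak fractional amplitude of a smooth
#'   multiplicative intensity bias field (sum of 3 low-order cosine modes
#'   with seeded random phases); must be in `[0, 1)`.
#' @param seed RNG seed for noise, bias phases and anything stochastic.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(96L, 96L, 48L),
                         spacing_mm = 2.4,
                         skull = list(outer = c(75, 90, 50),
                                      inner = c(67, 82, 42),
                                      hu_range = c(200, 2000)),
                         brain = list(grey = c(56, 62, 34),
                                      white = c(42, 46, 24),
                                      activity = c(grey = 4, white = 1)),
                         cavities = list(
                           list(center = c(0, 72, -8), radius = 6),
                           list(center = c(46, -30, -22), radius = 5)),
                         scalp_mm = 6,
                         soft_hu = 42,
                         zte_soft_level = 100,
                         zte_noise_sd = 0,
                         bias_amplitude = 0,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape <= 0))
    stop("grid_shape must be 3 positive integers")
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (any(spacing_mm <= 0)) stop("spacing_mm must be positive")
  if (any(skull$inner >= skull$outer))
    stop("inner skull ellipsoid must be strictly inside the outer one")
  if (any(brain$grey >= skull$inner))
    stop("grey-matter ellipsoid must be inside the inner skull")
  if (any(brain$white >= brain$grey))
    stop("white-matter ellipsoid must be inside the grey one")
  if (zte_noise_sd < 0) stop("zte_noise_sd must be >= 0")
  if (bias_amplitude < 0 || bias_amplitude >= 1)
    stop("bias_amplitude must be in [0, 1)")
  for (cv in cavities) {
    if (cv$radius <= 0) stop("cavity radius must be positive")
    # whole sphere inside the outer skull ellipsoid, conservatively via the
    # smallest semi-axis margin
    rho <- sqrt(sum((cv$center / skull$outer)^2))
    if (rho + cv$radius / min(skull$outer) >= 1)
      stop("cavity at (", paste(cv$center, collapse = ", "),
           ") is not inside the head")
  }
  if (scalp_mm < 0) stop("scalp_mm must be >= 0")
  structure(list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
                 skull = skull, brain = brain, cavities = cavities,
                 scalp_mm = scalp_mm,
                 soft_hu = soft_hu, zte_soft_level = zte_soft_level,
                 zte_noise_sd = zte_noise_sd, bias_amplitude = bias_amplitude,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# normalized ellipsoid radius on the voxel grid (1 on the surface)
ellipsoid_rho <- function(coords, semi) {
  cx <- coords$x / semi[1]; cy <- coords$y / semi[2]; cz <- coords$z / semi[3]
  sqrt(outer(outer(cx^2, cy^2, "+"), cz^2, "+"))
}

# smooth multiplicative bias field: 3 low-order cosine modes, random phases
bias_field <- function(dim, amplitude) {
  if (amplitude == 0) return(array(1, dim))
  f <- array(0, dim)
  gx <- seq_len(dim[1]) / dim[1]; gy <- seq_len(dim[2]) / dim[2]
  gz <- seq_len(dim[3]) / dim[3]
  for (m in 1:3) {
    kx <- sample(0:2, 1); ky <- sample(0:2, 1); kz <- sample(0:2, 1)
    ph <- stats::runif(3, 0, 2 * pi)
    mode <- outer(outer(cos(2 * pi * kx * gx + ph[1]),
                        cos(2 * pi * ky * gy + ph[2]), "*"),
                  cos(2 * pi * kz * gz + ph[3]), "*")
    f <- f + mode
  }
  1 + amplitude * f / max(abs(f))
}

#' Generate a synthetic paired ZTE/CT/activity head phantom
#'
#' Builds the label volume (0 background air, 1 soft tissue, 2 bone,
#' 3 interior air cavity, 4 grey matter, 5 white matter), the CT in HU
#' (air = -1000, soft = `soft_hu`, bone from a distance-weighted density
#' profile spanning `skull$hu_range`), the activity (grey/white levels,
#' zero elsewhere) and the raw ZTE intensity. The noiseless ZTE is the
#' exact inverse of the bone model: soft tissue at `zte_soft_level`, bone
#' at `zte_soft_level * (1 - (ct - 42) / 2400)`, air at zero. Multiplicative
#' bias and additive Gaussian noise (both seeded) are then applied to the
#' ZTE only.
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_bundle`: list with `ct`, `zte`, `activity`, `labels`
#'   (all `zteac_volume`s), `vois` (VOI name -> label codes) and `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("spec must be a phantom_spec")
  d <- spec$grid_shape
  vol0 <- volume(array(0, d), spec$spacing_mm)
  coords <- voxel_coords(vol0)

  rho_head <- ellipsoid_rho(coords, spec$skull$outer + spec$scalp_mm)
  rho_out <- ellipsoid_rho(coords, spec$skull$outer)
  rho_in <- ellipsoid_rho(coords, spec$skull$inner)
  rho_gm <- ellipsoid_rho(coords, spec$brain$grey)
  rho_wm <- ellipsoid_rho(coords, spec$brain$white)

  labels <- array(0L, d)
  labels[rho_head <= 1] <- 1L                     # soft tissue (incl. scalp)
  labels[rho_out <= 1 & rho_in > 1] <- 2L         # bone shell
  labels[rho_gm <= 1] <- 4L                       # grey matter
  labels[rho_wm <= 1] <- 5L                       # white matter
  for (cv in spec$cavities) {
    dist2 <- ellipsoid_rho(list(x = coords$x - cv$center[1],
                                y = coords$y - cv$center[2],
                                z = coords$z - cv$center[3]),
                           rep(cv$radius, 3))
    labels[dist2 <= 1 & labels != 0L & labels != 2L] <- 3L
  }

  # CT (HU)
  ct <- array(-1000, d)
  ct[labels == 1L | labels == 4L | labels == 5L] <- spec$soft_hu
  bone <- labels == 2L
  if (any(bone)) {
    # depth through the shell: 0 at outer surface, 1 at inner surface
    t_in <- (1 - rho_out[bone]) /
      pmax((1 - rho_out[bone]) + (rho_in[bone] - 1), 1e-12)
    hu <- spec$skull$hu_range[1] +
      diff(spec$skull$hu_range) * sin(pi * pmin(pmax(t_in, 0), 1))
    ct[bone] <- hu
  }

  # activity
  act <- array(0, d)
  act[labels == 4L] <- spec$brain$activity[["grey"]]
  act[labels == 5L] <- spec$brain$activity[["white"]]

  # ground-truth ZTE: inverse of the bone-density model, then bias + noise
  zte_n <- array(0, d)
  zte_n[labels == 1L | labels == 4L | labels == 5L] <- 1
  zte_n[bone] <- 1 - (ct[bone] - 42) / 2400
  zte <- with_seed(spec$seed, {
    b <- bias_field(d, spec$bias_amplitude)
    z <- zte_n * spec$zte_soft_level * b
    if (spec$zte_noise_sd > 0)
      z <- z + stats::rnorm(length(z),
                            sd = spec$zte_noise_sd * spec$zte_soft_level)
    pmax(z, 0)
  })
  dim(zte) <- d

  structure(list(
    ct = volume(ct, spec$spacing_mm, "hu"),
    zte = volume(zte, spec$spacing_mm, "zte"),
    activity = volume(act, spec$spacing_mm, "activity"),
    labels = volume(labels, spec$spacing_mm, "label"),
    vois = list(grey_matter = 4L, white_matter = 5L, whole_brain = c(4L, 5L)),
    spec = spec), class = "phantom_bundle")
}

#' @export
print.phantom_bundle <- function(x, ...) {
  d <- dim(x$labels$data)
  cat(sprintf("<phantom_bundle> %d x %d x %d voxels, seed %d\n",
              d[1], d[2], d[3], x$spec$seed))
  tb <- table(x$labels$data)
  cat("  label counts:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Generate a cohort of anatomically varied phantoms
#'
#' Stand-in for a patient cohort: each subject gets skull/brain ellipsoid
#' semi-axes jittered by up to `jitter` (fraction, uniform), cavity radii
#' jittered likewise, and its own noise/bias realization. Deterministic
#' given `seed`.
#'
#' @param n number of subjects.
#' @param seed master seed; subject k uses `seed + k`.
#' @param jitter maximal fractional size perturbation (default 0.08).
#' @param ... overrides passed to [phantom_spec()] (e.g. `grid_shape`,
#'   `spacing_mm`, `zte_noise_sd`).
#' @return list of `phantom_bundle`s.
#' @export
phantom_cohort <- function(n, seed = 1L, jitter = 0.08, ...) {
  base <- phantom_spec(...)
  lapply(seq_len(n), function(k) {
    sk <- as.integer(seed) + k
    j <- with_seed(sk * 131L, stats::runif(8, 1 - jitter, 1 + jitter))
    sp <- base
    sp$skull$outer <- base$skull$outer * j[1]
    sp$skull$inner <- base$skull$inner * j[1] * j[2]^0.25
    sp$brain$grey <- base$brain$grey * j[3]
    sp$brain$white <- base$brain$white * j[3] * j[4]^0.25
    sp$cavities <- lapply(seq_along(base$cavities), function(ci) {
      cv <- base$cavities[[ci]]
      cv$radius <- cv$radius * j[4 + ci]
      cv$center <- cv$center * j[1]
      cv
    })
    sp$seed <- sk
    generate_phantom(sp)
  })
}

#' Volume-of-interest masks of a phantom
#'
#' @param bundle a `phantom_bundle`.
#' @return named list of logical arrays: at least `grey_matter`,
#'   `white_matter` and `whole_brain` (= grey union white).
#' @export
phantom_vois <- function(bundle) {
  if (!inherits(bundle, "phantom_bundle")) stop("need a phantom_bundle")
  lab <- bundle$labels$data
  out <- lapply(bundle$vois, function(codes) {
    m <- array(lab %in% codes, dim(lab))
    m
  })
  for (nm in c("grey_matter", "white_matter")) {
    if (sum(out[[nm]]) == 0)
      stop("phantom has no voxels for label code ",
           paste(bundle$vois[[nm]], collapse = ","), " (", nm, ")")
  }
  out
}
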