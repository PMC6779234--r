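#' Construct a 3D volume
#'
#' A `zteac_volume` wraps a numeric 3D array together with its voxel spacing
#' (mm) and a declared value semantic. Arrays follow R's column-major
#' convention with dimensions `(nx, ny, nz)`; the world coordinate of voxel
#' center `(i, j, k)` (1-based) is `(index - (dim + 1) / 2) * spacing`, i.e.
#' the origin sits at the volume center.
#'
#' @param data numeric 3D array.
#' @param spacing voxel size in mm; scalar (isotropic) or length-3 vector.
#' @param semantic what the values mean; one of `"zte"`, `"hu"`, `"mu"`,
#'   `"activity"`, `"label"`, `"mask"`, `"other"`.
#' @return an object of class `zteac_volume`.
#' @export
volume <- function(data, spacing, semantic = c("other", "zte", "hu", "mu",
                                               "activity", "label", "mask")) {
  semantic <- match.arg(semantic)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array, got ", length(dim(data)), " dimension(s)")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be a positive scalar or length-3 vector (mm)")
  structure(list(data = data, spacing = as.numeric(spacing),
                 semantic = semantic),
            class = "zteac_volume")
}

#' @export
print.zteac_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<zteac_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, semantic '%s'\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$semantic))
  rng <- range(x$data)
  cat(sprintf("  values in [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
dim.zteac_volume <- function(x) dim(x$data)

#' @export
as.array.zteac_volume <- function(x, ...) x$data

is_volume <- function(x) inherits(x, "zteac_volume")

stopifnot_volume <- function(x, name = deparse(substitute(x))) {
  if (!is_volume(x)) stop("'", name, "' must be a zteac_volume")
  invisible(x)
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("volumes have different grid shapes: ",
         paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"))
  if (max(abs(a$spacing - b$spacing)) > 1e-6)
    stop("volumes have different voxel spacings")
  invisible(TRUE)
}

#' Voxel-center world coordinates along each axis
#'
#' @param vol a `zteac_volume`.
#' @return list with numeric vectors `x`, `y`, `z` of voxel-center
#'   coordinates in mm, origin at the volume center.
#' @export
voxel_coords <- function(vol) {
  stopifnot_volume(vol)
  d <- dim(vol$data)
  lapply(stats::setNames(1:3, c("x", "y", "z")), function(a)
    (seq_len(d[a]) - (d[a] + 1) / 2) * vol$spacing[a])
}

# run expr with a fixed RNG state, restoring the caller's state afterwards
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# deterministic per-stage seed derived from a master seed and a stage name
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 9973L
  as.integer((as.integer(seed) %% 214748L) * 9973L + h)
}
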