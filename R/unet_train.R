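# head mask shared by intensity normalization and patch sampling: the
# above-Otsu-threshold mask is morphologically closed (bridging the dark
# core of dense bone) and the largest 6-connected component kept
head_mask <- function(x, close_radius = 2L) {
  thr <- otsu_threshold(as.numeric(x))
  above <- array(x > thr, dim(x))
  if (close_radius > 0)
    above <- array(.morph3d(above, dim(x), as.integer(close_radius), "close"),
                   dim(x))
  lab <- .label3d(above, dim(x))
  if (max(lab) == 0) stop("no foreground found above the Otsu threshold")
  biggest <- which.max(tabulate(lab[lab > 0]))
  array(lab == biggest, dim(x))
}

#' Training configuration for the pseudo-CT network
#'
#' Mean-squared-error loss minimized with Adam. CT targets are divided by
#' `hu_scale` so the regression targets are O(1).
#'
#' @param iterations number of optimizer steps.
#' @param batch_size patches per step.
#' @param learning_rate Adam step size.
#' @param hu_scale divisor applied to CT targets (default 1000: the network
#'   learns HU/1000).
#' @param seed RNG seed for batch sampling.
#' @param average_last the returned weights are the average of the
#'   iterates over this many final iterations (tail/Polyak averaging;
#'   0 disables). Averaging the tail of the stochastic trajectory damps
#'   the batch-to-batch jitter of the final weights and reduces the
#'   dependence of the trained model on the RNG realization.
#' @param bn_recal_batches after optimization, batch-normalization
#'   statistics are re-estimated as the average batch statistics over this
#'   many freshly sampled batches (0 disables). The exponential running
#'   average tracked during optimization can sit far from the statistics of
#'   typical inputs when batch content is heterogeneous (air-only vs
#'   head-crossing patches), which degrades frozen-statistics inference;
#'   re-estimation removes that dependence on the tail of the batch
#'   sequence.
#' @return a `train_config`.
#' @export
train_config <- function(iterations = 2000L, batch_size = 8L,
                         learning_rate = 1e-3, hu_scale = 1000, seed = 1L,
                         average_last = 100L, bn_recal_batches = 50L) {
  if (iterations < 0) stop("iterations must be >= 0")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (hu_scale <= 0) stop("hu_scale must be positive")
  if (average_last < 0) stop("average_last must be >= 0")
  if (bn_recal_batches < 0) stop("bn_recal_batches must be >= 0")
  structure(list(iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, hu_scale = hu_scale,
                 seed = as.integer(seed),
                 average_last = min(as.integer(average_last), iterations),
                 bn_recal_batches = as.integer(bn_recal_batches)),
            class = "train_config")
}

#' Randomly sample paired ZTE/CT training patches
#'
#' ZTE patches are standardized by the whole-volume in-head mean and
#' standard deviation; patch origins are uniform over all positions whose
#' patch intersects the head mask. Deterministic given `seed`.
#'
#' @param zte,ct co-registered `zteac_volume`s on the same grid.
#' @param n number of patches.
#' @param spec a [unet_spec()] (for the patch shape).
#' @param seed RNG seed.
#' @return a `patch_set`: `inputs` and `targets` arrays of dim
#'   `c(patch_shape, n)` (inputs standardized, targets raw HU), `origins`
#'   (n x 3, 1-based), and the standardization constants `mean`/`sd`.
#' @export
sample_patches <- function(zte, ct, n, spec = unet_spec(), seed = 1L) {
  stopifnot_volume(zte); stopifnot_volume(ct)
  check_same_grid(zte, ct)
  d <- dim(zte$data)
  p <- spec$patch_shape
  if (any(d < p))
    stop("volume (", paste(d, collapse = "x"),
         ") is smaller than the patch (", paste(p, collapse = "x"), ")")
  mask <- head_mask(zte$data)
  mu <- mean(zte$data[mask])
  sd_ <- stats::sd(zte$data[mask])
  if (!is.finite(sd_) || sd_ == 0)
    stop("in-head ZTE standard deviation is zero; cannot standardize")
  zs <- (zte$data - mu) / sd_
  # candidate origins: any whose patch box intersects the mask bounding box
  bb <- apply(which(mask, arr.ind = TRUE), 2, range)
  lo <- pmax(1L, bb[1, ] - p + 1L)
  hi <- pmin(d - p + 1L, bb[2, ])
  origins <- matrix(0L, n, 3)
  with_seed(seed, {
    got <- 0L
    while (got < n) {
      o <- c(sample(lo[1]:hi[1], 1), sample(lo[2]:hi[2], 1),
             sample(lo[3]:hi[3], 1))
      if (any(mask[o[1]:(o[1] + p[1] - 1), o[2]:(o[2] + p[2] - 1),
                   o[3]:(o[3] + p[3] - 1)])) {
        got <- got + 1L
        origins[got, ] <- o
      }
    }
  })
  inputs <- array(0, c(p, n))
  targets <- array(0, c(p, n))
  for (t in seq_len(n)) {
    o <- origins[t, ]
    inputs[, , , t] <- zs[o[1]:(o[1] + p[1] - 1), o[2]:(o[2] + p[2] - 1),
                          o[3]:(o[3] + p[3] - 1)]
    targets[, , , t] <- ct$data[o[1]:(o[1] + p[1] - 1),
                                o[2]:(o[2] + p[2] - 1),
                                o[3]:(o[3] + p[3] - 1)]
  }
  structure(list(inputs = inputs, targets = targets, origins = origins,
                 mean = mu, sd = sd_, patch_shape = p),
            class = "patch_set")
}

#' Pool training patches from several volumes
#' @param sets list of `patch_set`s with identical patch shapes.
#' @return one combined `patch_set`.
#' @export
combine_patches <- function(sets) {
  p <- sets[[1]]$patch_shape
  n_total <- sum(vapply(sets, function(s) dim(s$inputs)[4], 0))
  inputs <- array(unlist(lapply(sets, `[[`, "inputs")), c(p, n_total))
  targets <- array(unlist(lapply(sets, `[[`, "targets")), c(p, n_total))
  structure(list(inputs = inputs, targets = targets,
                 origins = do.call(rbind, lapply(sets, `[[`, "origins")),
                 mean = NA_real_, sd = NA_real_, patch_shape = p),
            class = "patch_set")
}

# flatten model params to one numeric vector and back (for Adam)
flatten_params <- function(p) {
  unlist(p, use.names = FALSE)
}
unflatten_params <- function(template, v) {
  rel <- utils::relist(v, template)
  # relist drops matrix dims; restore them
  restore <- function(tpl, new) {
    if (is.list(tpl)) return(mapply(restore, tpl, new, SIMPLIFY = FALSE))
    attributes(new) <- attributes(tpl)
    new
  }
  restore(template, rel)
}

#' Train the pseudo-CT network
#'
#' Stochastic minimization of the mean squared error between the network
#' output and the scaled CT target with the Adam optimizer. Deterministic
#' given the config seed. Batch-normalization running statistics are
#' updated during training and frozen for inference.
#'
#' @param model a `unet_model` from [build_model()].
#' @param patches a `patch_set` from [sample_patches()].
#' @param cfg a [train_config()].
#' @return list with `model` (trained) and `loss` (per-iteration MSE
#'   trace, on the scaled-HU scale).
#' @export
train <- function(model, patches, cfg = train_config()) {
  if (!inherits(model, "unet_model")) stop("model must be a unet_model")
  if (!inherits(patches, "patch_set")) stop("patches must be a patch_set")
  n_avail <- dim(patches$inputs)[4]
  if (is.na(n_avail) || n_avail < 1) stop("patch set is empty")
  if (cfg$iterations == 0L)
    return(list(model = model, loss = numeric(0)))
  p <- patches$patch_shape
  theta <- flatten_params(model$params)
  m_adam <- numeric(length(theta)); v_adam <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  loss_trace <- numeric(cfg$iterations)
  with_seed(cfg$seed, {
    for (it in seq_len(cfg$iterations)) {
      idx <- sample.int(n_avail, cfg$batch_size, replace = TRUE)
      x <- patches$inputs[, , , idx, drop = FALSE]
      dim(x) <- c(1L, p, cfg$batch_size)
      tgt <- patches$targets[, , , idx, drop = FALSE] / cfg$hu_scale
      dim(tgt) <- c(1L, p, cfg$batch_size)
      fw <- unet_forward(model, x, train = TRUE)
      model$bn_state <- fw$bn_state
      resid <- fw$out - tgt
      loss <- mean(resid^2)
      if (!is.finite(loss))
        stop(sprintf(
          "training diverged: non-finite loss at iteration %d (lr = %g)",
          it, cfg$learning_rate))
      loss_trace[it] <- loss
      g <- unet_backward(model, fw$cache, 2 * resid / length(resid))
      gv <- flatten_params(g)
      m_adam <- beta1 * m_adam + (1 - beta1) * gv
      v_adam <- beta2 * v_adam + (1 - beta2) * gv^2
      mh <- m_adam / (1 - beta1^it)
      vh <- v_adam / (1 - beta2^it)
      theta <- theta - cfg$learning_rate * mh / (sqrt(vh) + eps)
      model$params <- unflatten_params(model$params, theta)
      if (cfg$average_last > 0 && it > cfg$iterations - cfg$average_last)
        theta_tail <- if (it == cfg$iterations - cfg$average_last + 1L)
          theta else theta_tail + theta
    }
    if (cfg$average_last > 0) {
      theta <- theta_tail / cfg$average_last
      model$params <- unflatten_params(model$params, theta)
    }
    # re-estimate batch-norm statistics with the final weights: average of
    # raw batch statistics over freshly drawn batches (continues the seeded
    # RNG stream, so the whole of train() stays deterministic)
    if (cfg$bn_recal_batches > 0) {
      acc <- NULL
      for (r in seq_len(cfg$bn_recal_batches)) {
        idx <- sample.int(n_avail, cfg$batch_size, replace = TRUE)
        x <- patches$inputs[, , , idx, drop = FALSE]
        dim(x) <- c(1L, p, cfg$batch_size)
        bs <- unet_forward(model, x, train = TRUE)$bn_state
        acc <- if (is.null(acc))
          lapply(bs, function(s) list(mean = s$bmean, var = s$bvar))
        else
          Map(function(a, s) list(mean = a$mean + s$bmean,
                                  var = a$var + s$bvar), acc, bs)
      }
      model$bn_state <- lapply(acc, function(a)
        list(mean = a$mean / cfg$bn_recal_batches,
             var = a$var / cfg$bn_recal_batches))
    }
  })
  model$hu_scale <- cfg$hu_scale
  model$trained <- TRUE
  list(model = model, loss = loss_trace)
}

#' Predict a pseudo-CT volume with overlapping patches
#'
#' Sliding-window inference: the input is standardized by its own in-head
#' mean and standard deviation, tiled with stride
#' `floor(patch * (1 - overlap_fraction))` (minimum 1) with the final
#' window clamped to the grid, and overlapping predictions are averaged
#' with uniform weights. Batch normalization runs in eval mode, so
#' prediction is deterministic. The output is rescaled to HU.
#'
#' @param model a `unet_model`.
#' @param zte a `zteac_volume` of raw ZTE intensities.
#' @param overlap_fraction fraction of patch overlap in `[0, 1)`;
#'   default 0.75.
#' @return a pseudo-CT `zteac_volume` (HU).
#' @export
predict_volume <- function(model, zte, overlap_fraction = 0.75) {
  if (!inherits(model, "unet_model")) stop("model must be a unet_model")
  stopifnot_volume(zte)
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)")
  d <- dim(zte$data)
  p <- model$spec$patch_shape
  if (any(d < p))
    stop("volume (", paste(d, collapse = "x"),
         ") is smaller than the patch (", paste(p, collapse = "x"), ")")
  mask <- head_mask(zte$data)
  mu <- mean(zte$data[mask]); sd_ <- stats::sd(zte$data[mask])
  if (!is.finite(sd_) || sd_ == 0)
    stop("in-head ZTE standard deviation is zero; cannot standardize")
  zs <- (zte$data - mu) / sd_
  stride <- pmax(1L, as.integer(floor(p * (1 - overlap_fraction))))
  starts <- lapply(1:3, function(a) {
    s <- unique(c(seq(1L, d[a] - p[a] + 1L, by = stride[a]), d[a] - p[a] + 1L))
    s
  })
  origins <- as.matrix(expand.grid(starts[[1]], starts[[2]], starts[[3]]))
  acc <- array(0, d); cov <- array(0, d)
  chunk <- 16L
  for (c0 in seq(1L, nrow(origins), by = chunk)) {
    idx <- c0:min(c0 + chunk - 1L, nrow(origins))
    x <- array(0, c(1L, p, length(idx)))
    for (t in seq_along(idx)) {
      o <- origins[idx[t], ]
      x[1, , , , t] <- zs[o[1]:(o[1] + p[1] - 1), o[2]:(o[2] + p[2] - 1),
                          o[3]:(o[3] + p[3] - 1)]
    }
    pred <- unet_forward(model, x, train = FALSE)$out
    for (t in seq_along(idx)) {
      o <- origins[idx[t], ]
      sel <- list(o[1]:(o[1] + p[1] - 1), o[2]:(o[2] + p[2] - 1),
                  o[3]:(o[3] + p[3] - 1))
      acc[sel[[1]], sel[[2]], sel[[3]]] <-
        acc[sel[[1]], sel[[2]], sel[[3]]] + array(pred[1, , , , t], p)
      cov[sel[[1]], sel[[2]], sel[[3]]] <-
        cov[sel[[1]], sel[[2]], sel[[3]]] + 1
    }
  }
  stopifnot(all(cov >= 1))
  volume(acc / cov * model$hu_scale, zte$spacing, "hu")
}

#' Per-voxel window coverage of sliding-window inference
#'
#' Exposes the tiling used by [predict_volume()] so coverage can be
#' checked against an independent enumeration of window placements.
#'
#' @inheritParams predict_volume
#' @param dim grid shape.
#' @return integer array of window counts per voxel.
#' @export
prediction_coverage <- function(model, dim, overlap_fraction = 0.75) {
  p <- model$spec$patch_shape
  d <- as.integer(dim)
  stride <- pmax(1L, as.integer(floor(p * (1 - overlap_fraction))))
  starts <- lapply(1:3, function(a)
    unique(c(seq(1L, d[a] - p[a] + 1L, by = stride[a]), d[a] - p[a] + 1L)))
  cov <- array(0L, d)
  for (oz in starts[[3]]) for (oy in starts[[2]]) for (ox in starts[[1]])
    cov[ox:(ox + p[1] - 1), oy:(oy + p[2] - 1), oz:(oz + p[3] - 1)] <-
      cov[ox:(ox + p[1] - 1), oy:(oy + p[2] - 1), oz:(oz + p[3] - 1)] + 1L
  cov
}
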