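#' 3D U-net architecture specification
#'
#' Encoder of four stages of batch-normalized 3x3x3 convolutions with
#' exponential-linear-unit activation, connected by max-pooling; the
#' decoder mirrors the encoder (nearest-neighbour upsampling followed by
#' convolution) with skip concatenations, and a final 1x1x1 linear head
#' produces one output channel. The thin (third) patch axis is pooled only
#' twice so it never drops below 4: pooling factors are
#' (2,2,2), (2,2,2), (2,2,1), (2,2,1).
#'
#' @param patch_shape integer length-3; each axis must be divisible by the
#'   product of its pooling factors (16, 16, 4 by default).
#' @param filters encoder filter counts, default `c(8, 32, 32, 8)`; the
#'   decoder mirrors them.
#' @return a `unet_spec`.
#' @export
unet_spec <- function(patch_shape = c(64L, 64L, 16L),
                      filters = c(8L, 32L, 32L, 8L)) {
  patch_shape <- as.integer(patch_shape)
  filters <- as.integer(filters)
  if (length(filters) != 4L || any(filters <= 0))
    stop("filters must be 4 positive counts")
  pools <- list(c(2L, 2L, 2L), c(2L, 2L, 2L), c(2L, 2L, 1L), c(2L, 2L, 1L))
  tot <- Reduce(`*`, pools)
  for (ax in 1:3)
    if (patch_shape[ax] %% tot[ax] != 0L)
      stop("patch axis ", ax, " (", patch_shape[ax],
           ") is not divisible by its total pooling factor ", tot[ax])
  structure(list(patch_shape = patch_shape, filters = filters,
                 pools = pools), class = "unet_spec")
}

# conv stage channel plan: list of c(cin, cout) for the 8 conv stages + head
unet_channel_plan <- function(spec) {
  f <- spec$filters
  enc <- list(c(1L, f[1]), c(f[1], f[2]), c(f[2], f[3]), c(f[3], f[4]))
  dec <- list(c(f[4] + f[4], f[4]), c(f[4] + f[3], f[3]),
              c(f[3] + f[2], f[2]), c(f[2] + f[1], f[1]))
  list(enc = enc, dec = dec, head = c(f[1], 1L))
}

#' Build a 3D U-net model
#'
#' Weights use He-normal initialization, deterministic given `seed`.
#' Batch-normalization scale/shift start at 1/0 with running statistics
#' 0/1; running statistics are frozen (eval mode) at inference.
#'
#' @param spec a [unet_spec()].
#' @param seed RNG seed for the initialization.
#' @return a `unet_model`; `n_parameters(model)` gives the trainable
#'   parameter count.
#' @export
build_model <- function(spec = unet_spec(), seed = 1L) {
  if (!inherits(spec, "unet_spec")) stop("spec must be a unet_spec")
  plan <- unet_channel_plan(spec)
  init_stage <- function(ch) {
    fan_in <- ch[1] * 27L
    list(W = matrix(stats::rnorm(ch[2] * fan_in, sd = sqrt(2 / fan_in)),
                    ch[2], fan_in),
         b = rep(0, ch[2]), gamma = rep(1, ch[2]), beta = rep(0, ch[2]))
  }
  model <- with_seed(seed, {
    params <- list(enc = lapply(plan$enc, init_stage),
                   dec = lapply(plan$dec, init_stage))
    params$head <- list(
      W = matrix(stats::rnorm(plan$head[1], sd = sqrt(2 / plan$head[1])),
                 1L, plan$head[1]),
      b = 0)
    params
  })
  state <- lapply(c(plan$enc, plan$dec), function(ch)
    list(mean = rep(0, ch[2]), var = rep(1, ch[2])))
  structure(list(spec = spec, seed = as.integer(seed), params = model,
                 bn_state = state, hu_scale = 1000, trained = FALSE),
            class = "unet_model")
}

#' Trainable parameter count of a U-net model
#' @param model a `unet_model`.
#' @return integer count (weights, biases and batch-norm scale/shift).
#' @export
n_parameters <- function(model) {
  stages <- c(model$params$enc, model$params$dec)
  n <- sum(vapply(stages, function(p)
    length(p$W) + length(p$b) + length(p$gamma) + length(p$beta), 0))
  n + length(model$params$head$W) + length(model$params$head$b)
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> patch %s, filters %s, %d parameters%s\n",
              paste(x$spec$patch_shape, collapse = "x"),
              paste(x$spec$filters, collapse = ","),
              n_parameters(x), if (x$trained) " (trained)" else ""))
  invisible(x)
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# conv + batch norm + ELU; returns output and backward cache
fw_stage <- function(x, P, S, train) {
  z <- .conv3_fw(x, P$W, P$b)
  d5 <- dim(z)
  C <- d5[1]
  dim(z) <- c(C, length(z) / C)
  if (train) {
    mu <- rowMeans(z)
    v <- rowMeans(z * z) - mu * mu
    # running stats for eval mode, plus this pass's raw batch stats so the
    # trainer can re-estimate the statistics after optimization
    new_state <- list(mean = (1 - BN_MOMENTUM) * S$mean + BN_MOMENTUM * mu,
                      var = (1 - BN_MOMENTUM) * S$var + BN_MOMENTUM * v,
                      bmean = mu, bvar = v)
  } else {
    mu <- S$mean; v <- S$var; new_state <- S
  }
  inv <- 1 / sqrt(v + BN_EPS)
  xhat <- (z - mu) * inv
  y <- P$gamma * xhat + P$beta
  a <- ifelse(y > 0, y, expm1(pmin(y, 0)))
  dim(a) <- d5
  list(out = a, state = new_state,
       cache = list(x = x, xhat = xhat, inv = inv, a = a, dim5 = d5))
}

bw_stage <- function(d, P, cache) {
  C <- cache$dim5[1]
  a <- cache$a
  dim(a) <- NULL
  d <- as.numeric(d) * ifelse(a > 0, 1, a + 1)
  dim(d) <- c(C, length(d) / C)
  M <- ncol(d)
  dgamma <- rowSums(d * cache$xhat)
  dbeta <- rowSums(d)
  dxhat <- d * P$gamma
  s1 <- rowSums(dxhat)
  s2 <- rowSums(dxhat * cache$xhat)
  dz <- (cache$inv / M) * (M * dxhat - s1 - cache$xhat * s2)
  dim(dz) <- cache$dim5
  g <- .conv3_bw(cache$x, P$W, dz)
  list(dx = g$dx, dW = g$dW, db = g$db, dgamma = dgamma, dbeta = dbeta)
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[2:5]))
  out[seq_len(da[1]), , , , ] <- a
  out[da[1] + seq_len(db[1]), , , , ] <- b
  out
}

# forward pass over a batch x of dim (1, px, py, pz, B)
unet_forward <- function(model, x, train = FALSE) {
  P <- model$params
  pools <- model$spec$pools
  cache <- list(enc = vector("list", 4), dec = vector("list", 4),
                pool = vector("list", 4))
  state <- model$bn_state
  a <- x
  skips <- vector("list", 4)
  for (i in 1:4) {
    st <- fw_stage(a, P$enc[[i]], state[[i]], train)
    state[[i]] <- st$state
    cache$enc[[i]] <- st$cache
    skips[[i]] <- st$out
    mp <- .maxpool3_fw(st$out, pools[[i]])
    cache$pool[[i]] <- list(arg = mp$arg, dimx = dim(st$out))
    a <- mp$y
  }
  for (j in 1:4) {
    i <- 5 - j                      # decoder stage j undoes pooling i
    up <- .upsample3_fw(a, pools[[i]])
    cat_in <- concat_ch(up, skips[[i]])
    st <- fw_stage(cat_in, P$dec[[j]], state[[4 + j]], train)
    state[[4 + j]] <- st$state
    cache$dec[[j]] <- c(st$cache, list(n_up = dim(up)[1], pool = pools[[i]]))
    a <- st$out
  }
  d5 <- dim(a)
  am <- a; dim(am) <- c(d5[1], length(a) / d5[1])
  out <- as.numeric(P$head$W %*% am) + P$head$b
  dim(out) <- c(1L, d5[2:5])
  cache$head_in <- am
  cache$out_dim <- dim(out)
  list(out = out, cache = cache, bn_state = state)
}

# backward pass; dout has the output's shape. Returns gradients shaped
# like model$params. Decoder stage j consumes the upsampled previous
# activation concatenated with encoder skip i = 5 - j, so its input
# gradient splits into the decoder chain and a per-stage skip gradient
# that is added back when the encoder unwinds.
unet_backward <- function(model, cache, dout) {
  P <- model$params
  g <- list(enc = vector("list", 4), dec = vector("list", 4))
  dm <- matrix(as.numeric(dout), 1L)
  g$head <- list(W = dm %*% t(cache$head_in), b = sum(dm))
  d <- t(P$head$W) %*% dm                      # grad wrt last decoder output
  dim(d) <- c(ncol(P$head$W), cache$out_dim[2:5])
  d_skip <- vector("list", 4)
  for (j in 4:1) {
    i <- 5 - j
    st <- bw_stage(d, P$dec[[j]], cache$dec[[j]])
    g$dec[[j]] <- st[c("dW", "db", "dgamma", "dbeta")]
    n_up <- cache$dec[[j]]$n_up
    dx <- st$dx
    dup <- dx[seq_len(n_up), , , , , drop = FALSE]
    d_skip[[i]] <- dx[n_up + seq_len(dim(dx)[1] - n_up), , , , ,
                      drop = FALSE]
    d <- .upsample3_bw(dup, cache$dec[[j]]$pool)
    # j > 1: d is now the grad wrt decoder output j - 1;
    # j == 1: d is the grad wrt the pooled encoder bottom
  }
  d_pooled <- d
  for (i in 4:1) {
    d_s <- .maxpool3_bw(cache$pool[[i]]$arg, d_pooled,
                        cache$pool[[i]]$dimx) + d_skip[[i]]
    st <- bw_stage(d_s, P$enc[[i]], cache$enc[[i]])
    g$enc[[i]] <- st[c("dW", "db", "dgamma", "dbeta")]
    d_pooled <- st$dx
  }
  g
}
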