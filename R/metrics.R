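#' Dice similarity coefficient of two masks
#'
#' `2 |A and B| / (|A| + |B|)`. Two empty masks have Dice 1 by convention
#' (flagged via the `"empty"` attribute).
#'
#' @param a,b logical arrays of the same shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks have different shapes")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(structure(1, empty = TRUE))
  2 * sum(a & b) / (na + nb)
}

#' Jaccard coefficient of two masks
#'
#' `|A and B| / |A or B|`; satisfies `J = D / (2 - D)`.
#'
#' @inheritParams dice
#' @return Jaccard coefficient in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks have different shapes")
  u <- sum(a | b)
  if (u == 0) return(structure(1, empty = TRUE))
  sum(a & b) / u
}

#' Relative PET error map
#'
#' `100 * (test - ref) / ref` per voxel inside `mask`; voxels where the
#' reference is not strictly positive are dropped from the effective mask
#' and counted.
#'
#' @param pet_test,pet_ref `zteac_volume`s on the same grid.
#' @param mask logical array (e.g. a brain mask).
#' @return an `error_volume`: `delta_suv` (array, % units, `NA` outside the
#'   mask), `mask` (effective mask), `n_dropped`.
#' @export
delta_suv <- function(pet_test, pet_ref, mask) {
  stopifnot_volume(pet_test); stopifnot_volume(pet_ref)
  check_same_grid(pet_test, pet_ref)
  if (!identical(dim(mask), dim(pet_ref$data)))
    stop("mask shape does not match the volumes")
  eff <- mask & pet_ref$data > 0
  n_dropped <- sum(mask) - sum(eff)
  if (sum(eff) == 0) stop("no usable voxels: reference is <= 0 in the mask")
  d <- array(NA_real_, dim(mask))
  d[eff] <- 100 * (pet_test$data[eff] - pet_ref$data[eff]) / pet_ref$data[eff]
  structure(list(delta_suv = d, mask = eff, n_dropped = n_dropped,
                 spacing = pet_ref$spacing),
            class = "error_volume")
}

#' Median and interquartile summary of an error map
#'
#' Linear-interpolation (type-7) quantiles; `IQR = IQ75 - IQ25`.
#'
#' @param e an `error_volume` (or numeric vector).
#' @return named numeric: `median`, `iqr`, `iq25`, `iq75`.
#' @export
summarize_errors <- function(e) {
  x <- if (inherits(e, "error_volume")) e$delta_suv[e$mask] else e
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("no finite values to summarize")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(median = q[2], iqr = q[3] - q[1], iq25 = q[1], iq75 = q[3])
}

#' Joint histogram and agreement statistics of two PET volumes
#'
#' 2D histogram over equal-width bins spanning the pooled in-mask range.
#' R^2 is computed against the identity line (predictions = reference
#' values), not a fitted regression; RMSE is in native intensity units.
#'
#' @param pet_test,pet_ref `zteac_volume`s on the same grid.
#' @param mask logical array.
#' @param n_bins histogram bins per axis.
#' @return list: `counts` (n_bins x n_bins, test x ref), `breaks`,
#'   `r_squared`, `rmse`, `n`.
#' @export
joint_histogram <- function(pet_test, pet_ref, mask, n_bins = 64L) {
  check_same_grid(pet_test, pet_ref)
  x <- pet_test$data[mask]; y <- pet_ref$data[mask]
  if (length(x) == 0) stop("empty mask")
  rng <- range(c(x, y))
  if (diff(rng) <= 0) stop("degenerate intensity range in mask")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bx <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L),
             n_bins)
  by <- pmin(pmax(findInterval(y, breaks, rightmost.closed = TRUE), 1L),
             n_bins)
  counts <- matrix(0L, n_bins, n_bins)
  tb <- table(factor(bx, levels = seq_len(n_bins)),
              factor(by, levels = seq_len(n_bins)))
  counts[] <- as.integer(tb)
  ss_res <- sum((x - y)^2)
  ss_tot <- sum((x - mean(x))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else if (ss_res == 0) 1 else -Inf
  list(counts = counts, breaks = breaks, r_squared = r2,
       rmse = sqrt(mean((x - y)^2)), n = length(x))
}

#' Per-VOI error table across subjects
#'
#' For each VOI and subject, the mean in-VOI error; then across-subject
#' mean and sample sd (n - 1 denominator; a single subject reports sd 0
#' with `flag = "n=1"`). Also returns the inter-regional variability: the
#' sd across VOI means.
#'
#' @param errors list of `error_volume`s, one per subject.
#' @param vois named list of logical VOI masks.
#' @param method method label recorded in the table.
#' @return list: `table` (data.frame voi/method/mean/sd/n/flag),
#'   `inter_regional_sd`.
#' @export
voi_errors <- function(errors, vois, method = "unknown") {
  if (length(errors) < 1) stop("need at least one subject")
  rows <- lapply(names(vois), function(nm) {
    m <- vois[[nm]]
    subj <- vapply(errors, function(e) {
      sel <- m & e$mask
      if (sum(sel) == 0) return(NA_real_)
      mean(e$delta_suv[sel])
    }, 0)
    flag <- ""
    if (any(is.na(subj))) flag <- "empty VOI"
    n <- sum(!is.na(subj))
    mu <- mean(subj, na.rm = TRUE)
    s <- if (n > 1) stats::sd(subj[!is.na(subj)]) else 0
    if (n == 1 && flag == "") flag <- "n=1"
    data.frame(voi = nm, method = method, mean_delta_suv = mu,
               sd_delta_suv = s, n_subjects = n, flag = flag,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       inter_regional_sd = stats::sd(tab$mean_delta_suv))
}

#' Two-way repeated-measures ANOVA
#'
#' Within-subject factors `method` and `region` on a complete balanced
#' design, with Greenhouse-Geisser sphericity correction. F ratios use the
#' factor-by-subject interaction as the error term; p-values come from the
#' epsilon-corrected F distribution.
#'
#' @param x 3D numeric array `subjects x method-levels x region-levels`
#'   (dimnames optional); missing cells are an error.
#' @return data.frame with one row per effect (`method`, `region`,
#'   `method:region`): `F`, `df1`, `df2`, `eps`, `p`.
#' @export
rm_anova <- function(x) {
  if (length(dim(x)) != 3L) stop("x must be subjects x method x region")
  if (any(!is.finite(x))) stop("missing or non-finite cells; the design must be complete")
  n <- dim(x)[1]; a <- dim(x)[2]; b <- dim(x)[3]
  if (n < 2) stop("need at least 2 subjects")
  G <- mean(x)
  Si <- apply(x, 1, mean)
  Am <- apply(x, 2, mean)
  Bm <- apply(x, 3, mean)
  ABm <- apply(x, c(2, 3), mean)
  SAm <- apply(x, c(1, 2), mean)
  SBm <- apply(x, c(1, 3), mean)
  ss_a <- n * b * sum((Am - G)^2)
  ss_b <- n * a * sum((Bm - G)^2)
  ss_ab <- n * sum((ABm - outer(Am, rep(1, b)) - outer(rep(1, a), Bm) + G)^2)
  ss_as <- b * sum((SAm - outer(Si, rep(1, a)) -
                      outer(rep(1, n), Am) + G)^2)
  ss_bs <- a * sum((SBm - outer(Si, rep(1, b)) -
                      outer(rep(1, n), Bm) + G)^2)
  pred <- array(0, dim(x))
  for (i in seq_len(n)) for (j in seq_len(a)) for (k in seq_len(b))
    pred[i, j, k] <- SAm[i, j] + SBm[i, k] + ABm[j, k] - Si[i] - Am[j] -
      Bm[k] + G
  ss_abs <- sum((x - pred)^2)
  gg_eps <- function(Y, C) {
    S <- stats::cov(Y)
    M <- C %*% S %*% t(C)
    d <- nrow(M)
    (sum(diag(M))^2) / (d * sum(M^2))
  }
  norm_contrasts <- function(k) {
    C <- t(stats::contr.helmert(k))
    C / sqrt(rowSums(C^2))
  }
  eps_a <- if (a > 1) gg_eps(SAm, norm_contrasts(a)) else 1
  eps_b <- if (b > 1) gg_eps(SBm, norm_contrasts(b)) else 1
  Yab <- matrix(x, n, a * b)   # columns vary method fastest
  Cab <- kronecker(norm_contrasts(b), norm_contrasts(a))
  eps_ab <- if (a > 1 && b > 1) gg_eps(Yab, Cab) else 1
  eff <- function(name, ss, df1, ss_err, df2, eps) {
    Fv <- (ss / df1) / (ss_err / df2)
    data.frame(effect = name, F = Fv, df1 = df1, df2 = df2, eps = eps,
               p = stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }
  rbind(
    eff("method", ss_a, a - 1, ss_as, (a - 1) * (n - 1), eps_a),
    eff("region", ss_b, b - 1, ss_bs, (b - 1) * (n - 1), eps_b),
    eff("method:region", ss_ab, (a - 1) * (b - 1), ss_abs,
        (a - 1) * (b - 1) * (n - 1), eps_ab))
}

#' Post-hoc paired t-tests with Bonferroni correction
#'
#' Standard paired t per contrast; `p_corrected = min(1, p * m)` with `m`
#' the number of contrasts. Zero-variance differences are handled by
#' convention: all-zero differences give `t = 0, p = 1`; constant nonzero
#' differences give `p = 0` flagged as degenerate.
#'
#' @param pairs named list of two-column matrices (or list(x, y) pairs) of
#'   paired observations.
#' @return data.frame: contrast, t, df, p_raw, p_corrected, flag.
#' @export
posthoc_paired_t <- function(pairs) {
  m <- length(pairs)
  if (m == 0) stop("no contrasts supplied")
  rows <- lapply(seq_len(m), function(i) {
    p <- pairs[[i]]
    if (is.list(p)) p <- cbind(p[[1]], p[[2]])
    if (nrow(p) < 2) stop("contrast ", i, " has fewer than 2 pairs")
    d <- p[, 1] - p[, 2]
    flag <- ""
    if (stats::sd(d) == 0) {
      if (mean(d) == 0) { tv <- 0; pv <- 1 } else { tv <- Inf; pv <- 0 }
      flag <- "degenerate: zero variance"
      df <- length(d) - 1
    } else {
      tt <- stats::t.test(p[, 1], p[, 2], paired = TRUE)
      tv <- unname(tt$statistic); pv <- tt$p.value; df <- unname(tt$parameter)
    }
    nm <- names(pairs)[i]
    data.frame(contrast = if (is.null(nm) || nm == "") paste0("c", i) else nm,
               t = tv, df = df, p_raw = pv,
               p_corrected = min(1, pv * m), flag = flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Levene's test for homogeneity of variance (median-centred)
#'
#' Brown-Forsythe variant: a one-way ANOVA on absolute deviations from the
#' group medians.
#'
#' @param groups list of numeric vectors (each of length >= 2).
#' @return list: `W` statistic, `df1`, `df2`, `p`, `center = "median"`.
#' @export
levene <- function(groups) {
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 0L) < 2)) stop("each group needs n >= 2")
  z <- lapply(groups, function(g) abs(g - stats::median(g)))
  ni <- vapply(z, length, 0L)
  N <- sum(ni)
  zi <- vapply(z, mean, 0)
  zbar <- sum(unlist(z)) / N
  num <- sum(ni * (zi - zbar)^2) / (k - 1)
  den <- sum(vapply(seq_len(k), function(i) sum((z[[i]] - zi[i])^2), 0)) /
    (N - k)
  W <- if (den == 0) { if (num == 0) 0 else Inf } else num / den
  list(W = W, df1 = k - 1, df2 = N - k,
       p = stats::pf(W, k - 1, N - k, lower.tail = FALSE),
       center = "median")
}
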