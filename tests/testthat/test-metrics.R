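mkvol <- function(a, sp = 2) volume(a, sp, "activity")

test_that("Dice and Jaccard identities", {
  d <- c(4L, 4L, 1L)
  a <- array(FALSE, d); b <- array(FALSE, d)
  a[1:2, 1, 1] <- TRUE; a[1:2, 2, 1] <- TRUE       # |a| = 4
  b[1:2, 2, 1] <- TRUE; b[1:2, 3, 1] <- TRUE       # |b| = 4, overlap 2
  expect_equal(as.numeric(dice(a, a)), 1)
  expect_equal(as.numeric(jaccard(b, b)), 1)
  expect_equal(as.numeric(dice(a, b)), 0.5)
  expect_equal(as.numeric(jaccard(a, b)), 1 / 3)
  disj <- array(FALSE, d); disj[4, 4, 1] <- TRUE
  expect_equal(as.numeric(dice(a, disj)), 0)
  # empty-mask convention: Dice 1, flagged
  e <- array(FALSE, d)
  expect_equal(as.numeric(dice(e, e)), 1)
  expect_true(attr(dice(e, e), "empty"))
  expect_error(dice(a, array(FALSE, c(2, 2, 2))), "shapes")
})

test_that("J = D / (2 - D) on random masks", {
  set.seed(8)
  for (k in 1:20) {
    a <- array(runif(64) < 0.4, c(4, 4, 4))
    b <- array(runif(64) < 0.4, c(4, 4, 4))
    D <- as.numeric(dice(a, b)); J <- as.numeric(jaccard(a, b))
    expect_equal(J, D / (2 - D), tolerance = 1e-12)
    expect_equal(D, as.numeric(dice(b, a)))
    # brute-force set computation
    expect_equal(J, length(intersect(which(a), which(b))) /
                   max(length(union(which(a), which(b))), 1))
  }
})

test_that("relative PET error has the stated sign convention", {
  d <- c(3L, 3L, 1L)
  ref <- mkvol(array(10, d))
  m <- array(TRUE, d)
  expect_true(all(delta_suv(ref, ref, m)$delta_suv == 0))
  up <- mkvol(array(11, d))
  expect_true(all(delta_suv(up, ref, m)$delta_suv[m] == 10))
  down <- mkvol(array(9.7, d))
  expect_equal(unique(as.numeric(delta_suv(down, ref, m)$delta_suv[m])), -3,
               tolerance = 1e-12)
  # non-positive reference voxels are dropped and counted
  ref2 <- ref; ref2$data[1, 1, 1] <- 0
  e <- delta_suv(up, ref2, m)
  expect_identical(e$n_dropped, 1L)
  expect_false(e$mask[1, 1, 1])
  expect_error(delta_suv(up, mkvol(array(0, d)), m), "no usable")
})

test_that("error summaries use type-7 quantiles", {
  x <- c(-2, -1, 0, 1, 2)
  e <- structure(list(delta_suv = array(x, c(5, 1, 1)),
                      mask = array(TRUE, c(5, 1, 1))),
                 class = "error_volume")
  s <- summarize_errors(e)
  expect_equal(s[["median"]], 0)
  expect_equal(s[["iqr"]], 2)
  expect_equal(s[["iq25"]], -1)
  const <- structure(list(delta_suv = array(3.5, c(4, 1, 1)),
                          mask = array(TRUE, c(4, 1, 1))),
                     class = "error_volume")
  sc <- summarize_errors(const)
  expect_equal(sc[["median"]], 3.5)
  expect_equal(sc[["iqr"]], 0)
  set.seed(10)
  sym <- stats::rnorm(2000)
  ssym <- summarize_errors(sym)
  expect_lt(abs(ssym[["median"]] - mean(sym)), 0.1)
})

test_that("joint histogram agreement statistics", {
  set.seed(11)
  d <- c(6L, 6L, 2L)
  ref <- mkvol(array(runif(prod(d), 1, 5), d))
  m <- array(TRUE, d)
  jh <- joint_histogram(ref, ref, m, n_bins = 16)
  expect_equal(jh$r_squared, 1)
  expect_equal(jh$rmse, 0)
  # all mass on the diagonal
  expect_equal(sum(diag(jh$counts)), sum(jh$counts))
  shift <- ref; shift$data <- shift$data + 0.7
  jh2 <- joint_histogram(shift, ref, m)
  expect_equal(jh2$rmse, 0.7, tolerance = 1e-12)
  # two-pass formula oracle on a random pair
  test <- mkvol(array(runif(prod(d), 1, 5), d))
  jh3 <- joint_histogram(test, ref, m)
  x <- test$data[m]; y <- ref$data[m]
  expect_equal(jh3$rmse, sqrt(mean((x - y)^2)))
  expect_equal(jh3$r_squared, 1 - sum((x - y)^2) / sum((x - mean(x))^2))
  expect_error(joint_histogram(mkvol(array(1, d)), mkvol(array(1, d)), m),
               "degenerate")
})

test_that("VOI tables aggregate per-subject means", {
  d <- c(4L, 4L, 2L)
  m1 <- array(FALSE, d); m1[1:2, , ] <- TRUE
  m2 <- array(FALSE, d); m2[3:4, , ] <- TRUE
  vois <- list(left = m1, right = m2)
  mke <- function(v) structure(list(delta_suv = array(v, d),
                                    mask = array(TRUE, d)),
                               class = "error_volume")
  one <- voi_errors(list(mke(2)), vois, method = "zte")
  expect_true(all(one$table$mean_delta_suv == 2))
  expect_true(all(one$table$sd_delta_suv == 0))
  expect_true(all(one$table$flag == "n=1"))
  expect_equal(one$inter_regional_sd, 0)
  two <- voi_errors(list(mke(1), mke(3)), vois, method = "zte")
  expect_true(all(two$table$mean_delta_suv == 2))
  expect_equal(two$table$sd_delta_suv, rep(sqrt(2), 2), tolerance = 1e-12)
  # empty VOI flagged, not dropped
  vois$empty <- array(FALSE, d)
  fl <- voi_errors(list(mke(1)), vois, method = "zte")
  expect_identical(fl$table$flag[fl$table$voi == "empty"], "empty VOI")
  expect_identical(nrow(fl$table), 3L)
})

test_that("repeated-measures ANOVA matches a sums-of-squares oracle", {
  # textbook-style 2-factor within-subject data (5 subjects, 2 x 3 design)
  set.seed(12)
  n <- 5; a <- 2; b <- 3
  x <- array(stats::rnorm(n * a * b, mean = rep(c(10, 12), each = n)),
             c(n, a, b))
  res <- rm_anova(x)
  # independent oracle: car's multivariate repeated-measures machinery
  skip_if_not_installed("car")
  Y <- matrix(x, n, a * b)
  idata <- expand.grid(method = factor(seq_len(a)),
                       region = factor(seq_len(b)))
  fit <- stats::lm(Y ~ 1)
  av <- car::Anova(fit, idata = idata, idesign = ~ method * region,
                   type = 3)
  sm <- suppressWarnings(summary(av, multivariate = FALSE))
  uni <- sm$univariate.tests
  expect_equal(res$F[res$effect == "method"], uni["method", "F value"],
               tolerance = 1e-8)
  expect_equal(res$F[res$effect == "region"], uni["region", "F value"],
               tolerance = 1e-8)
  expect_equal(res$F[res$effect == "method:region"],
               uni["method:region", "F value"], tolerance = 1e-8)
  gg <- sm$pval.adjustments
  expect_equal(res$eps[res$effect == "region"], gg["region", "GG eps"],
               tolerance = 1e-8)
  expect_equal(res$eps[res$effect == "method:region"],
               gg["method:region", "GG eps"], tolerance = 1e-8)
  # 2-level factor: sphericity is vacuous, epsilon exactly 1
  expect_equal(res$eps[res$effect == "method"], 1)
})

test_that("null effects give F near 0 and p near 1", {
  set.seed(13)
  n <- 6
  subj <- stats::rnorm(n)
  x <- array(rep(subj, 4), c(n, 2, 2))  # no method/region differences
  x <- x + stats::rnorm(length(x), sd = 1e-8)
  res <- rm_anova(x)
  expect_lt(res$F[res$effect == "method"], 5)
  res2 <- rm_anova(array(rep(subj, 4), c(n, 2, 2)) +
                     array(stats::rnorm(n * 4), c(n, 2, 2)))
  expect_true(all(res2$p >= 0 & res2$p <= 1))
  expect_error(rm_anova(array(c(NA, 1:7), c(2, 2, 2))), "complete")
})

test_that("post-hoc paired t-tests with Bonferroni correction", {
  # hand-computable differences {1, 1, 2}
  p <- cbind(c(2, 3, 5), c(1, 2, 3))
  res <- posthoc_paired_t(list(ab = p))
  dbar <- mean(c(1, 1, 2)); sdd <- stats::sd(c(1, 1, 2))
  expect_equal(res$t, dbar / (sdd / sqrt(3)), tolerance = 1e-12)
  expect_equal(res$p_corrected, res$p_raw)
  # identical pairs: t = 0, p = 1 by convention
  same <- cbind(1:4, 1:4)
  r2 <- posthoc_paired_t(list(same = same))
  expect_equal(r2$t, 0)
  expect_equal(r2$p_raw, 1)
  # constant nonzero difference: degenerate, p = 0
  r3 <- posthoc_paired_t(list(c1 = cbind(2:5, 1:4)))
  expect_equal(r3$p_raw, 0)
  expect_match(r3$flag, "degenerate")
  # Bonferroni arithmetic: m contrasts multiply the raw p
  many <- replicate(10, cbind(stats::rnorm(8), stats::rnorm(8)),
                    simplify = FALSE)
  rm_ <- posthoc_paired_t(many)
  expect_equal(rm_$p_corrected, pmin(1, rm_$p_raw * 10))
  expect_error(posthoc_paired_t(list(cbind(1, 2))), "fewer than 2")
})

test_that("median-centred Levene test matches the direct formula and car", {
  g1 <- c(1, 2, 3, 4, 5)
  g2 <- c(2, 4, 6, 8, 10)
  res <- levene(list(g1, g2))
  skip_if_not_installed("car")
  df <- data.frame(y = c(g1, g2),
                   g = factor(rep(1:2, times = c(5, 5))))
  lv <- car::leveneTest(y ~ g, data = df, center = stats::median)
  expect_equal(res$W, lv[1, "F value"], tolerance = 1e-10)
  expect_equal(res$p, lv[1, "Pr(>F)"], tolerance = 1e-10)
  # identical groups: W = 0
  expect_equal(levene(list(g1, g1))$W, 0)
  expect_error(levene(list(g1)), "2 groups")
})

test_that("Levene type-I error stays at or below nominal under equal variances", {
  # the median-centred variant is mildly conservative at moderate n, so the
  # calibrated property is: rejection rate <= alpha (within sampling error)
  # and not degenerate at zero
  set.seed(14)
  rejections <- vapply(1:400, function(i) {
    gs <- list(stats::rnorm(20), stats::rnorm(20), stats::rnorm(20))
    levene(gs)$p < 0.05
  }, TRUE)
  rate <- mean(rejections)
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / 400))
  expect_gt(rate, 0)
})
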