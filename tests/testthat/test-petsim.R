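test_that("central ray through a uniform disk integrates to the chord", {
  n <- 64; sp <- 2; R <- 40
  v <- volume(array(0, c(n, n, 1)), sp)
  cc <- voxel_coords(v)
  v$data[, , 1] <- outer(cc$x, cc$y, function(x, y)
    as.numeric(x^2 + y^2 <= R^2))
  g <- scan_geometry(4, 91, 2)
  s <- project(v, g)
  centre <- which.min(abs(g$offsets))
  expect_lt(abs(s$data[1, centre, 1] - 2 * R) / (2 * R), 0.01)
  # linearity: zero volume projects to zero
  z <- project(volume(array(0, c(n, n, 1)), sp), g)
  expect_true(all(z$data == 0))
})

test_that("projector matches a dense ray-sampling oracle", {
  set.seed(42)
  v <- volume(array(runif(64), c(8, 8, 1)), 3)
  # even bin count: no test ray lies exactly on a voxel-boundary plane,
  # where the line integral itself is ambiguous
  g <- scan_geometry(7, 14, 2.6)
  s <- project(v, g)
  for (a in seq_len(7)) for (b in seq_len(14)) {
    o <- ray_oracle(v$data[, , 1], 3, g$angles[a], g$offsets[b],
                    step_frac = 200)
    d <- s$data[a, b, 1]
    if (o > 3) {
      expect_lt(abs(d - o) / o, 0.005)
    } else {
      # grazing rays: compare at the oracle's own resolution
      expect_lt(abs(d - o), 0.05)
    }
  }
})

test_that("projector and backprojector are adjoint", {
  set.seed(1)
  g <- scan_geometry(7, 15, 3)
  x <- volume(array(runif(8 * 8 * 2), c(8, 8, 2)), 3)
  y <- array(runif(7 * 15 * 2), c(7, 15, 2))
  Px <- project(x, g)
  sy <- structure(list(data = y, geometry = g, semantic = "line-integral"),
                  class = "sinogram")
  Pty <- backproject(sy, c(8, 8, 2), 3)
  expect_equal(sum(Px$data * y), sum(x$data * Pty$data), tolerance = 1e-9)
})

test_that("geometry must cover the grid diagonal", {
  v <- volume(array(1, c(8, 8, 1)), 3)
  expect_error(project(v, scan_geometry(4, 3, 3)), "cover")
})

test_that("attenuation factors follow the exponential line integral", {
  n <- 50
  mu <- volume(array(0, c(n, n, 1)), 2, "mu")
  g <- scan_geometry(2, 81, 2)
  ac0 <- attenuation_factors(mu, g)
  expect_true(all(ac0$data == 1))
  # 10 cm water slab perpendicular to the angle-0 rays
  cc <- voxel_coords(mu)
  mu$data[abs(cc$x) <= 50, , 1] <- 0.096
  acf <- attenuation_factors(mu, g)
  centre <- which.min(abs(g$offsets))
  expect_equal(acf$data[1, centre, 1], exp(0.96), tolerance = 1e-6)
  expect_true(all(acf$data >= 1))
  # doubling mu squares the ACF, ray by ray
  mu2 <- mu; mu2$data <- mu2$data * 2
  acf2 <- attenuation_factors(mu2, g)
  expect_equal(acf2$data, acf$data^2, tolerance = 1e-9)
  bad <- mu; bad$data[1] <- -0.1
  expect_error(attenuation_factors(bad, g), ">= 0")
})

test_that("count simulation is seeded, scaled and noiseless on demand", {
  v <- volume(array(0, c(16, 16, 1)), 4, "activity")
  v$data[5:12, 5:12, 1] <- 2
  g <- default_geometry(v)
  nl <- simulate_counts(v, NULL, g, Inf)
  expect_equal(nl$data, project(v, g)$data, tolerance = 1e-12)
  c1 <- simulate_counts(v, NULL, g, 1e6, seed = 9)
  c2 <- simulate_counts(v, NULL, g, 1e6, seed = 9)
  expect_identical(c1$data, c2$data)
  expect_false(identical(c1$data,
                         simulate_counts(v, NULL, g, 1e6, seed = 10)$data))
  expect_lt(abs(sum(c1$data) - 1e6), 3 * sqrt(1e6))
  expect_error(simulate_counts(volume(array(0, c(16, 16, 1)), 4), NULL, g),
               "all zero")
})

test_that("first MLEM iterate equals the dense-matrix EM update", {
  g <- scan_geometry(2, 4, 4)
  dim3 <- c(2L, 2L, 1L)
  A <- dense_system_matrix(dim3, 5, g)
  xtrue <- c(2, 1, 4, 3)
  y <- as.numeric(A %*% xtrue)
  cnt <- structure(list(data = array(y, c(2, 4, 1)), geometry = g,
                        semantic = "counts"), class = "sinogram")
  x0 <- rep(1, 4)
  fp <- as.numeric(A %*% x0)
  ratio <- ifelse(fp > 0, y / fp, 0)
  xhat <- x0 * as.numeric(t(A) %*% ratio) / pmax(colSums(A), 1e-12)
  rec <- osem(cnt, NULL, dim3, 5, recon_config(iterations = 1, subsets = 1))
  expect_equal(as.numeric(rec$data), xhat, tolerance = 1e-12)
})

test_that("MLEM log-likelihood is non-decreasing", {
  set.seed(6)
  v <- volume(array(0, c(12, 12, 1)), 4, "activity")
  cc <- voxel_coords(v)
  v$data[, , 1] <- 5 * exp(-outer(cc$x^2, cc$y^2, "+") / (2 * 15^2))
  g <- default_geometry(v)
  mu <- volume(array(0.005, c(12, 12, 1)), 4, "mu")
  acf <- attenuation_factors(mu, g)
  cnt <- simulate_counts(v, mu, g, 5e4, seed = 2)
  lls <- vapply(1:20, function(it) {
    r <- osem(cnt, acf, dim(v$data), 4,
              recon_config(iterations = it, subsets = 1))
    poisson_loglik(r, cnt, acf)
  }, 0)
  expect_true(all(diff(lls) >= -1e-6 * abs(lls[-1])))
})

test_that("noiseless consistent data reconstructs the activity", {
  v <- volume(array(0, c(32, 32, 1)), 4, "activity")
  cc <- voxel_coords(v)
  v$data[, , 1] <- 10 * exp(-outer(cc$x^2, cc$y^2, "+") / (2 * 20^2))
  g <- default_geometry(v)
  cnt <- simulate_counts(v, NULL, g, Inf)
  r <- osem(cnt, NULL, dim(v$data), 4,
            recon_config(iterations = 20, subsets = 1))
  supp <- v$data > 0.1
  nrmse <- sqrt(mean((r$data[supp] - v$data[supp])^2)) / mean(v$data[supp])
  expect_lt(nrmse, 0.05)
})

test_that("all-zero counts give an all-zero reconstruction", {
  g <- scan_geometry(4, 13, 4)
  cnt <- structure(list(data = array(0, c(4, 13, 1)), geometry = g,
                        semantic = "counts"), class = "sinogram")
  r <- osem(cnt, NULL, c(8L, 8L, 1L), 4,
            recon_config(iterations = 1, subsets = 2))
  expect_true(all(r$data == 0))
})

test_that("OSEM with subsets approximates the same solution", {
  v <- volume(array(0, c(24, 24, 1)), 4, "activity")
  cc <- voxel_coords(v)
  v$data[, , 1] <- 8 * exp(-outer(cc$x^2, cc$y^2, "+") / (2 * 18^2))
  g <- default_geometry(v)
  cnt <- simulate_counts(v, NULL, g, Inf)
  r1 <- osem(cnt, NULL, dim(v$data), 4,
             recon_config(iterations = 16, subsets = 1))
  r4 <- osem(cnt, NULL, dim(v$data), 4,
             recon_config(iterations = 4, subsets = 4))
  supp <- v$data > 0.1
  expect_lt(mean(abs(r4$data[supp] - r1$data[supp])) / mean(v$data[supp]),
            0.05)
})
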