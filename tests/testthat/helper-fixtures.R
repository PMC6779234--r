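# Small shared fixtures, built once per test run.

# a compact head phantom: default anatomy on a 48^3-ish grid would distort
# the skull shell, so unit tests mostly use the default grid but cache it.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, .fixture_env)) assign(name, build(), .fixture_env)
  get(name, .fixture_env)
}

# default-geometry noiseless phantom
phantom_clean <- function() fixture("clean", function()
  generate_phantom(phantom_spec()))

# noiseless phantom whose bone intensities fall strictly inside the default
# bone band [0.1, 0.85] (bone HU >= 450 maps to IZTE <= 0.83)
phantom_inband <- function() fixture("inband", function()
  generate_phantom(phantom_spec(
    skull = list(outer = c(75, 90, 50), inner = c(67, 82, 42),
                 hu_range = c(450, 2000)))))

phantom_noisy <- function() fixture("noisy", function()
  generate_phantom(phantom_spec(zte_noise_sd = 0.05, seed = 7)))

# desk-scale network training protocol used by the acceptance suite
train_desk_model <- function() benchmark_bone_dice(seed = 1L)

# dense ray-sampling oracle for the parallel-beam projector (2D slice)
ray_oracle <- function(slice, spacing, theta, offset, step_frac = 20) {
  n1 <- nrow(slice); n2 <- ncol(slice)
  step <- spacing / step_frac
  tmax <- sqrt((n1 * spacing)^2 + (n2 * spacing)^2)
  t <- seq(-tmax, tmax, by = step)
  px <- offset * cos(theta) - t * sin(theta)
  py <- offset * sin(theta) + t * cos(theta)
  i <- floor((px + n1 * spacing / 2) / spacing) + 1
  j <- floor((py + n2 * spacing / 2) / spacing) + 1
  ok <- i >= 1 & i <= n1 & j >= 1 & j <= n2
  sum(slice[cbind(i[ok], j[ok])]) * step
}

# dense system matrix of a small geometry, one basis volume at a time
dense_system_matrix <- function(dim3, spacing, g) {
  nv <- prod(dim3)
  A <- matrix(0, g$n_angles * g$n_radial * dim3[3], nv)
  for (v in seq_len(nv)) {
    e <- array(0, dim3); e[v] <- 1
    A[, v] <- as.numeric(project(volume(e, spacing), g)$data)
  }
  A
}
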