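test_that("kernel values and standard deviations", {
  expect_equal(kernel_value(laplace_kernel(10), 0), 5)
  expect_equal(kernel_value(tophat_kernel(0.1), 0.05), 5)
  expect_equal(kernel_value(tophat_kernel(0.1), 0.2), 0)
  expect_equal(kernel_value(laplace_kernel(3), 0.4), kernel_value(laplace_kernel(3), -0.4))
  expect_equal(kernel_std(laplace_kernel(10)), sqrt(2) / 10)
  # top-hat sd by direct integration oracle: int x^2 K dx = delta^2/3
  sd_num <- sqrt(quad_simpson(function(x) x^2 * kernel_value(tophat_kernel(0.1), x),
                              -0.1, 0.1))
  expect_equal(kernel_std(tophat_kernel(0.1)), sd_num, tolerance = 1e-3)
  expect_equal(kernel_std(tophat_kernel(0.1)), 0.1 / sqrt(3))
})

test_that("discrete kernel weights integrate to one", {
  for (kn in list(laplace_kernel(10), laplace_kernel(3), tophat_kernel(0.1)))
    expect_lt(abs(sum(aggdiffenv:::kernel_weights(kn, 0.01)) - 1), 1e-12)
})

test_that("convolution is linear, normalised, and matches a dense oracle", {
  g <- make_grid(0.01)
  expect_equal(convolve_kernel(laplace_kernel(10), numeric(g$n), g$dx),
               numeric(g$n))
  # u = 1 on a wide interior block: interior values ~ 1
  u <- as.numeric(abs(g$x) < 0.5)
  ku <- convolve_kernel(tophat_kernel(0.1), u, g$dx)
  expect_equal(ku[abs(g$x) < 0.35], rep(1, sum(abs(g$x) < 0.35)), tolerance = 1e-12)
  # dense matrix-multiply oracle on a random density
  set.seed(7)
  u <- exp(-(g$x / 0.2)^2) * (1 + 0.3 * sin(5 * g$x))
  w <- aggdiffenv:::kernel_weights(laplace_kernel(10), g$dx)
  rad <- (length(w) - 1L) %/% 2L
  W <- matrix(0, g$n, g$n)
  for (i in seq_len(g$n)) for (j in seq_len(g$n))
    if (abs(i - j) <= rad) W[i, j] <- w[j - i + rad + 1L]
  expect_lt(max(abs(convolve_kernel(laplace_kernel(10), u, g$dx) - W %*% u)), 1e-12)
})

test_that("convolution preserves mass for interior-supported densities", {
  # support must sit at least one truncation radius (30/m for Laplace)
  # inside the boundary for exact preservation
  g <- make_grid(0.002)
  u <- ifelse(abs(g$x) < 0.1, (1 + cos(pi * g$x / 0.1)), 0)
  for (kn in list(laplace_kernel(40), tophat_kernel(0.1))) {
    ku <- convolve_kernel(kn, u, g$dx)
    expect_lt(abs(sum(ku) - sum(u)) * g$dx, 1e-12)
  }
})

test_that("Laplace kernel satisfies its Green's-function identity discretely", {
  # (d^2/dx^2 - m^2)(K_m * u) ~ -m^2 u in the interior, to O(dx^2)
  m <- 10
  err_at <- function(dx) {
    g <- make_grid(dx)
    u <- exp(-(g$x / 0.15)^2)
    ku <- convolve_kernel(laplace_kernel(m), u, g$dx)
    d2 <- aggdiffenv:::second_diff(ku, g$dx)
    core <- abs(g$x) < 0.5
    max(abs(d2[core] - m^2 * ku[core] + m^2 * u[core])) / m^2
  }
  expect_lt(err_at(0.005), 5e-3)
  expect_gt(err_at(0.01) / err_at(0.005), 2.5) # ~ O(dx^2) refinement
})

test_that("convolution matches the second-order kernel approximation", {
  g <- make_grid(0.002)
  u <- exp(-(g$x / 0.25)^2)
  d2 <- aggdiffenv:::second_diff(u, g$dx)
  err <- function(m) {
    s <- kernel_std(laplace_kernel(m))
    max(abs(convolve_kernel(laplace_kernel(m), u, g$dx) - u - s^2 / 2 * d2))
  }
  # error shrinks like sigma^4 as the kernel narrows (m = 10 -> 20 halves sigma)
  expect_lt(err(20), 0.02)
  expect_gt(err(10) / err(20), 8)
})
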