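# Shared fixtures and independent oracles.

params_default <- function(gamma = 2, sigma = 0.1, p = 1)
  model_params(gamma = gamma, sigma = sigma, p = p)

params_laplace <- function(gamma = 2, m = 10, p = 1)
  model_params(gamma = gamma, m = m, p = p, family = "laplace")

# Simpson quadrature oracle on a function (independent of the package's
# closed forms).
quad_simpson <- function(f, a, b, n = 4096L) {
  xs <- seq(a, b, length.out = n + 1L)
  h <- (b - a) / n
  w <- rep(c(2, 4), length.out = n + 1L); w[c(1L, n + 1L)] <- 1
  h / 3 * sum(w * f(xs))
}

# random admissible candidate draws under a fixed seed; r drawn across both
# branches (r < 1/n and r > 1/n)
draw_candidates <- function(n_draws, seed = 42L, require_admissible = FALSE,
                            family = "fourth_order") {
  set.seed(seed)
  out <- list()
  while (length(out) < n_draws) {
    gam <- runif(1, 1.2, 5); sig <- runif(1, 0.05, 0.3)
    nn <- sample(1:16, 1); amp <- runif(1, 0, 10)
    r <- runif(1, 0.05, 1)
    pp <- if (family == "fourth_order") model_params(gam, sigma = sig, p = 1)
          else model_params(gam, m = runif(1, 5, 20), p = 1, family = "laplace")
    sol <- tryCatch(build_candidate(pp, clump_env(nn, amp), r),
                    aggdiffenv_error = function(e) NULL)
    if (is.null(sol)) next
    if (require_admissible && !is_admissible(sol)$admissible) next
    out[[length(out) + 1L]] <- sol
  }
  out
}
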