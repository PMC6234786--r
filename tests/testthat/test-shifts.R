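# Birth-death p-functions, likelihoods, shift fitting, missing-taxa profile.

p0_closed <- function(t, l, m, r) {
  1 - r * (l - m) / (r * l + (l * (1 - r) - m) * exp(-(l - m) * t))
}
p1_closed <- function(t, l, m, r) {
  r * (l - m)^2 * exp(-(l - m) * t) /
    (r * l + (l * (1 - r) - m) * exp(-(l - m) * t))^2
}

test_that("p0 limits and closed-form agreement", {
  expect_equal(bd_p0(c(0.1, 5, 80), 0.2, 0, 1), c(0, 0, 0))     # Yule, rho 1
  expect_equal(bd_p0(1e7, 0.2, 0.1, 1), 0.5, tolerance = 1e-9)  # mu/lambda
  t <- c(0, 0.5, 3, 10, 40)
  for (par in list(c(0.2, 0.1, 0.55), c(0.3, 0.0, 1), c(0.1, 0.09, 0.8))) {
    expect_equal(bd_p0(t, par[1], par[2], par[3]),
                 p0_closed(t, par[1], par[2], par[3]), tolerance = 1e-12)
    expect_equal(bd_p1(t, par[1], par[2], par[3]),
                 p1_closed(t, par[1], par[2], par[3]), tolerance = 1e-12)
  }
  # lambda == mu handled by the series guard, continuous in lambda
  expect_equal(bd_p0(5, 0.1, 0.1, 0.7), bd_p0(5, 0.1 + 1e-11, 0.1, 0.7),
               tolerance = 1e-6)
})

test_that("p0 bounds and monotonicity across a parameter grid", {
  t <- c(1, 5, 20, 60)
  mus <- seq(0, 0.18, by = 0.03)
  rhos <- c(0.2, 0.5, 0.8, 1)
  for (tt in t) {
    v_mu <- vapply(mus, function(m) bd_p0(tt, 0.2, m, 0.6), numeric(1))
    expect_true(all(diff(v_mu) >= -1e-12))        # non-decreasing in mu
    v_rho <- vapply(rhos, function(r) bd_p0(tt, 0.2, 0.05, r), numeric(1))
    expect_true(all(diff(v_rho) <= 1e-12))        # non-increasing in rho
    expect_true(all(c(v_mu, v_rho) >= 0 & c(v_mu, v_rho) < 1))
  }
  # two-epoch p0/p1 stay in (0,1)
  p <- bd_p0(seq(0, 50, by = 2.5), c(0.15, 0.05), 0.02, 0.5, 10)
  expect_true(all(p >= 0 & p < 1))
})

test_that("piecewise likelihood collapses to the constant-rate form", {
  set.seed(8)
  bt <- sort(c(30, runif(80, 0.05, 29.9)), decreasing = TRUE)
  for (par in list(c(0.15, 0.05, 0.6), c(0.08, 0, 1), c(0.2, 0.18, 0.55))) {
    a <- loglik_constant(bt, par[1], par[2], par[3])
    b <- loglik_piecewise(bt, rep(par[1], 3), rep(par[2], 3), par[3],
                          c(5, 12))
    expect_equal(a, b, tolerance = 1e-9)
  }
  # a vanishing young epoch reduces to the older epoch's constant model
  c1 <- loglik_constant(bt, 0.12, 0.03, 0.7)
  c2 <- loglik_piecewise(bt, c(0.4, 0.12), c(0.1, 0.03), 0.7, 1e-9)
  expect_equal(c1, c2, tolerance = 1e-6)
  expect_error(loglik_piecewise(bt, c(0.1, 0.2), 0, 1, 35),
               class = "drydiv_bad_epochs")
})

test_that("likelihood is continuous in rho and order-invariant", {
  set.seed(9)
  bt <- sort(c(25, runif(40, 0.1, 24.9)), decreasing = TRUE)
  expect_equal(loglik_constant(bt, 0.1, 0.02, 1),
               loglik_constant(bt, 0.1, 0.02, 0.999999), tolerance = 1e-4)
  expect_identical(loglik_piecewise(bt, c(0.2, 0.1), 0, 0.8, 10),
                   loglik_piecewise(sample(bt), c(0.2, 0.1), 0, 0.8, 10))
})

test_that("Yule MLE matches the closed form to 1e-6", {
  set.seed(10)
  bt <- extract_branching_times(simulate_bd_tree(20, 0.15, seed = 2)$tree)
  lam_hat <- (length(bt) - 1) / (sum(bt[-1]) + 2 * bt[1])
  num <- stats::optimize(function(l) -loglik_constant(bt, l, 0, 1),
                         c(1e-4, 5), tol = 1e-10)$minimum
  expect_equal(num, lam_hat, tolerance = 1e-6)
})

test_that("the true rate beats a 3x misfit in likelihood almost always", {
  set.seed(12)
  wins <- replicate(30, {
    bt <- extract_branching_times(
      simulate_bd_tree(30, 0.15, seed = sample.int(1e6, 1))$tree)
    loglik_constant(bt, 0.15, 0, 1) > loglik_constant(bt, 0.45, 0, 1)
  })
  expect_gte(mean(wins), 0.9)
})

test_that("fit_shifts nests models and recovers a strong shift", {
  sim <- simulate_bd_tree(59.89, c(0.142, 0.053), 0, 10.4, 0.55, seed = 10)
  bt <- extract_branching_times(sim$tree)
  fit <- fit_shifts(bt, kmax = 1, grid_step = 0.5, start = 4, rho = 0.55,
                    turnover = "fixed", seed = 1)
  expect_gte(fit$table$loglik[2], fit$table$loglik[1])       # nesting
  expect_equal(fit$selected, 1L)
  f1 <- fit$fits[[2]]
  expect_lt(abs(f1$shift_times - 10.4), 5)
  expect_lt(abs(f1$r[2] / 0.053 - 1), 0.6)
  # shift times are reported on the requested grid
  expect_true(min(abs(f1$shift_times - fit$grid)) < 1e-9)
})

test_that("missing-fraction profile boundaries and jump detection", {
  fx <- small_fixture()
  tr <- attr(fx$trees, "representative")
  prof <- missing_fraction_profile(tr, fx$richness, grid_step = 0.5)
  x1 <- crown_age(tr)
  at_crown <- prof[which.min(abs(prof$t - x1)), ]
  expect_equal(at_crown$observed, 2)
  expect_equal(at_crown$expected, 2, tolerance = 1e-6)
  expect_equal(at_crown$missing, 0)
  n <- ape::Ntip(tr)
  expect_equal(prof$missing[1], 1 - n / attr(prof, "N_total"))
  expect_true(all(prof$missing >= 0 & prof$missing <= 1))
  # fully sampled trees: the across-replicate median profile stays small
  set.seed(13)
  M <- sapply(1:40, function(i) {
    tr <- simulate_bd_tree(30, 0.12, rho = 1, seed = sample.int(1e6, 1))$tree
    missing_fraction_profile(tr, grid_step = 1)$missing
  })
  expect_true(all(apply(M, 1, stats::median) < 0.2))
  expect_error(
    missing_fraction_profile(tr, data.frame(clade = "all", sampled = n,
                                            described = n - 20)),
    class = "drydiv_richness_invalid")
})
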