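test_that("steady state matches the closed-form solutions", {
  # all rates 1 except gamma_m6A = 10: direct substitution
  st <- steady_state(rate_set())
  expect_equal(st$nuc_A, 1)
  expect_equal(st$nuc_m6A, 1)
  expect_equal(st$cyt_A, 1)
  expect_equal(st$cyt_m6A, 0.1)

  # nuclear decay: Nuc = alpha / (beta + delta), Cyt = beta * Nuc / gamma
  st2 <- steady_state(rate_set(alpha_A = 1, beta_A = 1, gamma_A = 1,
                               delta = 1, alpha_m6A = 0))
  expect_equal(st2$nuc_A, 0.5)
  expect_equal(st2$cyt_A, 0.5)

  # no methylated production: empty m6A pools, zero m6A level
  st3 <- steady_state_indices(rate_set(alpha_m6A = 0))
  expect_equal(st3$nuc_m6A, 0)
  expect_equal(st3$cyt_m6A, 0)
  expect_equal(st3$m6a_level, 0)
})

test_that("steady state agrees with long-time numerical integration", {
  r <- rate_set(alpha_A = 1.2, alpha_m6A = 0.5, beta_A = 0.7,
                gamma_A = 1.3, delta = 0.4, S = 10)
  ode <- simulate_dynamics(r, initial = zero_state(), times = c(1, 200),
                           method = "ode", with_indices = FALSE)
  st <- steady_state(r)
  late <- ode[ode$time == 200, ]
  for (col in c("nuc_A", "nuc_m6A", "cyt_A", "cyt_m6A")) {
    expect_equal(late[[col]], st[[col]], tolerance = 1e-8)
  }
})

test_that("steady state rejects parameter sets without an equilibrium", {
  expect_error(steady_state(rate_set(beta_A = 0, delta = 0)),
               "no steady state")
  expect_error(steady_state(rate_set(gamma_A = 0)), "no steady state")
  expect_error(rate_set(alpha_A = -1), "non-negative")
  expect_error(rate_set(alpha_A = Inf), "finite")
  # zero production makes zero export harmless
  st <- steady_state(rate_set(alpha_m6A = 0, beta_m6A = 0, gamma_m6A = 0))
  expect_equal(st$nuc_m6A, 0)
})

test_that("derived indices implement the steady-state ratio definitions", {
  s <- tibble::tibble(nuc_A = 1, nuc_m6A = 1, cyt_A = 1, cyt_m6A = 0.1)
  d <- derive_indices(s)
  expect_equal(d$gene_level, 3.1)
  expect_equal(d$m6a_level, 1.1 / 3.1)
  expect_equal(d$nuc_cyt_ratio, 2 / 1.1)
  expect_equal(d$nuc_m6a_level, 0.5)
  expect_equal(d$cyt_m6a_level, 0.1 / 1.1)

  # symmetric kinetics: half the transcripts methylated everywhere
  sym <- steady_state_indices(rate_set(S = 1))
  expect_equal(sym$nuc_m6a_level, 0.5)
  expect_equal(sym$cyt_m6a_level, 0.5)
  expect_equal(sym$m6a_level, 0.5)

  # empty cytoplasm: flagged undefined, not an error
  d2 <- derive_indices(tibble::tibble(nuc_A = 1, nuc_m6A = 1,
                                      cyt_A = 0, cyt_m6A = 0))
  expect_true(is.na(d2$cyt_m6a_level))
  expect_true(is.na(d2$nuc_cyt_ratio))

  expect_error(derive_indices(zero_state()), "degenerate")
})

test_that("selective cytoplasmic decay orders the compartment m6A levels", {
  # nuclear > whole-cell > cytoplasmic m6A level whenever
  # gamma_m6A > gamma_A, for random rate sets at steady state
  r <- random_rate_sets(100, seed = 7)
  r$beta_m6A <- r$beta_A   # equal export, the baseline assumption
  r$gamma_m6A <- r$gamma_A * withr::with_seed(8, stats::runif(100, 1.01, 20))
  d <- steady_state_indices(r)
  expect_true(all(d$nuc_m6a_level > d$m6a_level))
  expect_true(all(d$m6a_level > d$cyt_m6a_level))
})

test_that("closed-form dynamics agree with adaptive integration", {
  cases <- list(
    random_rate_sets(10, seed = 1),
    random_rate_sets(5, seed = 2, degenerate = TRUE)  # beta+delta == gamma
  )
  times <- c(0.1, 0.5, 1, 2, 5)
  for (r in cases) {
    init <- withr::with_seed(99, tibble::tibble(
      nuc_A = stats::runif(nrow(r), 0, 2),
      nuc_m6A = stats::runif(nrow(r), 0, 2),
      cyt_A = stats::runif(nrow(r), 0, 2),
      cyt_m6A = stats::runif(nrow(r), 0, 2)
    ))
    a <- simulate_dynamics(r, init, times, method = "analytic",
                           with_indices = FALSE)
    o <- simulate_dynamics(r, init, times, method = "ode",
                           with_indices = FALSE)
    for (col in c("nuc_A", "nuc_m6A", "cyt_A", "cyt_m6A")) {
      rel <- abs(a[[col]] - o[[col]]) / pmax(abs(o[[col]]), 1e-8)
      expect_lt(max(rel), 1e-6)
    }
  }
})

test_that("dynamics reproduce textbook special cases", {
  # pure nuclear export decay: half the pool gone at t = ln 2
  r <- rate_set(alpha_A = 0, alpha_m6A = 0, beta_A = 1, S = 1)
  tc <- simulate_dynamics(r, initial = tibble::tibble(
    nuc_A = 1, nuc_m6A = 0, cyt_A = 0, cyt_m6A = 0
  ), times = c(log(2)), with_indices = FALSE)
  expect_equal(tc$nuc_A, 0.5, tolerance = 1e-12)

  # two-exponential cytoplasmic transient, alpha = 0, beta = 1, gamma = 10
  tc2 <- simulate_dynamics(
    rate_set(alpha_A = 0, alpha_m6A = 0, beta_A = 1, gamma_A = 10, S = 1),
    initial = tibble::tibble(nuc_A = 1, nuc_m6A = 0, cyt_A = 0.1,
                             cyt_m6A = 0),
    times = 1, with_indices = FALSE
  )
  expected <- (1 / 9) * (exp(-1) - exp(-10)) + 0.1 * exp(-10)
  expect_equal(tc2$cyt_A, expected, tolerance = 1e-12)

  # the steady state is a fixed point of the dynamics
  r3 <- rate_set(alpha_A = 2, alpha_m6A = 0.3, beta_A = 0.8, gamma_A = 1.7)
  st <- steady_state(r3)
  tc3 <- simulate_dynamics(r3, times = c(0.5, 1, 3, 10),
                           with_indices = FALSE)
  for (col in c("nuc_A", "nuc_m6A", "cyt_A", "cyt_m6A")) {
    expect_equal(tc3[[col]], rep(st[[col]], 4), tolerance = 1e-12)
  }
})

test_that("dynamics validate their inputs", {
  r <- rate_set()
  expect_error(simulate_dynamics(r, times = c(-1, 0)), "non-negative")
  expect_error(simulate_dynamics(r, times = c(1, 1)), "increasing")
  bad <- tibble::tibble(nuc_A = -1, nuc_m6A = 0, cyt_A = 0, cyt_m6A = 0)
  expect_error(simulate_dynamics(r, initial = bad, times = 1),
               "non-negative")
})

test_that("scaling production scales pools linearly, indices unchanged", {
  r <- random_rate_sets(20, seed = 5)
  r$gamma_m6A <- 10 * r$gamma_A
  r2 <- r
  r2$alpha_A <- 3.7 * r$alpha_A
  r2$alpha_m6A <- 3.7 * r$alpha_m6A
  d1 <- steady_state_indices(r)
  d2 <- steady_state_indices(r2)
  for (col in c("nuc_A", "nuc_m6A", "cyt_A", "cyt_m6A")) {
    expect_equal(d2[[col]], 3.7 * d1[[col]], tolerance = 1e-12)
  }
  for (col in c("m6a_level", "nuc_m6a_level", "cyt_m6a_level",
                "nuc_cyt_ratio")) {
    expect_equal(d2[[col]], d1[[col]], tolerance = 1e-12)
  }
})

test_that("steady-state indices are monotone across the parameter sweep", {
  grid <- seq(0.08, 3.5, length.out = 25)
  base <- function(...) rate_set(..., S = 10)

  m6a_beta <- sapply(grid, function(b)
    steady_state_indices(base(beta_A = b))$m6a_level)
  expect_true(all(diff(m6a_beta) <= 1e-12))

  m6a_gm <- sapply(grid, function(g)
    steady_state_indices(rate_set(gamma_m6A = g))$m6a_level)
  expect_true(all(diff(m6a_gm) <= 1e-12))

  m6a_am <- sapply(grid, function(a)
    steady_state_indices(base(alpha_m6A = a))$m6a_level)
  expect_true(all(diff(m6a_am) >= -1e-12))

  ncr_am <- sapply(grid, function(a)
    steady_state_indices(base(alpha_m6A = a))$nuc_cyt_ratio)
  expect_true(all(diff(ncr_am) >= -1e-12))
})

test_that("model variants transform rates as named", {
  base <- rate_set(gamma_A = 0.7, S = 10)
  expect_equal(apply_variant(base, "ko")$gamma_m6A, base$gamma_A)
  expect_equal(apply_variant(base, "export_facilitated")$beta_m6A,
               10 * base$beta_A)
  expect_equal(apply_variant(base, "export_inhibited")$beta_m6A,
               0.1 * base$beta_A)
  expect_equal(apply_variant(base, "baseline", S = 10)$gamma_m6A,
               10 * base$gamma_A)
  nd <- apply_variant(base, "nuclear_decay", delta = 0.3)
  expect_equal(nd$delta, 0.3)
  expect_error(apply_variant(base, "unknown"))
  # the base table is untouched
  invisible(apply_variant(base, "ko"))
  expect_equal(base$gamma_m6A, 7)
})
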