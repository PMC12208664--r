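# Shared fixture builders; everything is generated in code under fixed
# seeds so the suite is self-contained.

tiny_cohort <- function(n = 50, seed = 42, ...) {
  sample_rates(n, seed = seed, ...)
}

zero_state <- function() {
  tibble::tibble(nuc_A = 0, nuc_m6A = 0, cyt_A = 0, cyt_m6A = 0)
}

# n random rate sets with rates well away from zero, optionally forcing
# the beta == gamma degeneracy for one species.
random_rate_sets <- function(n, seed, degenerate = FALSE) {
  withr::with_seed(seed, {
    r <- tibble::tibble(
      gene_id = paste0("r", seq_len(n)),
      alpha_A = stats::runif(n, 0.1, 3),
      alpha_m6A = stats::runif(n, 0.1, 3),
      beta_A = stats::runif(n, 0.1, 3),
      beta_m6A = stats::runif(n, 0.1, 3),
      gamma_A = stats::runif(n, 0.1, 3),
      gamma_m6A = stats::runif(n, 0.1, 3),
      delta = sample(c(0, 0.5), n, replace = TRUE),
      S = 1
    )
    if (degenerate) {
      r$gamma_A <- r$beta_A + r$delta   # exact two-equal-eigenvalue case
    }
    r
  })
}

# Per-gene value of `col` at time `t`, aligned to `gene_ids`.
traj_at <- function(trajectory, t, col, gene_ids) {
  x <- trajectory[trajectory$time == t, ]
  x[[col]][match(gene_ids, x$gene_id)]
}
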