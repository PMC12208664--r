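#' Analytic steady state of the compartment model
#'
#' Solves `dNuc/dt = alpha - (beta + delta) * Nuc` and
#' `dCyt/dt = beta * Nuc - gamma * Cyt` at equilibrium for each species:
#' `Nuc = alpha / (beta + delta)` and `Cyt = beta * Nuc / gamma`, which for
#' `delta = 0` reduces to `Nuc = alpha / beta`, `Cyt = alpha / gamma`.
#'
#' A species with zero production has empty pools regardless of the other
#' rates. A species with positive production but zero export and zero
#' nuclear decay (or zero cytoplasmic decay) accumulates without bound and
#' has no steady state; this is an error.
#'
#' @param rates A rate table ([rate_set()], [sample_rates()]).
#' @return The input table with pool columns `nuc_A`, `nuc_m6A`, `cyt_A`,
#'   `cyt_m6A` appended (abundances in arbitrary copy units).
#' @examples
#' steady_state(rate_set())  # nuc_A = nuc_m6A = cyt_A = 1, cyt_m6A = 0.1
#' @export
steady_state <- function(rates) {
  validate_rates(rates)
  out <- rates
  for (sp in c("A", "m6A")) {
    alpha <- rates[[paste0("alpha_", sp)]]
    beta <- rates[[paste0("beta_", sp)]]
    gamma <- rates[[paste0("gamma_", sp)]]
    b <- beta + rates$delta
    bad <- alpha > 0 & (b <= 0 | gamma <= 0)
    if (any(bad)) {
      stop("no steady state for species ", sp, " in row(s) ",
           paste(which(bad), collapse = ", "),
           ": production > 0 requires export + nuclear decay > 0 and ",
           "cytoplasmic decay > 0", call. = FALSE)
    }
    nuc <- ifelse(alpha > 0, alpha / b, 0)
    cyt <- ifelse(alpha > 0, beta * nuc / gamma, 0)
    out[[paste0("nuc_", sp)]] <- nuc
    out[[paste0("cyt_", sp)]] <- cyt
  }
  out
}

#' Derived steady-state indices of a compartment state
#'
#' From the four pools (`nuc_A`, `nuc_m6A`, `cyt_A`, `cyt_m6A`) computes:
#' * `gene_level`: total abundance over both species and compartments;
#' * `nuc_m6a_level`: methylated fraction of the nuclear pool;
#' * `cyt_m6a_level`: methylated fraction of the cytoplasmic pool;
#' * `m6a_level`: methylated fraction over the whole cell;
#' * `nuc_cyt_ratio`: total nuclear over total cytoplasmic abundance.
#'
#' A fraction whose compartment is empty is undefined and reported as `NA`
#' (e.g. `cyt_m6a_level` when the cytoplasm holds no transcripts); a row
#' whose four pools are all zero is degenerate and raises an error.
#'
#' @param state A table holding the four pool columns (e.g. the output of
#'   [steady_state()] or one timepoint of [simulate_dynamics()]).
#' @return The input with the five index columns appended (dimensionless).
#' @examples
#' derive_indices(steady_state(rate_set()))$m6a_level  # 1.1 / 3.1
#' @export
derive_indices <- function(state) {
  missing <- setdiff(pool_cols, names(state))
  if (length(missing) > 0) {
    stop("state is missing pool column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pools <- as.matrix(state[pool_cols])
  if (!all(is.finite(pools)) || any(pools < 0)) {
    stop("pools must be finite and non-negative", call. = FALSE)
  }
  nuc <- state$nuc_A + state$nuc_m6A
  cyt <- state$cyt_A + state$cyt_m6A
  total <- nuc + cyt
  if (any(total == 0)) {
    stop("degenerate all-zero state in row(s) ",
         paste(which(total == 0), collapse = ", "), call. = FALSE)
  }
  out <- state
  out$gene_level <- total
  out$nuc_m6a_level <- ifelse(nuc > 0, state$nuc_m6A / nuc, NA_real_)
  out$cyt_m6a_level <- ifelse(cyt > 0, state$cyt_m6A / cyt, NA_real_)
  out$m6a_level <- (state$nuc_m6A + state$cyt_m6A) / total
  out$nuc_cyt_ratio <- ifelse(cyt > 0, nuc / cyt, NA_real_)
  out
}

#' Steady state plus derived indices in one call
#'
#' @inheritParams steady_state
#' @return The rate table with pools and the five derived indices appended.
#' @export
steady_state_indices <- function(rates) {
  derive_indices(steady_state(rates))
}
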