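#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

# Canonical rate columns; every kinetic function expects these.
rate_cols <- c("alpha_A", "alpha_m6A", "beta_A", "beta_m6A",
               "gamma_A", "gamma_m6A", "delta")

pool_cols <- c("nuc_A", "nuc_m6A", "cyt_A", "cyt_m6A")

index_cols <- c("gene_level", "nuc_m6a_level", "cyt_m6a_level",
                "m6a_level", "nuc_cyt_ratio")

#' Construct a rate set for the two-species compartment model
#'
#' Each transcript species (unmethylated `A`, methylated `m6A`) is produced
#' in the nucleus at rate `alpha`, exported at rate `beta`, and degraded in
#' the cytoplasm at rate `gamma`; `delta` is an optional nuclear decay rate
#' shared by both species. Under the baseline parameterization export rates
#' are equal (`beta_m6A = beta_A`) and methylated transcripts decay faster
#' by the selectivity factor `S` (`gamma_m6A = S * gamma_A`).
#'
#' Rates are in arbitrary, mutually consistent per-unit-time units; no
#' physical time unit is imposed.
#'
#' @param alpha_A,alpha_m6A Production rates of the two species.
#' @param beta_A Export rate of unmethylated transcripts.
#' @param gamma_A Cytoplasmic decay rate of unmethylated transcripts.
#' @param S Decay selectivity multiplier; used to default `gamma_m6A`.
#' @param beta_m6A Export rate of methylated transcripts
#'   (default: equal to `beta_A`).
#' @param gamma_m6A Cytoplasmic decay rate of methylated transcripts
#'   (default: `S * gamma_A`).
#' @param delta Nuclear decay rate (default 0, i.e. the baseline model).
#' @param gene_id Optional gene identifier(s).
#'
#' @return A tibble with one row per gene and columns `gene_id`, the seven
#'   rates, and `S`.
#' @examples
#' rate_set()                      # all rates 1, S = 10
#' rate_set(gamma_A = 2, S = 10)   # gamma_m6A = 20
#' @export
rate_set <- function(alpha_A = 1, alpha_m6A = 1, beta_A = 1, gamma_A = 1,
                     S = 10, beta_m6A = beta_A, gamma_m6A = S * gamma_A,
                     delta = 0, gene_id = NULL) {
  rates <- tibble::tibble(
    alpha_A = alpha_A, alpha_m6A = alpha_m6A,
    beta_A = beta_A, beta_m6A = beta_m6A,
    gamma_A = gamma_A, gamma_m6A = gamma_m6A,
    delta = delta, S = S
  )
  if (is.null(gene_id)) gene_id <- paste0("gene_", seq_len(nrow(rates)))
  rates <- tibble::add_column(rates, gene_id = gene_id, .before = 1)
  validate_rates(rates)
  rates
}

validate_rates <- function(rates) {
  missing <- setdiff(rate_cols, names(rates))
  if (length(missing) > 0) {
    stop("rate table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(rates[rate_cols])
  if (!all(is.finite(vals))) {
    stop("all rates must be finite", call. = FALSE)
  }
  if (any(vals < 0)) {
    stop("all rates must be non-negative", call. = FALSE)
  }
  invisible(rates)
}

variant_names <- c("baseline", "nuclear_decay", "export_facilitated",
                   "export_inhibited", "ko")

#' Apply a named model variant to a rate table
#'
#' Variants re-parameterize how methylation affects export and decay:
#' * `baseline`: `beta_m6A = beta_A`, `gamma_m6A = S * gamma_A`, `delta = 0`.
#' * `nuclear_decay`: baseline relationships plus nuclear decay `delta > 0`.
#' * `export_facilitated`: `beta_m6A = 10 * beta_A`.
#' * `export_inhibited`: `beta_m6A = 0.1 * beta_A`.
#' * `ko`: writer/reader loss of function, `gamma_m6A = gamma_A`
#'   (no m6A-facilitated cytoplasmic degradation).
#'
#' The input table is not modified; a transformed copy is returned.
#'
#' @param rates A rate table as returned by [rate_set()] or [sample_rates()].
#' @param variant One of `r paste0('"', variant_names, '"', collapse = ", ")`.
#' @param S Selectivity factor used by `baseline`/`nuclear_decay`; defaults
#'   to the table's `S` column (or 10 if absent).
#' @param delta Nuclear decay rate for `nuclear_decay` (default 1, on the
#'   same unit scale as the other rates).
#' @return A rate table of the same shape.
#' @examples
#' apply_variant(rate_set(), "ko")$gamma_m6A        # == gamma_A
#' apply_variant(rate_set(), "export_facilitated")  # beta_m6A = 10 * beta_A
#' @export
apply_variant <- function(rates, variant = variant_names, S = NULL,
                          delta = 1) {
  variant <- match.arg(variant)
  validate_rates(rates)
  out <- rates
  if (is.null(S)) S <- if ("S" %in% names(out)) out$S else 10
  switch(variant,
    baseline = {
      out$beta_m6A <- out$beta_A
      out$gamma_m6A <- S * out$gamma_A
      out$delta <- 0
      out$S <- S
    },
    nuclear_decay = {
      out$beta_m6A <- out$beta_A
      out$gamma_m6A <- S * out$gamma_A
      out$delta <- delta
      out$S <- S
    },
    export_facilitated = {
      out$beta_m6A <- 10 * out$beta_A
    },
    export_inhibited = {
      out$beta_m6A <- 0.1 * out$beta_A
    },
    ko = {
      out$gamma_m6A <- out$gamma_A
      out$S <- 1
    }
  )
  out
}
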