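#' Fit a half-life from a transcription-shutoff decay course
#'
#' Regresses natural-log abundance on time by ordinary least squares. The
#' slope is the decay rate `k`; the half-life `HL = ln(2) / (-k)` is
#' reported only when the slope is negative with a two-sided p-value below
#' `alpha` (the standard t-test on the regression slope). A perfect
#' zero-residual fit is treated as `p = 0`, so ideal exponential input
#' always passes the filter.
#'
#' Non-positive abundances have no logarithm; the fit is returned as failed
#' (`passed = FALSE`, everything `NA`) rather than raising, so a single bad
#' series does not abort a cohort-level pipeline.
#'
#' @param abundance Positive abundances (TPM, normalized counts, ...).
#' @param times Matching timepoints (>= 3 required).
#' @param log_base Base in which to additionally report the slope
#'   (`slope_user`); `k` and the half-life always use natural log.
#' @param alpha Significance threshold for the slope filter.
#' @return A `half_life_fit` object with fields `k`, `se`, `p_value`,
#'   `half_life`, `passed`, `n_points`, `r_squared`.
#' @examples
#' fit <- fit_half_life(exp(-log(2) * 0:3), 0:3)
#' fit$half_life  # 1
#' @export
fit_half_life <- function(abundance, times, log_base = exp(1),
                          alpha = 0.05) {
  if (length(abundance) != length(times)) {
    stop("abundance and times must have equal length", call. = FALSE)
  }
  keep <- is.finite(abundance) & is.finite(times)
  abundance <- abundance[keep]; times <- times[keep]
  if (length(times) < 3) {
    stop("need at least 3 timepoints to fit a decay rate", call. = FALSE)
  }
  failed <- function() {
    new_half_life_fit(k = NA_real_, se = NA_real_, p_value = NA_real_,
                      half_life = NA_real_, passed = FALSE,
                      n_points = length(times), r_squared = NA_real_)
  }
  if (any(abundance <= 0)) return(failed())

  y <- log(abundance)
  fit <- ols_slope(times, y)
  slope_user <- fit$k / log(log_base)
  hl <- if (fit$passed_sign && fit$p_value < alpha) log(2) / -fit$k
        else NA_real_
  new_half_life_fit(k = fit$k, se = fit$se, p_value = fit$p_value,
                    half_life = hl,
                    passed = fit$passed_sign && fit$p_value < alpha,
                    n_points = length(times), r_squared = fit$r_squared,
                    slope_user = slope_user)
}

# closed-form simple linear regression with slope t-test; residual
# variance indistinguishable from zero => p = 0 (perfect fit).
ols_slope <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  k <- sum((x - mean(x)) * (y - mean(y))) / sxx
  resid <- y - (mean(y) + k * (x - mean(x)))
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - 2)
  if (sigma2 < 1e-24 * max(tss, 1)) {
    se <- 0
    p <- 0
  } else {
    se <- sqrt(sigma2 / sxx)
    p <- 2 * stats::pt(-abs(k / se), df = n - 2)
  }
  list(k = k, se = se, p_value = p,
       r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
       passed_sign = k < 0)
}

new_half_life_fit <- function(..., slope_user = NA_real_) {
  structure(c(list(...), list(slope_user = slope_user)),
            class = "half_life_fit")
}

#' @export
print.half_life_fit <- function(x, ...) {
  cat("<half_life_fit> k =", format(x$k, digits = 4),
      " p =", format(x$p_value, digits = 3),
      " HL =", format(x$half_life, digits = 4),
      " passed =", x$passed, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn fit_half_life One-row tibble of the fit parameters.
#' @param x A `half_life_fit` object.
#' @param ... Unused.
#' @export
tidy.half_life_fit <- function(x, ...) {
  tibble::tibble(k = x$k, se = x$se, p_value = x$p_value,
                 half_life = x$half_life, passed = x$passed)
}

#' @describeIn fit_half_life One-row tibble of fit diagnostics.
#' @export
glance.half_life_fit <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n_points = x$n_points)
}

#' Half-lives of a cohort from simulated shutoff courses
#'
#' For each gene the model is run from its steady state with production set
#' to zero (an actinomycin-D analog) and the total abundance (both species,
#' both compartments) is fitted with the filtered log-linear regression of
#' [fit_half_life()]. The `"ko"` condition first abolishes m6A-dependent
#' decay (`gamma_m6A = gamma_A`), so `HL_KO / HL_WT` measures each gene's
#' m6A-dependent stability deficit.
#'
#' The default sampling grid is per-gene, `{0, 1, 2, 4, 8} * ln(2) /
#' gamma_A`, mimicking a shutoff course scaled to gene kinetics; a fixed
#' global grid may be supplied instead.
#'
#' @param cohort A rate table.
#' @param times Optional fixed time grid shared by all genes.
#' @param condition `"wt"` (rates as given) or `"ko"`.
#' @param alpha Slope-filter significance threshold.
#' @return A per-gene tibble: `gene_id`, `k`, `p_value`, `half_life`,
#'   `passed`, `n_points`.
#' @export
cohort_half_lives <- function(cohort, times = NULL,
                              condition = c("wt", "ko"), alpha = 0.05) {
  condition <- match.arg(condition)
  rates <- if (condition == "ko") apply_variant(cohort, "ko") else cohort
  init <- steady_state(rates)
  shutoff <- rates
  shutoff$alpha_A <- 0
  shutoff$alpha_m6A <- 0

  n <- nrow(rates)
  tm <- if (is.null(times)) {
    outer(log(2) / rates$gamma_A, c(0, 1, 2, 4, 8))
  } else {
    matrix(times, nrow = n, ncol = length(times), byrow = TRUE)
  }

  a <- closed_form_species(shutoff$alpha_A, shutoff$beta_A,
                           shutoff$gamma_A, shutoff$delta,
                           init$nuc_A, init$cyt_A, tm)
  m <- closed_form_species(shutoff$alpha_m6A, shutoff$beta_m6A,
                           shutoff$gamma_m6A, shutoff$delta,
                           init$nuc_m6A, init$cyt_m6A, tm)
  total <- a$nuc + a$cyt + m$nuc + m$cyt

  fit <- ols_slope_rows(tm, log(total))
  bad <- apply(total <= 0 | !is.finite(total), 1, any)
  passed <- !bad & fit$k < 0 & fit$p_value < alpha
  tibble::tibble(
    gene_id = if ("gene_id" %in% names(rates)) rates$gene_id
              else paste0("gene_", seq_len(n)),
    k = ifelse(bad, NA_real_, fit$k),
    p_value = ifelse(bad, NA_real_, fit$p_value),
    half_life = ifelse(passed, log(2) / -fit$k, NA_real_),
    passed = passed,
    n_points = ncol(tm)
  )
}

# Row-wise simple linear regression of y on x (matrices, one series per
# row) with the same slope t-test and perfect-fit convention as
# ols_slope().
ols_slope_rows <- function(x, y) {
  nk <- ncol(x)
  xm <- rowMeans(x); ym <- rowMeans(y)
  dx <- x - xm
  sxx <- rowSums(dx^2)
  k <- rowSums(dx * (y - ym)) / sxx
  resid <- y - ym - k * dx
  rss <- rowSums(resid^2)
  tss <- rowSums((y - ym)^2)
  sigma2 <- rss / (nk - 2)
  perfect <- sigma2 < 1e-24 * pmax(tss, 1)
  se <- sqrt(sigma2 / sxx)
  p <- 2 * stats::pt(-abs(k / se), df = nk - 2)
  p[perfect] <- 0
  list(k = k, se = ifelse(perfect, 0, se), p_value = p)
}
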