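preset_names <- c("actd", "cpt", "ythdf_ko", "export_block", "hs_induction")

#' Define an instantaneous rate perturbation
#'
#' A perturbation changes one rate (or a rate pair) at `t = 0`: production
#' `"alpha"` acts on both species jointly (as in a transcriptional drug),
#' `"alpha_A"`/`"alpha_m6A"` on one species, `"beta"` on both export rates,
#' and `"gamma_m6A"` on methylation-dependent decay. Modes: `"set"`
#' (replace with `value`), `"scale"` (multiply by `value`), and `"match"`
#' (for `"gamma_m6A"` only: set equal to the gene's `gamma_A`, i.e. abolish
#' m6A-dependent decay).
#'
#' @param target One of `"alpha"`, `"alpha_A"`, `"alpha_m6A"`, `"beta"`,
#'   `"gamma_m6A"`.
#' @param mode `"set"`, `"scale"`, or `"match"`.
#' @param value New rate (`"set"`) or multiplier (`"scale"`); ignored for
#'   `"match"`.
#' @return A `perturbation` object.
#' @seealso [perturbation_preset()] for the named experimental scenarios.
#' @export
perturbation <- function(target = c("alpha", "alpha_A", "alpha_m6A",
                                    "beta", "gamma_m6A"),
                         mode = c("set", "scale", "match"),
                         value = NULL) {
  target <- match.arg(target)
  mode <- match.arg(mode)
  if (mode == "match" && target != "gamma_m6A") {
    stop('mode "match" is only defined for target "gamma_m6A"',
         call. = FALSE)
  }
  if (mode != "match") {
    if (is.null(value) || !is.finite(value) || value < 0) {
      stop("value must be a non-negative number", call. = FALSE)
    }
  }
  structure(list(target = target, mode = mode, value = value),
            class = "perturbation")
}

#' Named perturbation presets for the classic experimental scenarios
#'
#' * `actd`: actinomycin D, transcriptional shutoff (`alpha` set to 0);
#' * `cpt`: camptothecin, reduced production (`alpha` scaled to 10%);
#' * `ythdf_ko`: loss of cytoplasmic m6A readers
#'   (`gamma_m6A` matched to `gamma_A`);
#' * `export_block`: export rates reduced to 10%;
#' * `hs_induction`: transcriptional induction (`alpha` scaled by 10).
#'
#' @param name One of `r paste0('"', preset_names, '"', collapse = ", ")`.
#' @return A `perturbation` object.
#' @examples
#' perturbation_preset("actd")
#' @export
perturbation_preset <- function(name = preset_names) {
  name <- match.arg(name)
  switch(name,
    actd = perturbation("alpha", "set", 0),
    cpt = perturbation("alpha", "scale", 0.1),
    ythdf_ko = perturbation("gamma_m6A", "match"),
    export_block = perturbation("beta", "scale", 0.1),
    hs_induction = perturbation("alpha", "scale", 10)
  )
}

#' @export
print.perturbation <- function(x, ...) {
  val <- if (x$mode == "match") "gamma_A" else format(x$value)
  cat("<perturbation> ", x$target, " ", x$mode, " ", val, "\n", sep = "")
  invisible(x)
}

#' Apply a perturbation to a rate table
#'
#' @param rates A rate table.
#' @param perturbation A [perturbation()] object or preset name.
#' @return The transformed rate table (the input is unchanged).
#' @export
apply_perturbation <- function(rates, perturbation) {
  if (is.character(perturbation)) {
    perturbation <- perturbation_preset(perturbation)
  }
  stopifnot(inherits(perturbation, "perturbation"))
  validate_rates(rates)
  out <- rates
  cols <- switch(perturbation$target,
    alpha = c("alpha_A", "alpha_m6A"),
    beta = c("beta_A", "beta_m6A"),
    perturbation$target
  )
  for (col in cols) {
    out[[col]] <- switch(perturbation$mode,
      set = rep_len(perturbation$value, nrow(out)),
      scale = out[[col]] * perturbation$value,
      match = out$gamma_A
    )
  }
  validate_rates(out)
  out
}

# Default trajectory grid: 0 plus a dense logarithmic grid reaching
# 10 / min(positive post-perturbation rates), so both fast and slow genes
# are resolved.
default_time_grid <- function(rates, n_points = 25) {
  pos <- as.matrix(rates[rate_cols])
  pos <- pos[pos > 0]
  t_max <- 10 / min(pos)
  c(0, exp(seq(log(t_max / 1e3), log(t_max), length.out = n_points)))
}

#' Run a perturbation time course on a cohort
#'
#' Each gene starts at its pre-perturbation steady state; at `t = 0` the
#' perturbation is applied and the exact post-perturbation dynamics are
#' evaluated on the time grid, with all derived indices computed at every
#' timepoint. If the post-perturbation rates admit no steady state (e.g. a
#' blocked export with continued production) the transient is still valid
#' and is simulated with a warning.
#'
#' @param cohort A rate table.
#' @param perturbation A [perturbation()] object or preset name.
#' @param times Time grid; default: `0` plus a logarithmic grid covering
#'   ten characteristic times of the slowest post-perturbation rate.
#' @return A long tibble: `gene_id`, `time`, pools, indices.
#' @examples
#' tr <- run_perturbation_course(rate_set(), "actd", times = 0:3)
#' @export
run_perturbation_course <- function(cohort, perturbation, times = NULL) {
  if (is.character(perturbation)) {
    perturbation <- perturbation_preset(perturbation)
  }
  before <- steady_state(cohort)
  after <- apply_perturbation(cohort, perturbation)
  ok <- tryCatch({ steady_state(after); TRUE }, error = function(e) FALSE)
  if (!ok) {
    warning("post-perturbation rates admit no steady state; ",
            "trajectories describe the transient only", call. = FALSE)
  }
  if (is.null(times)) times <- default_time_grid(after)
  simulate_dynamics(after, initial = before[pool_cols], times = times)
}

#' Normalize trajectory index columns
#'
#' `"t0"` divides each gene's trajectory by its value at the first
#' timepoint (so every trajectory starts at 1); `"zscore"` centers and
#' scales each gene's trajectory across timepoints (row scaling, as used
#' for trajectory heatmaps).
#'
#' @param trajectory Output of [run_perturbation_course()].
#' @param columns Character vector of columns to normalize.
#' @param method `"t0"` or `"zscore"`.
#' @return The trajectory with `<col>_norm` columns appended.
#' @export
normalize_trajectory <- function(trajectory,
                                 columns = c("m6a_level", "nuc_cyt_ratio",
                                             "gene_level"),
                                 method = c("t0", "zscore")) {
  method <- match.arg(method)
  trajectory %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::arrange(.data$time, .by_group = TRUE) %>%
    dplyr::mutate(dplyr::across(
      dplyr::all_of(columns),
      function(v) {
        if (method == "t0") v / v[1]
        else (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
      },
      .names = "{.col}_norm"
    )) %>%
    dplyr::ungroup()
}

#' Transcriptional-shutoff decline ordering
#'
#' Runs the `actd` scenario (production set to zero) and tracks two
#' t0-normalized readouts per gene: the methylated-transcript abundance
#' (`m6a_amount` = `nuc_m6A + cyt_m6A`) and the whole-cell m6A fraction
#' (`m6a_level`). With all other rates equal, genes with larger
#' cytoplasmic decay rates lose their methylated transcripts faster at
#' every timepoint; `decline_rank` orders genes by that readout
#' (1 = fastest decline). The m6A fraction behaves more subtly all else
#' being equal — a fast-decay gene becomes export-limited in both species
#' and its fraction plateaus — but across a sampled cohort both readouts
#' decline faster for shorter-lived genes.
#'
#' @param cohort A rate table.
#' @param times Time grid (default as in [run_perturbation_course()]).
#' @return A long tibble: `gene_id`, `gamma_A`, `time`, `m6a_level`,
#'   `m6a_level_norm`, `m6a_amount`, `m6a_amount_norm`, `decline_rank`.
#' @export
decay_ordering <- function(cohort, times = NULL) {
  tr <- run_perturbation_course(cohort, "actd", times = times)
  tr$m6a_amount <- tr$nuc_m6A + tr$cyt_m6A
  tr <- normalize_trajectory(tr, columns = c("m6a_level", "m6a_amount"),
                             method = "t0")
  tr %>%
    dplyr::left_join(dplyr::select(cohort, "gene_id", "gamma_A"),
                     by = "gene_id") %>%
    dplyr::group_by(.data$time) %>%
    dplyr::mutate(decline_rank = rank(.data$m6a_amount_norm,
                                      ties.method = "first")) %>%
    dplyr::ungroup() %>%
    dplyr::select("gene_id", "gamma_A", "time", "m6a_level",
                  "m6a_level_norm", "m6a_amount", "m6a_amount_norm",
                  "decline_rank")
}

#' Writer/reader knockout versus wild-type comparison
#'
#' Contrasts each gene's baseline (WT) steady state with the knockout (KO)
#' state in which m6A-dependent decay is abolished
#' (`gamma_m6A = gamma_A`). Reports the localization shift
#' `delta_nuc_cyt = log(NucCyt_WT) - log(NucCyt_KO)` and the
#' m6A-dependent half-life ratio `hl_ratio = HL_KO / HL_WT`, where each
#' half-life is fitted on the gene's transcription-shutoff total-RNA decay
#' course (see [cohort_half_lives()]).
#'
#' @param cohort A baseline rate table.
#' @param hl_times Optional fixed time grid for the half-life fits;
#'   defaults to the per-gene grid of [cohort_half_lives()].
#' @return A per-gene tibble: WT/KO m6A level and Nuc:Cyt ratio,
#'   `delta_nuc_cyt`, `hl_wt`, `hl_ko`, `hl_ratio` (NA when a fit fails).
#' @export
ko_comparison <- function(cohort, hl_times = NULL) {
  wt <- cohort_steady_state(cohort)
  ko <- cohort_steady_state(apply_variant(cohort, "ko"))
  hl_wt <- cohort_half_lives(cohort, times = hl_times, condition = "wt")
  hl_ko <- cohort_half_lives(cohort, times = hl_times, condition = "ko")
  tibble::tibble(
    gene_id = wt$gene_id,
    m6a_level_wt = wt$m6a_level,
    m6a_level_ko = ko$m6a_level,
    nuc_cyt_wt = wt$nuc_cyt_ratio,
    nuc_cyt_ko = ko$nuc_cyt_ratio,
    delta_nuc_cyt = log(wt$nuc_cyt_ratio) - log(ko$nuc_cyt_ratio),
    hl_wt = hl_wt$half_life,
    hl_ko = hl_ko$half_life,
    hl_ratio = hl_ko / hl_wt
  )
}
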