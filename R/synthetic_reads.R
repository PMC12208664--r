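#' Counting-noise model for synthetic sequencing fixtures
#'
#' Parameters of the negative-binomial read-counting layer placed on top
#' of model-derived abundances. `dispersion` is the NB overdispersion
#' shared across genes (`size = 1/dispersion`; 0 means Poisson).
#' `ip_background` is the fraction of unmethylated molecules captured in
#' an IP library (antibody background).
#'
#' @param depth Expected reads per library (> 0, or 0 for empty
#'   libraries).
#' @param dispersion NB overdispersion (>= 0).
#' @param ip_background In `[0, 1)`.
#' @param seed Integer seed making every generator a pure function of its
#'   inputs.
#' @return A `noise_model` object.
#' @export
noise_model <- function(depth = 1e6, dispersion = 0.1,
                        ip_background = 0.05, seed = 1L) {
  if (!is.finite(depth) || depth < 0) stop("depth must be >= 0",
                                           call. = FALSE)
  if (!is.finite(dispersion) || dispersion < 0) {
    stop("dispersion must be >= 0", call. = FALSE)
  }
  if (ip_background < 0 || ip_background >= 1) {
    stop("ip_background must be in [0, 1)", call. = FALSE)
  }
  structure(list(depth = depth, dispersion = dispersion,
                 ip_background = ip_background, seed = as.integer(seed)),
            class = "noise_model")
}

# NB draw with mean mu; dispersion 0 degenerates to Poisson.
rcounts <- function(mu, dispersion) {
  mu <- pmax(mu, 0)
  if (dispersion == 0) stats::rpois(length(mu), mu)
  else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

cohort_pools <- function(cohort) {
  if (!all(pool_cols %in% names(cohort))) cohort <- steady_state(cohort)
  cohort
}

make_count_table <- function(gene_id, mu_per_rep, n_reps, prefix,
                             dispersion) {
  cols <- purrr::map(seq_len(n_reps), function(r) rcounts(mu_per_rep,
                                                          dispersion))
  names(cols) <- paste0(prefix, seq_len(n_reps))
  tibble::as_tibble(c(list(gene_id = gene_id), cols))
}

#' Synthetic nuclear/cytoplasmic fractionation counts
#'
#' Expected counts in each fraction library are proportional to the
#' gene's total pool in that compartment (`nuc_A + nuc_m6A`, resp.
#' `cyt_A + cyt_m6A`), scaled to the library depth, with NB noise.
#'
#' @param cohort A rate table (steady states are computed if absent).
#' @param noise A [noise_model()].
#' @param n_reps Replicate libraries per fraction.
#' @return A list: `nuc` and `cyt` count tables, and `truth` with the
#'   generating per-gene pools and `nuc_cyt_ratio`.
#' @export
generate_fraction_counts <- function(cohort, noise, n_reps = 2) {
  stopifnot(inherits(noise, "noise_model"))
  st <- cohort_pools(cohort)
  nuc_tot <- st$nuc_A + st$nuc_m6A
  cyt_tot <- st$cyt_A + st$cyt_m6A
  withr::with_seed(noise$seed, {
    nuc <- make_count_table(st$gene_id,
                            noise$depth * nuc_tot / sum(nuc_tot),
                            n_reps, "rep", noise$dispersion)
    cyt <- make_count_table(st$gene_id,
                            noise$depth * cyt_tot / sum(cyt_tot),
                            n_reps, "rep", noise$dispersion)
  })
  truth <- dplyr::select(derive_indices_tolerant(st), "gene_id",
                         dplyr::all_of(pool_cols), "nuc_cyt_ratio")
  list(nuc = nuc, cyt = cyt, truth = truth)
}

#' Synthetic meRIP (IP/input) counts
#'
#' Input library expectations are proportional to total gene abundance;
#' IP expectations to the methylated abundance plus `ip_background` times
#' the unmethylated abundance (per-molecule capture efficiency), with NB
#' noise. By default each library is scaled to the nominal depth. With
#' `preserve_yield = TRUE` the IP expectations are instead anchored to
#' the input pool (`depth * captured / sum(total)`), so the realized IP
#' library size reflects the sample's overall methylation — the situation
#' in a pooled multiplexed IP — and the raw IP/input ratio
#' (`normalization = "none"` in [m6a_gene_index()]) estimates the
#' absolute methylated fraction.
#'
#' @inheritParams generate_fraction_counts
#' @param preserve_yield Anchor IP library size to the input pool so
#'   sample-level methylation differences survive (see Details).
#' @return A list: `ip` and `input` count tables, and `truth` with the
#'   generating `m6a_level`.
#' @export
generate_merip_counts <- function(cohort, noise, n_reps = 2,
                                  preserve_yield = FALSE) {
  stopifnot(inherits(noise, "noise_model"))
  st <- cohort_pools(cohort)
  total <- st$nuc_A + st$nuc_m6A + st$cyt_A + st$cyt_m6A
  meth <- st$nuc_m6A + st$cyt_m6A
  captured <- meth + noise$ip_background * (total - meth)
  ip_scale <- if (preserve_yield) sum(total) else sum(captured)
  withr::with_seed(noise$seed, {
    input <- make_count_table(st$gene_id,
                              noise$depth * total / sum(total),
                              n_reps, "rep", noise$dispersion)
    ip <- make_count_table(st$gene_id,
                           noise$depth * captured / ip_scale,
                           n_reps, "rep", noise$dispersion)
  })
  truth <- dplyr::select(derive_indices_tolerant(st), "gene_id",
                         "m6a_level", "gene_level")
  list(ip = ip, input = input, truth = truth)
}

#' Synthetic deamination (GLORI) site table
#'
#' For each gene, `sites_per_gene` DRACH sites are drawn with coverage
#' from `coverage_law`; the unconverted count at a site is binomial with
#' the gene's true whole-cell m6A level as success probability, and the
#' score is unconverted/coverage. Decoy non-DRACH sites with background
#' scores are interleaved. Per-gene adenosine totals are emitted for the
#' index denominator.
#'
#' @inheritParams generate_fraction_counts
#' @param sites_per_gene DRACH sites per gene (>= 1).
#' @param coverage_law Function `n -> integer coverages` (default:
#'   Poisson with mean 50, shifted by 1).
#' @param decoys_per_gene Non-DRACH decoy sites per gene.
#' @param background Deamination-resistance background score probability
#'   for decoys.
#' @param adenosine_count Adenosines per gene (scalar or per-gene vector).
#' @return A list: `sites` (site table: `site_id`, `gene_id`, `coverage`,
#'   `score`, `in_drach`), `adenosine_counts`, `truth` (`m6a_level`).
#' @export
generate_glori_sites <- function(cohort, noise, sites_per_gene = 3,
                                 coverage_law = function(n)
                                   stats::rpois(n, 50) + 1L,
                                 decoys_per_gene = 1,
                                 background = 0.01,
                                 adenosine_count = 1000) {
  stopifnot(inherits(noise, "noise_model"), sites_per_gene >= 1)
  st <- derive_indices_tolerant(cohort_pools(cohort))
  n <- nrow(st)
  level <- st$m6a_level
  withr::with_seed(noise$seed, {
    n_drach <- n * sites_per_gene
    n_decoy <- n * decoys_per_gene
    cov_d <- coverage_law(n_drach)
    cov_x <- if (n_decoy > 0) coverage_law(n_decoy) else integer(0)
    p_d <- rep(level, each = sites_per_gene)
    unconv_d <- stats::rbinom(n_drach, cov_d, p_d)
    unconv_x <- if (n_decoy > 0) stats::rbinom(n_decoy, cov_x, background)
                else integer(0)
  })
  sites <- tibble::tibble(
    gene_id = c(rep(st$gene_id, each = sites_per_gene),
                rep(st$gene_id, each = max(decoys_per_gene, 0))),
    coverage = c(cov_d, cov_x),
    score = c(unconv_d / cov_d,
              if (n_decoy > 0) unconv_x / cov_x else numeric(0)),
    in_drach = rep(c(TRUE, FALSE), c(n_drach, n_decoy))
  )
  sites <- tibble::add_column(sites,
                              site_id = sprintf("site_%05d",
                                                seq_len(nrow(sites))),
                              .before = 1)
  list(
    sites = sites,
    adenosine_counts = tibble::tibble(gene_id = st$gene_id,
                                      adenosine_count = adenosine_count),
    truth = dplyr::select(st, "gene_id", "m6a_level")
  )
}

#' Synthetic transcription-shutoff decay counts
#'
#' Runs the shutoff scenario (production set to zero) from each gene's
#' steady state and draws one library per timepoint. Expected counts are
#' scaled against the t = 0 total-RNA pool (a constant, spike-in-like
#' scale), so per-gene counts decay in proportion to absolute abundance
#' and log-linear fits of sampled counts are unbiased for the true decay
#' rate.
#'
#' @inheritParams generate_fraction_counts
#' @param times Time grid of the course (first point must be 0).
#' @return A list: `counts` (long tibble `gene_id`, `time`, `count`,
#'   `expected`), `truth` (per-gene `gamma_A`, `gamma_m6A`).
#' @export
generate_decay_counts <- function(cohort, times, noise) {
  stopifnot(inherits(noise, "noise_model"))
  if (times[1] != 0) stop("decay course must start at time 0",
                          call. = FALSE)
  st <- cohort_pools(cohort)
  shutoff <- apply_perturbation(cohort, "actd")
  tc <- simulate_dynamics(shutoff, initial = st[pool_cols], times = times,
                          with_indices = FALSE)
  tc$total <- tc$nuc_A + tc$nuc_m6A + tc$cyt_A + tc$cyt_m6A
  scale0 <- sum(tc$total[tc$time == 0])
  tc$expected <- if (scale0 > 0) noise$depth * tc$total / scale0 else 0
  withr::with_seed(noise$seed, {
    tc$count <- rcounts(tc$expected, noise$dispersion)
  })
  list(
    counts = dplyr::select(tc, "gene_id", "time", "count", "expected"),
    truth = dplyr::select(cohort, "gene_id", "gamma_A", "gamma_m6A")
  )
}
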