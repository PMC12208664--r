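#' Read and write rate tables as flat key-value configs
#'
#' A single-gene rate set round-trips through a flat YAML (or JSON)
#' mapping with keys `alpha_A`, `alpha_m6A`, `beta_A`, `beta_m6A`,
#' `gamma_A`, `gamma_m6A`, `delta`, `S`; multi-gene tables are written as
#' a list of such mappings keyed by `gene_id`.
#'
#' @param rates A rate table.
#' @param path File path (`.yaml`/`.yml`, or `.json` with jsonlite
#'   installed).
#' @return `rates_to_config()` returns `path` invisibly;
#'   `rates_from_config()` returns a rate table.
#' @export
rates_to_config <- function(rates, path) {
  validate_rates(rates)
  keys <- c(rate_cols, "S")
  entries <- purrr::map(seq_len(nrow(rates)), function(i)
    as.list(rates[i, intersect(keys, names(rates))]))
  names(entries) <- rates$gene_id
  if (nrow(rates) == 1) entries <- entries[[1]]
  if (grepl("\\.json$", path)) {
    rlang::check_installed("jsonlite", "to write JSON configs")
    jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(entries, path, precision = 15)
  }
  invisible(path)
}

#' @rdname rates_to_config
#' @export
rates_from_config <- function(path) {
  if (grepl("\\.json$", path)) {
    rlang::check_installed("jsonlite", "to read JSON configs")
    cfg <- jsonlite::read_json(path)
  } else {
    cfg <- yaml::read_yaml(path)
  }
  flat <- !is.null(names(cfg)) && any(rate_cols %in% names(cfg))
  if (flat) cfg <- list(gene_1 = cfg)
  rows <- purrr::imap(cfg, function(entry, id) {
    args <- entry[intersect(names(entry),
                            c(rate_cols, "S"))]
    do.call(rate_set, c(args, list(gene_id = id)))
  })
  dplyr::bind_rows(rows)
}

#' Write a time course (or any tidy table) as TSV
#'
#' @param x A tibble (e.g. a trajectory from
#'   [run_perturbation_course()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tidy_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read a gene x sample count table from TSV
#'
#' Expects a `gene_id` column plus one numeric column per sample.
#'
#' @param path TSV path.
#' @return A count-table tibble.
#' @export
read_counts_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"gene_id" %in% names(out)) {
    stop("count TSV must have a gene_id column", call. = FALSE)
  }
  out
}

#' Read a deamination site table from TSV
#'
#' Expects columns `site_id`, `gene_id`, `coverage`, `score`, `in_drach`.
#'
#' @param path TSV path.
#' @return A site-table tibble.
#' @export
read_sites_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("gene_id", "coverage", "score", "in_drach")
  if (!all(need %in% names(out))) {
    stop("site TSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out
}
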