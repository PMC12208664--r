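# Count tables are wide tibbles: a `gene_id` column plus one numeric
# column per sample. IP/input (and nuclear/cytoplasmic) tables are paired
# by sample column name.

count_samples <- function(counts) {
  setdiff(names(counts), "gene_id")
}

count_matrix <- function(counts) {
  m <- as.matrix(counts[count_samples(counts)])
  rownames(m) <- counts$gene_id
  if (any(m < 0) || any(!is.finite(m))) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  m
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values factors (log-ratio trim 0.3, abundance trim
#' 0.05, doubly trimmed weighted mean of gene-wise log ratios against a
#' reference sample), computed with [edgeR::calcNormFactors()]. Factors
#' multiply library sizes and have geometric mean 1 across samples.
#'
#' @param counts A count table (`gene_id` plus one column per sample).
#' @param reference Optional reference sample name; default lets the
#'   procedure pick the library whose upper quartile is closest to the
#'   mean.
#' @return A tibble: `sample`, `lib_size`, `norm_factor`,
#'   `effective_lib_size`.
#' @export
tmm_factors <- function(counts, reference = NULL) {
  m <- count_matrix(counts)
  if (ncol(m) < 2) stop("need at least 2 samples", call. = FALSE)
  ref <- if (is.null(reference)) NULL else match(reference, colnames(m))
  nf <- edgeR::calcNormFactors(m, method = "TMM", refColumn = ref)
  tibble::tibble(
    sample = colnames(m),
    lib_size = colSums(m),
    norm_factor = unname(nf),
    effective_lib_size = colSums(m) * unname(nf)
  )
}

sample_scales <- function(counts,
                          normalization = c("tmm", "library_size",
                                            "none")) {
  normalization <- match.arg(normalization)
  m <- count_matrix(counts)
  if (normalization == "none") {
    return(stats::setNames(rep(1, ncol(m)), colnames(m)))
  }
  lib <- colSums(m)
  if (normalization == "tmm" && ncol(m) >= 2) {
    lib <- lib * edgeR::calcNormFactors(m, method = "TMM")
  }
  lib
}

#' Gene-level m6A index from IP and input counts (m6A-GI)
#'
#' For each gene and paired sample, the m6A gene index is the gene's
#' depth-normalized IP abundance divided by its depth-normalized input
#' abundance — local IP enrichment over input, aggregated at the gene
#' level. Library scales are TMM-adjusted library sizes by default
#' (computed separately within the IP and the input fraction), or plain
#' library sizes; `"none"` skips depth normalization for counts that are
#' already on a common scale, as in a pooled multiplexed IP where
#' per-sample IP yield is preserved and the raw IP/input ratio estimates
#' the absolute methylated fraction.
#'
#' Genes with fewer than `min_input` input reads in a sample are reported
#' as `NA` in that sample: the index is a ratio and is unstable on weakly
#' covered genes.
#'
#' @param ip,input Count tables with identical `gene_id` sets and sample
#'   columns (samples are paired by name).
#' @param normalization `"tmm"`, `"library_size"`, or `"none"`.
#' @param min_input Minimum input count for a gene to receive an index.
#' @return A tibble: `gene_id` plus one GI column per sample.
#' @examples
#' ip <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(200, 800))
#' inp <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(100, 900))
#' m6a_gene_index(ip, inp, normalization = "library_size", min_input = 0)
#' @export
m6a_gene_index <- function(ip, input,
                           normalization = c("tmm", "library_size",
                                             "none"),
                           min_input = 20) {
  normalization <- match.arg(normalization)
  samples <- count_samples(ip)
  if (!identical(sort(samples), sort(count_samples(input)))) {
    stop("IP and input tables must share the same sample columns",
         call. = FALSE)
  }
  input <- input[match(ip$gene_id, input$gene_id), ]
  if (any(is.na(input$gene_id))) {
    stop("IP and input tables must share the same genes", call. = FALSE)
  }
  ip_m <- count_matrix(ip)[, samples, drop = FALSE]
  in_m <- count_matrix(input)[, samples, drop = FALSE]
  ip_scale <- sample_scales(ip, normalization)[samples]
  in_scale <- sample_scales(input, normalization)[samples]

  gi <- sweep(ip_m, 2, ip_scale, "/") / sweep(in_m, 2, in_scale, "/")
  gi[in_m < pmax(min_input, 1)] <- NA_real_
  out <- tibble::as_tibble(gi)
  tibble::add_column(out, gene_id = ip$gene_id, .before = 1)
}

#' Sample-level m6A index (m6A-SI)
#'
#' The expression-weighted mean of a sample's gene indices, with weights
#' proportional to the gene's input abundance in that sample: a single
#' scalar summarizing overall methylation of a sample.
#'
#' Under per-sample depth normalization this mean is identically 1 (the
#' weights cancel the scales), so between-sample comparisons require
#' yield-preserving counts and `normalization = "none"`, mirroring the
#' pooled multiplexed IP design in which each sample's share of the IP
#' pool reflects its absolute methylation.
#'
#' @inheritParams m6a_gene_index
#' @return A tibble: `sample`, `si`, `n_genes`.
#' @export
m6a_sample_index <- function(ip, input,
                             normalization = c("tmm", "library_size",
                                               "none"),
                             min_input = 20) {
  gi <- m6a_gene_index(ip, input, normalization, min_input)
  samples <- count_samples(gi)
  input <- input[match(gi$gene_id, input$gene_id), ]
  purrr::map_dfr(samples, function(s) {
    g <- gi[[s]]
    w <- input[[s]]
    keep <- !is.na(g) & w > 0
    tibble::tibble(
      sample = s,
      si = stats::weighted.mean(g[keep], w[keep]),
      n_genes = sum(keep)
    )
  })
}

#' Gene-level m6A index from deamination (GLORI) site scores
#'
#' A site's GLORI score is the fraction of unconverted adenosines at that
#' site (converted reads report unmethylated A). Per gene, the scores of
#' all eligible sites — sites inside a DRACH motif with coverage of at
#' least `min_coverage` and a score strictly greater than `min_score` —
#' are summed and normalized by the gene's total adenosine count.
#'
#' @param sites A site table: `gene_id`, `coverage`, `score`, `in_drach`
#'   (and optionally `site_id`).
#' @param adenosine_counts A tibble `gene_id`, `adenosine_count`; genes
#'   with a zero or missing count get `NA`.
#' @param min_coverage Minimum site coverage (inclusive).
#' @param min_score Minimum site score (exclusive: a score equal to the
#'   threshold is dropped).
#' @return A tibble: `gene_id`, `n_sites` (passing), `glori_gi`.
#' @examples
#' sites <- tibble::tibble(
#'   gene_id = "g1", coverage = c(25, 30, 19, 50),
#'   score = c(0.5, 0.3, 0.9, 0.05), in_drach = TRUE
#' )
#' ad <- tibble::tibble(gene_id = "g1", adenosine_count = 100)
#' glori_gene_index(sites, ad)$glori_gi  # (0.5 + 0.3) / 100 = 0.008
#' @export
glori_gene_index <- function(sites, adenosine_counts,
                             min_coverage = 20, min_score = 0.1) {
  stopifnot(all(c("gene_id", "coverage", "score", "in_drach") %in%
                  names(sites)))
  if (any(sites$score < 0 | sites$score > 1, na.rm = TRUE)) {
    stop("site scores must lie in [0, 1]", call. = FALSE)
  }
  passing <- sites %>%
    dplyr::filter(.data$in_drach,
                  .data$coverage >= min_coverage,
                  .data$score > min_score) %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(n_sites = dplyr::n(),
                     score_sum = sum(.data$score), .groups = "drop")
  adenosine_counts %>%
    dplyr::left_join(passing, by = "gene_id") %>%
    dplyr::mutate(
      n_sites = dplyr::coalesce(.data$n_sites, 0L),
      score_sum = dplyr::coalesce(.data$score_sum, 0),
      glori_gi = dplyr::if_else(.data$adenosine_count > 0,
                                .data$score_sum / .data$adenosine_count,
                                NA_real_)
    ) %>%
    dplyr::select("gene_id", "n_sites", "glori_gi")
}

#' Nuclear:cytoplasmic log2 fold-change per gene
#'
#' Counts are normalized within each fraction (TMM-adjusted library sizes
#' by default, across the samples of that fraction), rescaled to the mean
#' effective library size so a pseudocount of one read stays on the count
#' scale, and contrasted per paired sample:
#' `lfc = log2(nuc_norm + c) - log2(cyt_norm + c)`.
#'
#' @param nuc,cyt Count tables for the nuclear and cytoplasmic fractions;
#'   samples paired by column name.
#' @param normalization `"tmm"` or `"library_size"`.
#' @param pseudocount Pseudocount `c` on the normalized count scale.
#' @return A tibble: `gene_id` plus one `lfc` column per paired sample.
#' @export
nuc_cyt_lfc <- function(nuc, cyt, normalization = c("tmm", "library_size"),
                        pseudocount = 1) {
  normalization <- match.arg(normalization)
  samples <- count_samples(nuc)
  if (!identical(sort(samples), sort(count_samples(cyt)))) {
    stop("nuclear and cytoplasmic tables must share sample columns",
         call. = FALSE)
  }
  cyt <- cyt[match(nuc$gene_id, cyt$gene_id), ]
  if (any(is.na(cyt$gene_id))) {
    stop("fractions must share the same genes", call. = FALSE)
  }
  norm_counts <- function(tab) {
    m <- count_matrix(tab)[, samples, drop = FALSE]
    scale <- sample_scales(tab, normalization)[samples]
    sweep(m, 2, scale / mean(scale), "/")
  }
  lfc <- log2(norm_counts(nuc) + pseudocount) -
    log2(norm_counts(cyt) + pseudocount)
  out <- tibble::as_tibble(lfc)
  tibble::add_column(out, gene_id = nuc$gene_id, .before = 1)
}

#' PC1 decomposition of a gene-index matrix
#'
#' Principal component analysis of a gene x sample index matrix after
#' log2 transformation and per-gene centering/scaling, with genes as
#' observations. Genes must have an index in every sample (rows with any
#' missing value are dropped); constant genes cannot be scaled and are
#' dropped with a warning. The per-gene PC1 score ranks genes by whether
#' their index rises (positive) or falls (negative) along the sample
#' series: the sign is fixed so that the per-sample PC1 weight profile
#' correlates positively with `sample_order`.
#'
#' @param gi A gene-index table (`gene_id` plus one column per sample),
#'   e.g. from [m6a_gene_index()].
#' @param sample_order Samples in series order (default: column order).
#' @return An object of class `m6a_pca`: `genes` (tibble `gene_id`,
#'   `loading`, unit-norm over genes), `samples` (tibble `sample`,
#'   `weight`), `var_explained` (fraction of variance on PC1). `tidy()`
#'   returns the gene table; `glance()` the variance summary.
#' @export
pc1_loadings <- function(gi, sample_order = NULL) {
  samples <- count_samples(gi)
  if (length(samples) < 3) stop("need at least 3 samples", call. = FALSE)
  if (is.null(sample_order)) sample_order <- samples
  if (!setequal(sample_order, samples)) {
    stop("sample_order must name exactly the sample columns",
         call. = FALSE)
  }
  m <- as.matrix(gi[samples])
  rownames(m) <- gi$gene_id
  keep <- stats::complete.cases(m) & apply(m > 0, 1, all)
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 2) stop("fewer than 2 complete genes", call. = FALSE)
  lm2 <- log2(m)
  sds <- apply(lm2, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) dropped before scaling",
            call. = FALSE)
    lm2 <- lm2[sds > 0, , drop = FALSE]
  }
  if (nrow(lm2) < 2 || all(apply(lm2, 1, stats::sd) == 0)) {
    stop("no variance left after filtering; PC1 undefined", call. = FALSE)
  }
  z <- t(scale(t(lm2)))  # per-gene center and scale
  pca <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  scores <- pca$x[, 1]
  weights <- pca$rotation[, 1]
  ord <- match(samples, sample_order)
  flip <- stats::cor(weights, ord)
  if (is.finite(flip) && flip < 0) {
    scores <- -scores
    weights <- -weights
  }
  scores <- scores / sqrt(sum(scores^2))
  structure(list(
    genes = tibble::tibble(gene_id = rownames(z), loading = unname(scores)),
    samples = tibble::tibble(sample = samples, weight = unname(weights)),
    var_explained = unname(pca$sdev[1]^2 / sum(pca$sdev^2))
  ), class = "m6a_pca")
}

#' @export
print.m6a_pca <- function(x, ...) {
  cat("<m6a_pca> ", nrow(x$genes), " genes, ", nrow(x$samples),
      " samples; PC1 explains ",
      sprintf("%.1f%%", 100 * x$var_explained), " of variance\n", sep = "")
  invisible(x)
}

#' @rdname pc1_loadings
#' @param x An `m6a_pca` object.
#' @param ... Unused.
#' @export
tidy.m6a_pca <- function(x, ...) x$genes

#' @rdname pc1_loadings
#' @export
glance.m6a_pca <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$genes), n_samples = nrow(x$samples),
                 var_explained = x$var_explained)
}
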