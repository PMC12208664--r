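make_counts <- function(gene_id, ...) {
  tibble::tibble(gene_id = gene_id, ...)
}

test_that("gene index is normalized IP/input enrichment", {
  ip <- make_counts(c("g1", "g2"), s1 = c(200, 800))
  input <- make_counts(c("g1", "g2"), s1 = c(100, 900))
  gi <- m6a_gene_index(ip, input, normalization = "library_size",
                       min_input = 0)
  expect_equal(gi$s1, c(2.0, 8 / 9))  # (ip/lib) / (input/lib) per gene

  # proportional IP and input: GI = 1 everywhere
  ip2 <- make_counts(paste0("g", 1:5), a = c(10, 20, 30, 40, 100) * 3,
                     b = c(5, 10, 15, 20, 50))
  in2 <- make_counts(paste0("g", 1:5), a = c(10, 20, 30, 40, 100),
                     b = c(10, 20, 30, 40, 100))
  gi2 <- m6a_gene_index(ip2, in2, normalization = "library_size",
                        min_input = 0)
  expect_equal(unname(as.matrix(gi2[c("a", "b")])),
               matrix(1, 5, 2), tolerance = 1e-12)

  # depth invariance: scaling a whole sample leaves GI unchanged
  ip3 <- ip2
  ip3$a <- ip3$a * 7
  gi3 <- m6a_gene_index(ip3, in2, normalization = "library_size",
                        min_input = 0)
  expect_equal(gi3$a, gi2$a, tolerance = 1e-12)

  # low-input genes are flagged missing
  gi4 <- m6a_gene_index(ip2, in2, normalization = "library_size",
                        min_input = 20)
  expect_true(is.na(gi4$a[1]))
  expect_false(is.na(gi4$a[2]))
  expect_error(m6a_gene_index(ip, make_counts("g1", s2 = 1)),
               "sample columns")
})

test_that("sample index is the expression-weighted mean of gene indices", {
  ip <- make_counts(paste0("g", 1:4), s1 = c(100, 200, 300, 400))
  input <- make_counts(paste0("g", 1:4), s1 = c(100, 200, 300, 400))
  si <- m6a_sample_index(ip, input, normalization = "library_size",
                         min_input = 0)
  expect_equal(si$si, 1)
  # a non-trivial table: SI equals the input-weighted mean of the GIs,
  # which is linear in the gene indices
  ip2 <- make_counts(paste0("g", 1:4), s1 = c(400, 300, 200, 100))
  gi2 <- m6a_gene_index(ip2, input, normalization = "library_size",
                        min_input = 0)
  si2 <- m6a_sample_index(ip2, input, normalization = "library_size",
                          min_input = 0)
  expect_equal(si2$si, stats::weighted.mean(gi2$s1, input$s1))
  expect_equal(si2$n_genes, 4L)
})

test_that("deamination gene index applies the printed filters", {
  sites <- tibble::tibble(
    gene_id = "g1",
    coverage = c(25, 30, 19, 50),
    score = c(0.5, 0.3, 0.9, 0.05),
    in_drach = TRUE
  )
  ad <- tibble::tibble(gene_id = "g1", adenosine_count = 100)
  gi <- glori_gene_index(sites, ad)
  expect_equal(gi$glori_gi, 0.008)   # (0.5 + 0.3) / 100
  expect_equal(gi$n_sites, 2L)

  # the score threshold is strict: exactly 0.1 is excluded
  s2 <- tibble::tibble(gene_id = "g1", coverage = 100,
                       score = 0.1, in_drach = TRUE)
  expect_equal(glori_gene_index(s2, ad)$glori_gi, 0)

  # non-DRACH sites never contribute
  s3 <- dplyr::mutate(sites, in_drach = c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(glori_gene_index(s3, ad)$glori_gi, 0.005)

  # no passing sites -> 0; zero adenosines -> undefined
  none <- tibble::tibble(gene_id = "g2", coverage = 5, score = 0.5,
                         in_drach = TRUE)
  ad2 <- tibble::tibble(gene_id = "g2", adenosine_count = c(0))
  expect_equal(glori_gene_index(none,
    tibble::tibble(gene_id = "g2", adenosine_count = 50))$glori_gi, 0)
  expect_true(is.na(glori_gene_index(none, ad2)$glori_gi))
  expect_error(glori_gene_index(dplyr::mutate(sites, score = 2), ad),
               "\\[0, 1\\]")
})

# independent trimmed-mean-of-M-values computation used as an oracle
tmm_oracle <- function(mat, ref_col) {
  lib <- colSums(mat)
  f <- vapply(seq_len(ncol(mat)), function(j) {
    x <- mat[, j]; r <- mat[, ref_col]
    keep <- x > 0 & r > 0
    x <- x[keep]; r <- r[keep]
    nx <- lib[j]; nr <- lib[ref_col]
    m <- log2((x / nx) / (r / nr))
    a <- 0.5 * log2((x / nx) * (r / nr))
    w <- (nx - x) / (nx * x) + (nr - r) / (nr * r)
    if (max(abs(m)) < 1e-6) return(1)
    n <- length(m)
    lo_m <- floor(n * 0.3) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * 0.05) + 1; hi_a <- n + 1 - lo_a
    keep2 <- rank(m) >= lo_m & rank(m) <= hi_m &
      rank(a) >= lo_a & rank(a) <= hi_a
    2^(sum(m[keep2] / w[keep2]) / sum(1 / w[keep2]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

test_that("TMM factors match an independent implementation", {
  withr::with_seed(71, {
    base <- stats::rpois(200, exp(stats::rnorm(200, 5, 1)))
    m <- cbind(s1 = base + stats::rpois(200, 5),
               s2 = 2 * base + stats::rpois(200, 5),
               s3 = base + stats::rpois(200, 5))
  })
  # 5% of genes strongly up in s3 only
  m[1:10, "s3"] <- m[1:10, "s3"] * 10
  counts <- tibble::as_tibble(m)
  counts <- tibble::add_column(counts, gene_id = paste0("g", 1:200),
                               .before = 1)
  got <- tmm_factors(counts, reference = "s1")
  want <- tmm_oracle(m, ref_col = 1)
  expect_equal(got$norm_factor, unname(want), tolerance = 1e-10)
  expect_equal(exp(mean(log(got$norm_factor))), 1, tolerance = 1e-12)

  # identical columns: unit factors
  same <- make_counts(paste0("g", 1:50), a = 1:50 + 10L, b = 1:50 + 10L)
  expect_equal(tmm_factors(same)$norm_factor, c(1, 1))

  # after normalization, unchanged genes agree across the outlier sample
  eff <- got$effective_lib_size
  norm <- sweep(m, 2, eff / mean(eff), "/")
  ratio <- norm[11:200, "s3"] / norm[11:200, "s1"]
  expect_equal(stats::median(ratio), 1, tolerance = 0.02)
})

test_that("nuclear:cytoplasmic log fold-change behaves definitionally", {
  nuc <- make_counts(c("g1", "g2"), s1 = c(200, 800))
  cyt <- make_counts(c("g1", "g2"), s1 = c(50, 950))
  lfc <- nuc_cyt_lfc(nuc, cyt, normalization = "library_size",
                     pseudocount = 0)
  expect_equal(lfc$s1[1], 2.0)  # log2(200/50) at equal scales
  eq <- nuc_cyt_lfc(nuc, nuc, normalization = "library_size",
                    pseudocount = 0)
  expect_equal(eq$s1, c(0, 0))
  expect_error(nuc_cyt_lfc(nuc, make_counts("g1", other = 1)),
               "sample columns")
})

test_that("PC1 separates rising from falling genes and fixes its sign", {
  trend <- seq(-1, 1, length.out = 5)
  up <- t(replicate(10, 2^(5 + trend)))
  down <- t(replicate(10, 2^(5 - trend)))
  m <- rbind(up, down)
  gi <- tibble::as_tibble(m, .name_repair = ~ paste0("t", 1:5))
  gi <- tibble::add_column(gi, gene_id = paste0("g", 1:20), .before = 1)
  pca <- pc1_loadings(gi)
  expect_gt(pca$var_explained, 0.999)
  expect_true(all(pca$genes$loading[1:10] > 0))
  expect_true(all(pca$genes$loading[11:20] < 0))
  expect_equal(sum(pca$genes$loading^2), 1, tolerance = 1e-12)
  # sample weight profile rises with declared sample order
  expect_gt(stats::cor(pca$samples$weight, 1:5), 0)
  # reversing the declared order flips every sign
  rev_pca <- pc1_loadings(gi, sample_order = paste0("t", 5:1))
  expect_equal(rev_pca$genes$loading, -pca$genes$loading)
  # permuting genes permutes loadings identically
  perm <- c(20:1)
  p2 <- pc1_loadings(gi[perm, ])
  expect_equal(p2$genes$loading[match(gi$gene_id, p2$genes$gene_id)],
               pca$genes$loading)
  expect_equal(tidy(pca), pca$genes)
  expect_equal(glance(pca)$n_samples, 5L)

  # constant matrix: no principal direction
  const <- gi
  const[2:6] <- 1
  expect_error(suppressWarnings(pc1_loadings(const)), "variance")
  expect_error(pc1_loadings(gi[, 1:3]), "at least 3")
})
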