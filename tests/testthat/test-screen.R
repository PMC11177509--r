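make_expr <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples,
              dimnames = list(c("MYC", sprintf("G%03d", seq_len(n_genes - 1))),
                              sprintf("S%03d", seq_len(n_samples))))
  m
}

test_that("select_pmn_wt returns the complement of the hit set", {
  hits <- data.frame(sample_id = c("S1", "S2", "S3"),
                     pmn_hit = c(TRUE, FALSE, TRUE))
  expect_equal(select_pmn_wt(hits), "S2")
  hits$pmn_hit <- TRUE
  expect_length(select_pmn_wt(hits), 0)
  expect_error(select_pmn_wt(hits[0, ]), "empty")
})

test_that("correlation filter: perfect copy passes, constant gene is flagged", {
  m <- make_expr(4, 20, seed = 31)
  m["G001", ] <- m["MYC", ]          # r = 1
  m["G002", ] <- 5                   # zero variance
  res <- suppressMessages(correlation_filter(m, colnames(m)))
  expect_equal(res$pearson_r[res$gene == "G001"], 1)
  expect_true(res$passes_a[res$gene == "G001"])
  expect_equal(res$flag[res$gene == "G002"], "zero_variance")
  expect_false(res$passes_a[res$gene == "G002"])
})

test_that("correlation filter matches the formula-level recomputation to 1e-12", {
  m <- make_expr(11, 20, seed = 32)
  res <- correlation_filter(m, colnames(m))
  y <- m["MYC", ]
  n <- ncol(m)
  for (i in seq_len(nrow(res))) {
    x <- m[res$gene[i], ]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), n - 2)
    expect_equal(res$pearson_r[i], r, tolerance = 1e-12)
    expect_equal(res$pearson_p[i], p, tolerance = 1e-12)
    expect_equal(res$passes_a[i], abs(r) > 0.2 && p < 0.05)
  }
})

test_that("filter (a) is invariant to sample reordering", {
  m <- make_expr(6, 15, seed = 33)
  r1 <- correlation_filter(m, colnames(m))
  r2 <- correlation_filter(m[, rev(colnames(m))], colnames(m))
  expect_equal(r1$pearson_r, r2$pearson_r, tolerance = 1e-12)
})

test_that("excluded genes never appear in screen output", {
  m <- make_expr(4, 15, seed = 34)
  rownames(m)[2] <- "TP53"
  rownames(m)[3] <- "MXI1"
  res <- correlation_filter(m, colnames(m))
  expect_false(any(c("TP53", "MXI1", "MYC") %in% res$gene))
})

test_that("alteration filter: small-sample p equals exact enumeration", {
  set.seed(35)
  for (rep in 1:25) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    x <- stats::rnorm(nx); y <- stats::rnorm(ny)
    p_pkg <- astromyc:::.wilcoxon_greater(x, y)
    expect_equal(p_pkg, oracle_wilcoxon_greater(x, y), tolerance = 1e-12)
  }
})

test_that("alteration filter applies the frequency window and direction", {
  # 20 WT samples; gene GA altered (loss) in 6 with MYC shifted up 2 SD
  set.seed(36)
  samples <- sprintf("S%03d", 1:20)
  altered <- samples[1:6]
  myc <- stats::rnorm(20)
  myc[1:6] <- myc[1:6] + 2
  m <- matrix(stats::rnorm(40), 2, 20,
              dimnames = list(c("MYC", "GA"), samples))
  m["MYC", ] <- myc
  calls <- calls_from(rep(samples, 2), rep(c("GA", "GB"), each = 20),
                      c(ifelse(samples %in% altered, -0.8, 0), rep(0, 20)))
  no_var <- data.frame(sample_id = character(0), gene = character(0),
                       variant_class = character(0))
  res <- alteration_filter(calls, no_var, m, samples)
  ga <- res[res$gene == "GA", ]
  gb <- res[res$gene == "GB", ]
  expect_equal(ga$n_altered, 6)
  expect_equal(ga$altered_fraction, 0.3)
  expect_true(ga$passes_b)
  expect_true(is.na(gb$wilcoxon_p))   # 0 altered -> outside window
  expect_false(gb$passes_b)
})

test_that("identical altered/unaltered distributions do not pass filter (b)", {
  samples <- sprintf("S%03d", 1:20)
  vals <- rep(seq(1, 10), 2)
  m <- matrix(vals, 1, 20, dimnames = list("MYC", samples))
  calls <- calls_from(samples, rep("GA", 20),
                      rep(c(-0.8, 0), 10))   # altered = odd indices
  no_var <- data.frame(sample_id = character(0), gene = character(0),
                       variant_class = character(0))
  res <- alteration_filter(calls, no_var, m, samples)
  expect_gte(res$wilcoxon_p, 0.5)
  expect_false(res$passes_b)
})

test_that("combine_screen requires both filters and sorts candidates", {
  a <- data.frame(gene = c("G1", "G2", "G3"),
                  pearson_r = c(0.5, -0.6, 0.9),
                  pearson_p = c(0.01, 0.02, 0.001),
                  passes_a = c(TRUE, TRUE, FALSE), flag = "ok")
  b <- data.frame(gene = c("G1", "G2", "G3"),
                  wilcoxon_p = c(0.04, 0.04, 0.001), n_altered = 5,
                  altered_fraction = 0.25,
                  passes_b = c(TRUE, TRUE, TRUE))
  out <- combine_screen(a, b)
  # G3 fails (a); G1/G2 tie on p, broken by |r| descending
  expect_equal(out$gene, c("G2", "G1"))

  b$passes_b <- FALSE
  expect_equal(nrow(combine_screen(a, b)), 0)
  a$passes_a <- c(TRUE, FALSE, FALSE)
  b$passes_b <- c(FALSE, TRUE, FALSE)
  expect_equal(nrow(combine_screen(a, b)), 0)
})

test_that("null cohort yields few candidates (alpha^2-level false positives)", {
  set.seed(37)
  samples <- sprintf("S%03d", 1:40)
  n_genes <- 30
  fp <- numeric(20)
  for (rep in 1:20) {
    m <- matrix(stats::rnorm((n_genes + 1) * 40), n_genes + 1, 40,
                dimnames = list(c("MYC", sprintf("G%03d", 1:n_genes)),
                                samples))
    # every gene altered in a random 30% of samples, independent of MYC
    calls <- do.call(rbind, lapply(sprintf("G%03d", 1:n_genes), function(g) {
      calls_from(samples, rep(g, 40),
                 ifelse(stats::runif(40) < 0.3, -0.8, 0))
    }))
    no_var <- data.frame(sample_id = character(0), gene = character(0),
                         variant_class = character(0))
    a <- correlation_filter(m, samples)
    b <- alteration_filter(calls, no_var, m, samples)
    fp[rep] <- nrow(combine_screen(a, b)) / n_genes
  }
  # independent filters: expected candidate rate ~ alpha * alpha/2 << 2%
  expect_lt(mean(fp), 0.02)
})
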