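mcr_region <- data.frame(chrom = "chr19", start = 55005440, end = 56958964,
                         stringsAsFactors = FALSE)

test_that("cancer-cell selection is identity/subset and errors on typos", {
  set.seed(601)
  cn <- matrix(rnorm(9 * 100, 0, 0.05), 9, 100)
  types <- rep(c("Cancer stem cells", "Macrophages"), c(55, 45))
  x <- small_cell_cn(cn, types = types, counts = rpois(100, 3))
  expect_equal(ncol(select_cancer_cells(x)$cn), 55)

  all_cancer <- small_cell_cn(cn, counts = rpois(100, 3))
  expect_equal(select_cancer_cells(all_cancer)$cn, all_cancer$cn)

  expect_error(select_cancer_cells(x, "Cancer stemcells"),
               "available labels.*Macrophages")
  only_mac <- small_cell_cn(cn, types = rep("Macrophages", 100),
                            counts = rpois(100, 3))
  expect_error(select_cancer_cells(only_mac), "not present")
})

test_that("cell MCR-status classification applies the threshold to the region mean", {
  cn <- matrix(c(rep(-0.2, 9), rep(0, 9)), 9, 2)
  x <- small_cell_cn(cn, counts = c(5L, 2L))
  st <- classify_cell_mcr_status(x, mcr_region)
  expect_equal(as.character(st), c("WITH_LOSS", "WITHOUT_LOSS"))
  # regions outside the MCR are ignored; error if none overlap
  far <- small_cell_cn(cn, counts = c(5L, 2L),
                       regions = tile_regions("chr8", 1e6, 2e6, 9))
  expect_error(classify_cell_mcr_status(far, mcr_region), "no region")
})

test_that("planted cell status is recovered accurately and sensitivity sweep runs", {
  cfg <- sim_config(n_cells = 2000, seed = 7)
  sc <- simulate_cells(cfg, tile_regions("chr19", 55005440, 56958964, 9))
  cancer <- select_cancer_cells(sc$cells)
  st <- classify_cell_mcr_status(cancer, mcr_region)
  truth <- sc$truth$mcr_loss[match(cancer$cell_meta$cell_id,
                                   sc$truth$cell_id)]
  acc <- mean((st == "WITH_LOSS") == truth)
  expect_gte(acc, 0.95)

  sw <- cell_status_sensitivity(cancer, mcr_region,
                                thresholds = c(-0.15, -0.05, -0.01))
  expect_equal(nrow(sw), 3)
  expect_true(all(diff(sw$n_with_loss) >= 0))  # monotone in threshold
})

test_that("degenerate CN (all zero) reduces to intercept-only with flags", {
  set.seed(602)
  y <- rpois(60, 5)
  cn <- matrix(0, 1, 60)
  x <- small_cell_cn(cn, counts = y,
                     regions = mcr_region)
  st <- factor(rep(c("WITH_LOSS", "WITHOUT_LOSS"), 30),
               levels = c("WITH_LOSS", "WITHOUT_LOSS"))
  f <- fit_poisson_interaction(x, st, 1)
  expect_equal(f$beta0, log(mean(y)), tolerance = 1e-10)
  expect_true(is.na(f$beta1) && is.na(f$beta2))
  expect_true(any(grepl("inestimable", f$flags)))
})

test_that("minimum group size is enforced", {
  set.seed(603)
  cn <- matrix(rnorm(30), 1, 30)
  x <- small_cell_cn(cn, counts = rpois(30, 3), regions = mcr_region)
  st <- factor(rep(c("WITH_LOSS", "WITHOUT_LOSS"), c(5, 25)),
               levels = c("WITH_LOSS", "WITHOUT_LOSS"))
  expect_error(fit_poisson_interaction(x, st, 1), "at least 10 cells")
})

test_that("Poisson fit matches direct likelihood maximization on tiny data", {
  set.seed(604)
  for (rep in 1:25) {
    n <- 30
    wl <- rep(c(TRUE, FALSE), 15)
    x <- rnorm(n, ifelse(wl, -0.2, 0), 0.3)  # spread -> curvature in both slopes
    y <- rpois(n, exp(1 - 2 * x * wl + 0 * x))
    cc <- small_cell_cn(matrix(x, 1), counts = y, regions = mcr_region)
    st <- factor(ifelse(wl, "WITH_LOSS", "WITHOUT_LOSS"),
                 levels = c("WITH_LOSS", "WITHOUT_LOSS"))
    f <- fit_poisson_interaction(cc, st, 1)
    orc <- oracle_poisson_fit(y, x, wl)
    expect_true(f$converged)
    expect_equal(c(f$beta0, f$beta1, f$beta2), orc$beta, tolerance = 1e-6)
    expect_equal(f$loglik, orc$loglik, tolerance = 1e-6)
    # log-likelihood is non-decreasing across IRLS iterations
    expect_true(all(diff(f$loglik_trace) > -1e-8))
    # CIs contain their point estimates
    expect_true(f$ci95_beta1[1] <= f$beta1 && f$beta1 <= f$ci95_beta1[2])
  }
})

test_that("Poisson fit is exactly scale-consistent in CN", {
  set.seed(605)
  n <- 200
  wl <- rep(c(TRUE, FALSE), n / 2)
  x <- rnorm(n, ifelse(wl, -0.2, 0), 0.05)
  y <- rpois(n, exp(1 - 2 * x * wl))
  st <- factor(ifelse(wl, "WITH_LOSS", "WITHOUT_LOSS"),
               levels = c("WITH_LOSS", "WITHOUT_LOSS"))
  f1 <- fit_poisson_interaction(small_cell_cn(matrix(x, 1), counts = y,
                                              regions = mcr_region), st, 1)
  f2 <- fit_poisson_interaction(small_cell_cn(matrix(3 * x, 1), counts = y,
                                              regions = mcr_region), st, 1)
  expect_equal(f2$beta1, f1$beta1 / 3, tolerance = 1e-8)
  expect_equal(f2$beta2, f1$beta2 / 3, tolerance = 1e-8)
  expect_equal(f2$beta0, f1$beta0, tolerance = 1e-8)
})

test_that("one fit per region: 9 planted regions give 9 results", {
  cfg <- sim_config(n_cells = 600, noncancer_fraction = 0, seed = 9)
  sc <- simulate_cells(cfg, tile_regions("chr19", 55005440, 56958964, 9))
  st <- classify_cell_mcr_status(sc$cells, mcr_region)
  fits <- fit_poisson_all_regions(sc$cells, st)
  expect_length(fits, 9)
  expect_true(all(vapply(fits, function(f) f$converged, logical(1))))
})

test_that("all-non-cancer input refuses the fit path", {
  cfg <- sim_config(n_cells = 100, noncancer_fraction = 1, seed = 10)
  sc <- simulate_cells(cfg, mcr_region)
  expect_error(select_cancer_cells(sc$cells), "not present|no cancer cells")
})

test_that("aggregate MCR expression vs MYC behaves on constructed cases", {
  set.seed(606)
  n <- 50
  myc <- rpois(n, 10)
  # exact negative monotone transform -> Spearman -1
  expr <- rbind(A = -as.numeric(myc) + 0.001 * seq_len(n) * 0,
                B = -2 * as.numeric(myc))
  st <- factor(rep(c("WITH_LOSS", "WITHOUT_LOSS"), n / 2))
  r <- aggregate_mcr_expression_vs_myc(expr, myc, st, c("A", "B"))
  expect_equal(r$rho, -1)
  expect_equal(nrow(r$per_gene), 2)
  expect_equal(nrow(r$by_status), 2)

  # single gene: aggregate equals that gene
  r1 <- aggregate_mcr_expression_vs_myc(expr, myc, st, "A")
  expect_equal(unname(r1$aggregate), unname(expr["A", ]))
  expect_error(aggregate_mcr_expression_vs_myc(expr, myc, st, "NOPE"),
               "none of the MCR genes")

  # independent values -> |rho| small at n = 1000
  myc2 <- rpois(1000, 10)
  expr2 <- matrix(rnorm(1000), 1, dimnames = list("A", NULL))
  r2 <- aggregate_mcr_expression_vs_myc(expr2, myc2,
                                        factor(rep("WITHOUT_LOSS", 1000)),
                                        "A")
  expect_lt(abs(r2$rho), 0.1)
})
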