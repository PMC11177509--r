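# Single-cell validation: cancer-cell selection, per-cell MCR-loss
# classification, and the per-region Poisson interaction model of MYC
# counts on copy-number estimates.

#' Restrict a cell_cn object to cancer cells
#'
#' @param cn A [cell_cn()] object.
#' @param cancer_labels Cell-type labels to keep (default
#'   `"Cancer stem cells"`).
#' @return A [cell_cn()] restricted to those cells.
#' @export
select_cancer_cells <- function(cn, cancer_labels = "Cancer stem cells") {
  stopifnot(inherits(cn, "cell_cn"))
  available <- unique(cn$cell_meta$cell_type)
  missing <- setdiff(cancer_labels, available)
  if (length(missing)) {
    stop("label(s) not present: ", paste(missing, collapse = ", "),
         "; available labels: ", paste(available, collapse = ", "))
  }
  keep <- cn$cell_meta$cell_type %in% cancer_labels
  if (!any(keep)) stop("no cancer cells after filtering")
  subset_cells(cn, which(keep))
}

#' Classify cells by MCR-loss status
#'
#' A cell is `WITH_LOSS` iff the mean copy-number estimate across the
#' regions overlapping the MCR intervals is below `loss_threshold`
#' (strict). The threshold is deliberately exposed: how cells were
#' dichotomized is the least-specified step of the procedure, and the
#' default of -0.05 on CopyKat-like log-ratios should be sensitivity-checked
#' (see [cell_status_sensitivity()]).
#'
#' @param cn A [cell_cn()] object.
#' @param mcr_intervals `data.frame` with `chrom`, `start`, `end` (e.g.
#'   `find_mcr(...)$intervals`).
#' @param loss_threshold Log-ratio cutoff (default -0.05).
#' @return Factor per cell with levels `WITH_LOSS`, `WITHOUT_LOSS`.
#' @export
classify_cell_mcr_status <- function(cn, mcr_intervals,
                                     loss_threshold = -0.05) {
  stopifnot(inherits(cn, "cell_cn"))
  h <- .fo(.as_granges(cn$regions),
                                   .as_granges(mcr_intervals))
  rows <- unique(S4Vectors::queryHits(h))
  if (length(rows) == 0) stop("no region overlaps the MCR intervals")
  avg <- colMeans(cn$cn[rows, , drop = FALSE])
  factor(ifelse(avg < loss_threshold, "WITH_LOSS", "WITHOUT_LOSS"),
         levels = c("WITH_LOSS", "WITHOUT_LOSS"))
}

#' Sweep the cell-level loss threshold
#'
#' Reports, for each candidate threshold, how many cells are classified
#' `WITH_LOSS` — a cheap sensitivity analysis for the least-specified
#' parameter of the single-cell pipeline.
#'
#' @param cn A [cell_cn()] object.
#' @param mcr_intervals MCR intervals `data.frame`.
#' @param thresholds Numeric vector of thresholds.
#' @return `data.frame` with `threshold`, `n_with_loss`, `fraction`.
#' @export
cell_status_sensitivity <- function(cn, mcr_intervals,
                                    thresholds = seq(-0.2, 0, by = 0.025)) {
  res <- lapply(thresholds, function(th) {
    st <- classify_cell_mcr_status(cn, mcr_intervals, th)
    data.frame(threshold = th, n_with_loss = sum(st == "WITH_LOSS"),
               fraction = mean(st == "WITH_LOSS"))
  })
  do.call(rbind, res)
}

# Poisson log-likelihood for counts y and linear predictor eta.
.pois_loglik <- function(y, eta) {
  sum(y * eta - exp(eta) - lgamma(y + 1))
}

#' Fit the per-region Poisson interaction model
#'
#' Maximum-likelihood Poisson regression with log link of per-cell MYC
#' counts on the region's copy-number estimate, interacted with MCR-loss
#' status:
#' `E[count] = exp(b0 + b1 * CN * I(WITH_LOSS) + b2 * CN * I(WITHOUT_LOSS))`.
#' Fitting is by iteratively reweighted least squares to a relative
#' log-likelihood tolerance of 1e-8 (max 100 iterations); 95% Wald
#' confidence intervals come from the observed-information covariance. No
#' exposure/offset term is used. If the CN column for a status group is
#' identically zero (or collinear) the corresponding coefficient is
#' inestimable: it is returned as `NA` and flagged; with both slopes
#' inestimable the model reduces to the intercept-only fit
#' `b0 = log(mean(count))`.
#'
#' @param cn A [cell_cn()] object (typically cancer cells only).
#' @param status Per-cell factor from [classify_cell_mcr_status()].
#' @param region_index Row index of the region to fit.
#' @param min_cells_per_group Minimum cells per status group (default 10).
#' @return Object of class `poisson_fit`: list with `region`, `beta0`,
#'   `beta1`, `beta2`, `se`, `ci95_beta1`, `ci95_beta2`, `converged`,
#'   `n_cells`, `loglik`, `n_iter`, `flags`.
#' @export
fit_poisson_interaction <- function(cn, status, region_index,
                                    min_cells_per_group = 10) {
  stopifnot(inherits(cn, "cell_cn"))
  stopifnot(region_index >= 1, region_index <= nrow(cn$regions))
  y <- cn$cell_meta$myc_count
  x <- cn$cn[region_index, ]
  wl <- status == "WITH_LOSS"
  if (sum(wl) < min_cells_per_group || sum(!wl) < min_cells_per_group) {
    stop("need at least ", min_cells_per_group, " cells per status group; ",
         "got ", sum(wl), " WITH_LOSS / ", sum(!wl), " WITHOUT_LOSS")
  }
  flags <- character(0)
  if (all(y[wl] == 0) || all(y[!wl] == 0)) {
    flags <- c(flags, "all-zero counts in a status group (separation risk)")
  }
  X <- cbind(intercept = 1, b1 = x * wl, b2 = x * (!wl))
  estimable <- c(TRUE,
                 any(X[, 2] != 0) && stats::sd(X[, 2]) > 0,
                 any(X[, 3] != 0) && stats::sd(X[, 3]) > 0)
  if (!estimable[2]) flags <- c(flags, "beta1 inestimable (no CN variation)")
  if (!estimable[3]) flags <- c(flags, "beta2 inestimable (no CN variation)")
  Xe <- X[, estimable, drop = FALSE]
  if (qr(Xe)$rank < ncol(Xe)) {
    stop("design matrix is rank deficient beyond the flagged columns")
  }

  beta <- rep(0, ncol(Xe))
  beta[1] <- log(mean(y) + 1e-8)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  ll_trace <- numeric(0)
  repeat {
    iter <- iter + 1L
    eta <- as.numeric(Xe %*% beta)
    eta <- pmin(eta, 30)             # guard against overflow
    mu <- exp(eta)
    ll <- .pois_loglik(y, eta)
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll) && abs(ll - ll_old) / (abs(ll) + 0.1) < 1e-8) {
      converged <- TRUE
      break
    }
    if (iter > 100L) break
    ll_old <- ll
    z <- eta + (y - mu) / mu
    XtW <- t(Xe * mu)
    beta_new <- tryCatch(solve(XtW %*% Xe, XtW %*% z),
                         error = function(e) NULL)
    if (is.null(beta_new)) {
      flags <- c(flags, "IRLS normal equations singular")
      beta <- rep(NA_real_, ncol(Xe))
      break
    }
    beta_new <- as.numeric(beta_new)
    # step-halving keeps the log-likelihood non-decreasing
    for (h in 1:30) {
      ll_new <- .pois_loglik(y, pmin(as.numeric(Xe %*% beta_new), 30))
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      beta_new <- (beta + beta_new) / 2
    }
    beta <- beta_new
  }
  if (!converged) flags <- c(flags, "did not converge in 100 iterations")

  full <- rep(NA_real_, 3)
  se_full <- rep(NA_real_, 3)
  if (all(is.finite(beta))) {
    mu <- exp(pmin(as.numeric(Xe %*% beta), 30))
    info <- t(Xe * mu) %*% Xe
    covb <- tryCatch(solve(info), error = function(e) NULL)
    full[estimable] <- beta
    if (!is.null(covb)) se_full[estimable] <- sqrt(diag(covb))
    ll <- .pois_loglik(y, pmin(as.numeric(Xe %*% beta), 30))
  } else {
    ll <- NA_real_
  }
  zq <- stats::qnorm(0.975)
  ci <- function(i) c(full[i] - zq * se_full[i], full[i] + zq * se_full[i])
  structure(list(
    region = cn$regions[region_index, , drop = FALSE],
    beta0 = full[1], beta1 = full[2], beta2 = full[3],
    se = stats::setNames(se_full, c("beta0", "beta1", "beta2")),
    ci95_beta1 = ci(2), ci95_beta2 = ci(3),
    converged = converged, n_cells = length(y), loglik = ll,
    loglik_trace = ll_trace, n_iter = iter, flags = flags
  ), class = "poisson_fit")
}

#' @export
print.poisson_fit <- function(x, ...) {
  r <- x$region
  cat("Poisson interaction fit,", paste0(r$chrom, ":", r$start, "-", r$end),
      "(n =", x$n_cells, "cells)\n")
  cat(sprintf("  beta0 = %.4f  beta1 = %.4f [%.4f, %.4f]  beta2 = %.4f [%.4f, %.4f]\n",
              x$beta0, x$beta1, x$ci95_beta1[1], x$ci95_beta1[2],
              x$beta2, x$ci95_beta2[1], x$ci95_beta2[2]))
  cat("  converged:", x$converged, " loglik:", format(x$loglik, digits = 6),
      "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Fit the Poisson interaction model for every region
#' @inheritParams fit_poisson_interaction
#' @return List of `poisson_fit` objects, one per region of `cn`.
#' @export
fit_poisson_all_regions <- function(cn, status, min_cells_per_group = 10) {
  lapply(seq_len(nrow(cn$regions)), function(i) {
    fit_poisson_interaction(cn, status, i, min_cells_per_group)
  })
}

#' Aggregated MCR-gene expression versus MYC within cells
#'
#' Per cell, the aggregate is the mean log-normalized expression of the MCR
#' genes present in the input. Reports the Spearman correlation of the
#' aggregate with MYC counts, per-status medians, and per-gene Spearman
#' correlations.
#'
#' @param expr Genes x cells numeric matrix of log-normalized expression.
#' @param myc_counts Per-cell MYC counts (or expression).
#' @param status Per-cell status factor (`WITH_LOSS`/`WITHOUT_LOSS`).
#' @param mcr_genes Character vector of MCR gene symbols.
#' @return List with `rho`, `p_value`, `aggregate` (per-cell values),
#'   `by_status` (medians per status), `per_gene` (`data.frame` of per-gene
#'   correlations).
#' @export
aggregate_mcr_expression_vs_myc <- function(expr, myc_counts, status,
                                            mcr_genes) {
  present <- intersect(mcr_genes, rownames(expr))
  if (length(present) == 0) {
    stop("none of the MCR genes are present in the expression input")
  }
  agg <- colMeans(expr[present, , drop = FALSE])
  ct <- suppressWarnings(
    stats::cor.test(agg, myc_counts, method = "spearman", exact = FALSE)
  )
  by_status <- do.call(rbind, lapply(levels(factor(status)), function(s) {
    idx <- status == s
    data.frame(status = s, n = sum(idx),
               median_aggregate = stats::median(agg[idx]),
               median_myc = stats::median(myc_counts[idx]),
               stringsAsFactors = FALSE)
  }))
  per_gene <- data.frame(
    gene = present,
    rho = vapply(present, function(g) {
      suppressWarnings(stats::cor(expr[g, ], myc_counts,
                                  method = "spearman"))
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, aggregate = agg,
       by_status = by_status, per_gene = per_gene)
}
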