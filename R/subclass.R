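# Three-way subclassification (PMN_HIT / MCR_LOSS / WT) and the bulk-level
# association analyses run on it.

#' Assign the three tumour sub-classes
#'
#' `PMN_HIT` if the sample has any somatic PMN alteration; otherwise
#' `MCR_LOSS` if any LOSS-state segment (mean `< -threshold`) overlaps an
#' MCR interval by at least 1 bp; otherwise `WT`. The partition is
#' exhaustive and disjoint, with PMN-hit taking precedence.
#'
#' @param hits PMN-hit table from [pmn_hit_status()].
#' @param segments Segment `data.frame`.
#' @param mcr An `mcr_result` from [find_mcr()] (or any list with an
#'   `intervals` data.frame); must be non-empty.
#' @param threshold Positive log-ratio threshold (default 0.3).
#' @return `data.frame` with `sample_id` and `subclass` (factor with levels
#'   `PMN_HIT`, `MCR_LOSS`, `WT`).
#' @export
assign_subclass <- function(hits, segments, mcr, threshold = 0.3) {
  intervals <- if (is.data.frame(mcr)) mcr else mcr$intervals
  if (is.null(intervals) || nrow(intervals) == 0) {
    stop("MCR is empty; cannot assign the MCR_LOSS subclass")
  }
  segments <- validate_segments(segments)
  loss <- segments[segments$segment_mean < -threshold, , drop = FALSE]
  overlapping <- character(0)
  if (nrow(loss) > 0) {
    h <- .fo(.as_granges(loss),
                                     .as_granges(intervals))
    overlapping <- unique(loss$sample_id[S4Vectors::queryHits(h)])
  }
  sub <- ifelse(hits$pmn_hit, "PMN_HIT",
                ifelse(hits$sample_id %in% overlapping, "MCR_LOSS", "WT"))
  data.frame(sample_id = hits$sample_id,
             subclass = factor(sub, levels = c("PMN_HIT", "MCR_LOSS", "WT")),
             stringsAsFactors = FALSE)
}

#' Linear model of MYC expression on PMN-hit status, adjusting for grade
#'
#' Ordinary least squares of MYC log-expression on an indicator of PMN-hit
#' plus molecular grade as a categorical covariate (grade 2 reference).
#' With a single grade present, the grade term is dropped and the model
#' reduces to a two-group comparison whose coefficient is the group mean
#' difference.
#'
#' @param expr Expression matrix (genes x samples).
#' @param hits PMN-hit table from [pmn_hit_status()] (or any data.frame
#'   with `sample_id` and a logical `pmn_hit`).
#' @param clinical Clinical table (needs `sample_id`, `molecular_grade`).
#' @param gene Response gene (default `"MYC"`).
#' @return Object of class `myc_lm`: list with `coef_pmn_hit`, `se`,
#'   `p_value` (two-sided t), `grade_coefs`, `n`, and the `lm` fit.
#' @export
myc_linear_model <- function(expr, hits, clinical, gene = "MYC") {
  ids <- intersect(intersect(colnames(expr), hits$sample_id),
                   clinical$sample_id)
  if (length(ids) < 4) stop("too few samples with complete data")
  y <- expr[gene, ids]
  hit <- hits$pmn_hit[match(ids, hits$sample_id)]
  grade <- factor(clinical$molecular_grade[match(ids, clinical$sample_id)])
  grade <- droplevels(grade)
  dat <- data.frame(y = y, pmn_hit = hit, grade = grade)
  fit <- if (nlevels(grade) > 1) {
    stats::lm(y ~ pmn_hit + grade, data = dat)
  } else {
    stats::lm(y ~ pmn_hit, data = dat)
  }
  cf <- stats::coef(fit)
  if (any(is.na(cf))) {
    stop("singular design; aliased column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  grade_rows <- grepl("^grade", rownames(sm))
  structure(list(
    coef_pmn_hit = unname(sm["pmn_hitTRUE", "Estimate"]),
    se = unname(sm["pmn_hitTRUE", "Std. Error"]),
    p_value = unname(sm["pmn_hitTRUE", "Pr(>|t|)"]),
    grade_coefs = stats::setNames(sm[grade_rows, "Estimate"],
                                  rownames(sm)[grade_rows]),
    n = length(ids), fit = fit
  ), class = "myc_lm")
}

#' @export
print.myc_lm <- function(x, ...) {
  cat("MYC ~ PMN-hit + grade (n =", x$n, ")\n")
  cat("PMN-hit coefficient:", format(x$coef_pmn_hit, digits = 4),
      "(SE", format(x$se, digits = 3), "), p =",
      format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Cochran-Armitage trend test across ordered grades
#'
#' Score test for a linear trend in a binary label across ordered grade
#' levels; the statistic is standard normal under the null and the p-value
#' is two-sided. Equal proportions across grades give statistic 0, p = 1.
#'
#' @param labels Logical (or 0/1) vector per sample.
#' @param grades Ordered grade values per sample (e.g. 2, 3, 4).
#' @param scores Numeric scores for the ordered levels (default: the sorted
#'   unique grade values).
#' @return List with `statistic` (Z) and `p_value`.
#' @export
grade_trend_test <- function(labels, grades, scores = NULL) {
  labels <- as.numeric(labels)
  lev <- sort(unique(grades))
  if (length(lev) < 2) stop("need at least 2 grade levels present")
  if (is.null(scores)) scores <- lev
  stopifnot(length(scores) == length(lev))
  n_i <- as.numeric(table(factor(grades, levels = lev)))
  x_i <- as.numeric(tapply(labels, factor(grades, levels = lev), sum))
  N <- sum(n_i)
  pbar <- sum(x_i) / N
  num <- sum(scores * x_i) - pbar * sum(scores * n_i)
  v <- pbar * (1 - pbar) * (sum(n_i * scores^2) - sum(n_i * scores)^2 / N)
  if (v <= 0) return(list(statistic = 0, p_value = 1))
  z <- num / sqrt(v)
  list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' k-group log-rank test
#'
#' Standard log-rank chi-square with k-1 degrees of freedom, via
#' [survival::survdiff()].
#'
#' @param times Event/censoring times.
#' @param events Logical (or 0/1) event indicators.
#' @param groups Group label per subject.
#' @return List with `chi2`, `df`, `p_value`.
#' @export
logrank_test <- function(times, events, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (sum(events) < 1) stop("need at least 1 event")
  sd <- survival::survdiff(survival::Surv(times, as.numeric(events)) ~ groups)
  df <- nlevels(groups) - 1
  list(chi2 = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Fisher's exact test of subclass vs grade
#'
#' Exact network algorithm where feasible; falls back to a Monte-Carlo
#' p-value (flagged) if the exact computation fails or the table is large.
#'
#' @param subclass Subclass label per sample.
#' @param grades Grade per sample.
#' @param mc_B Monte-Carlo replicates for the fallback (default 1e5).
#' @return List with `p_value`, `method` (`"exact"` or `"monte-carlo"`),
#'   and the contingency `table`.
#' @export
subclass_fisher <- function(subclass, grades, mc_B = 1e5) {
  tab <- table(droplevels(factor(subclass)), droplevels(factor(grades)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) ||
      nrow(tab) < 2 || ncol(tab) < 2) {
    stop("contingency table has an empty margin")
  }
  ft <- tryCatch(stats::fisher.test(tab, workspace = 2e6),
                 error = function(e) NULL)
  if (is.null(ft)) {
    ft <- stats::fisher.test(tab, simulate.p.value = TRUE, B = mc_B)
    method <- "monte-carlo"
  } else {
    method <- "exact"
  }
  list(p_value = ft$p.value, method = method, table = tab)
}
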