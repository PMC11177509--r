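# Two-filter screen for candidate MYC regulators in PMN-wild-type samples:
# (a) expression correlation with MYC, (b) alteration associated with higher
# MYC expression.

#' Default gene exclusion list for the regulator screen
#'
#' Commonly mutated astrocytoma genes (IDH1/2, TP53, ATRX, CDKN2A/B) plus
#' the 14 PMN genes.
#'
#' @return Character vector of symbols.
#' @export
screen_exclude_genes <- function() {
  c("IDH1", "IDH2", "TP53", "ATRX", "CDKN2A", "CDKN2B", pmn_genes())
}

#' Select PMN-wild-type samples
#' @param hits PMN-hit table from [pmn_hit_status()].
#' @return Character vector of sample ids with no somatic PMN alteration.
#' @export
select_pmn_wt <- function(hits) {
  if (nrow(hits) == 0) stop("empty hit table")
  hits$sample_id[!hits$pmn_hit]
}

#' Screen filter (a): expression correlation with MYC
#'
#' Pearson correlation between each non-excluded gene and the target gene
#' across the given samples, with p-values from the t transform on `n - 2`
#' degrees of freedom. A gene passes iff `|r| > r_min` and `p < alpha`
#' (both strict). Zero-variance genes are flagged and never pass.
#'
#' @param expr Expression matrix (genes x samples, log scale).
#' @param samples Sample ids to use (at least 3).
#' @param target_gene Target symbol (default `"MYC"`).
#' @param r_min Correlation magnitude cutoff (default 0.2).
#' @param alpha Significance cutoff (default 0.05).
#' @param exclude Symbols excluded from testing
#'   (default [screen_exclude_genes()]).
#' @return `data.frame` with `gene`, `pearson_r`, `pearson_p`, `passes_a`,
#'   `flag` (`"ok"` or `"zero_variance"`).
#' @export
correlation_filter <- function(expr, samples, target_gene = "MYC",
                               r_min = 0.2, alpha = 0.05,
                               exclude = screen_exclude_genes()) {
  if (!(target_gene %in% rownames(expr))) {
    stop("target gene '", target_gene, "' not in expression matrix")
  }
  samples <- intersect(colnames(expr), samples)
  if (length(samples) < 3) stop("need at least 3 samples")
  genes <- setdiff(rownames(expr), c(target_gene, exclude))
  E <- expr[genes, samples, drop = FALSE]
  y <- expr[target_gene, samples]
  n <- length(samples)

  sds <- apply(E, 1, stats::sd)
  flag <- ifelse(sds == 0 | stats::sd(y) == 0, "zero_variance", "ok")
  r <- rep(NA_real_, length(genes))
  ok <- flag == "ok"
  if (any(ok)) {
    r[ok] <- as.numeric(stats::cor(t(E[ok, , drop = FALSE]), y))
  }
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  passes <- !is.na(r) & abs(r) > r_min & p < alpha
  if (any(!ok)) {
    message(sum(!ok), " zero-variance gene(s) flagged and excluded from ",
            "filter (a)")
  }
  data.frame(gene = genes, pearson_r = r, pearson_p = p,
             passes_a = passes, flag = flag,
             stringsAsFactors = FALSE, row.names = NULL)
}

# One-tailed Wilcoxon rank-sum p-value (alternative: x stochastically
# greater than y). Exact enumeration when both groups are small and there
# are no ties; otherwise normal approximation with tie and continuity
# correction.
.wilcoxon_greater <- function(x, y, exact_max = 10) {
  use_exact <- min(length(x), length(y)) <= exact_max &&
    !any(duplicated(c(x, y)))
  w <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "greater", exact = use_exact,
                       correct = TRUE)
  )
  unname(w$p.value)
}

#' Screen filter (b): alterations associated with higher MYC expression
#'
#' A sample is "altered" for gene g iff g has a non-NEUTRAL copy-number
#' call or a non-silent variant in that sample. Genes altered in at least
#' `freq_range[1]` and at most `freq_range[2]` of the samples (inclusive)
#' are tested with a one-tailed Wilcoxon rank-sum test for higher MYC
#' expression in the altered group; a gene passes iff `p < alpha`.
#'
#' @param calls Gene call `data.frame` from [call_gene_scna()].
#' @param variants Variant `data.frame` (may be empty).
#' @param expr Expression matrix (genes x samples).
#' @param samples Sample ids to use.
#' @param target_gene Expression readout gene (default `"MYC"`).
#' @param freq_range Altered-fraction window (default `c(0.1, 0.9)`).
#' @param alpha Significance cutoff (default 0.05).
#' @param exclude Symbols excluded from testing.
#' @param nonsilent Variant classes counted as alterations.
#' @return `data.frame` with `gene`, `wilcoxon_p`, `n_altered`,
#'   `altered_fraction`, `passes_b`.
#' @export
alteration_filter <- function(calls, variants, expr, samples,
                              target_gene = "MYC", freq_range = c(0.1, 0.9),
                              alpha = 0.05,
                              exclude = screen_exclude_genes(),
                              nonsilent = nonsilent_classes()) {
  samples <- intersect(unique(calls$sample_id), samples)
  samples <- intersect(samples, colnames(expr))
  if (length(samples) < 3) stop("need at least 3 samples")
  y <- expr[target_gene, samples]
  genes <- setdiff(unique(calls$gene), c(target_gene, exclude))

  m <- .alteration_matrix(calls)[samples, , drop = FALSE]
  if (nrow(variants) > 0) {
    v <- variants[variants$sample_id %in% samples &
                    variants$gene %in% colnames(m) &
                    variants$variant_class %in% nonsilent, , drop = FALSE]
    if (nrow(v) > 0) {
      m[cbind(match(v$sample_id, samples), match(v$gene, colnames(m)))] <- TRUE
    }
  }
  n <- length(samples)
  res <- lapply(genes, function(g) {
    alt <- if (g %in% colnames(m)) m[, g] else rep(FALSE, n)
    na <- sum(alt)
    frac <- na / n
    if (frac >= freq_range[1] && frac <= freq_range[2]) {
      p <- .wilcoxon_greater(y[alt], y[!alt])
      data.frame(gene = g, wilcoxon_p = p, n_altered = na,
                 altered_fraction = frac, passes_b = p < alpha,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(gene = g, wilcoxon_p = NA_real_, n_altered = na,
                 altered_fraction = frac, passes_b = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Combine the two screen filters into candidate calls
#'
#' A gene is a candidate iff it passes both filter (a) and filter (b).
#' Candidates are sorted by Wilcoxon p ascending, ties broken by `|r|`
#' descending, then by symbol.
#'
#' @param a_results Output of [correlation_filter()].
#' @param b_results Output of [alteration_filter()].
#' @return `data.frame` of candidate genes with all screen columns.
#' @export
combine_screen <- function(a_results, b_results) {
  merged <- merge(a_results, b_results, by = "gene")
  merged$candidate <- merged$passes_a & merged$passes_b
  cand <- merged[merged$candidate, , drop = FALSE]
  if (nrow(cand) > 0) {
    cand <- cand[order(cand$wilcoxon_p, -abs(cand$pearson_r), cand$gene), ,
                 drop = FALSE]
  }
  rownames(cand) <- NULL
  cand
}
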