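# Stratified Monte-Carlo permutation test for SCNA-count enrichment in a
# gene set.

# samples x genes logical alteration matrix from a gene-call table
.alteration_matrix <- function(calls) {
  samples <- unique(calls$sample_id)
  genes <- unique(calls$gene)
  m <- matrix(FALSE, length(samples), length(genes),
              dimnames = list(samples, genes))
  alt <- calls[calls$state != "NEUTRAL", , drop = FALSE]
  m[cbind(match(alt$sample_id, samples), match(alt$gene, genes))] <- TRUE
  m
}

#' Count SCNA events over a sample and gene subset
#'
#' Number of (sample, gene) pairs in `samples x genes` whose call state is
#' not NEUTRAL.
#'
#' @param calls Gene call `data.frame` from [call_gene_scna()].
#' @param samples Character vector of sample ids (subset of the call
#'   universe).
#' @param genes Character vector of gene symbols.
#' @return Integer count.
#' @export
count_scna_events <- function(calls, samples, genes) {
  if (length(samples) == 0 || length(genes) == 0) {
    stop("samples and genes must be non-empty")
  }
  m <- .alteration_matrix(calls)
  if (!all(samples %in% rownames(m))) stop("unknown sample id(s)")
  if (!all(genes %in% colnames(m))) stop("unknown gene(s)")
  sum(m[samples, genes, drop = FALSE])
}

#' Stratified Monte-Carlo permutation test for SCNA enrichment
#'
#' Tests whether the observed number of SCNA events in a target gene set,
#' counted over the samples that carry at least one such event, exceeds what
#' random sampling would produce. Each of `B` iterations draws, without
#' replacement, the same number of samples from the full cohort and the same
#' number of genes from the full gene universe and counts SCNA events in the
#' random block. The empirical p-value uses the add-one estimator
#' `(1 + #\{null >= observed\}) / (B + 1)`, so it is never exactly zero, and
#' ties count toward the numerator.
#'
#' @param calls Gene call `data.frame` from [call_gene_scna()].
#' @param target_genes Character vector of target gene symbols.
#' @param n_altered_samples Optional integer; if supplied it must equal the
#'   number of samples carrying at least one SCNA in `target_genes`
#'   (consistency check against an externally stated count).
#' @param B Number of Monte-Carlo iterations (default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @return Object of class `perm_test`: list with `observed_count`,
#'   `null_counts` (length `B`), `b_iterations`, `p_value`,
#'   `n_altered_samples`, `n_target_genes`, `seed`.
#' @export
stratified_permutation_test <- function(calls, target_genes,
                                        n_altered_samples = NULL,
                                        B = 10000, seed = NULL) {
  stopifnot(B >= 1)
  m <- .alteration_matrix(calls)
  if (!all(target_genes %in% colnames(m))) {
    stop("target gene(s) not in call universe: ",
         paste(setdiff(target_genes, colnames(m)), collapse = ", "))
  }
  k <- length(target_genes)
  if (k > ncol(m)) stop("gene universe smaller than target set")
  altered <- rownames(m)[rowSums(m[, target_genes, drop = FALSE]) > 0]
  if (length(altered) == 0) stop("no sample has an SCNA in the target genes")
  if (is.null(n_altered_samples)) {
    n_altered_samples <- length(altered)
  } else if (n_altered_samples != length(altered)) {
    stop("n_altered_samples (", n_altered_samples, ") does not match the ",
         length(altered), " samples with >=1 SCNA in the target genes")
  }
  if (n_altered_samples > nrow(m)) stop("n_altered_samples exceeds cohort")
  observed <- sum(m[altered, target_genes, drop = FALSE])

  if (!is.null(seed)) set.seed(seed)
  nS <- nrow(m)
  nG <- ncol(m)
  null_counts <- integer(B)
  for (b in seq_len(B)) {
    si <- sample.int(nS, n_altered_samples)
    gi <- sample.int(nG, k)
    null_counts[b] <- sum(m[si, gi])
  }
  p <- (1 + sum(null_counts >= observed)) / (B + 1)
  structure(list(observed_count = observed, null_counts = null_counts,
                 b_iterations = B, p_value = p,
                 n_altered_samples = n_altered_samples,
                 n_target_genes = k, seed = seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Stratified permutation test:", x$observed_count, "SCNA events in",
      x$n_target_genes, "genes across", x$n_altered_samples, "samples\n")
  cat("null mean", round(mean(x$null_counts), 2), "over", x$b_iterations,
      "iterations; p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}
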