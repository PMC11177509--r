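# Per-sample genomic-instability metrics and group comparisons. The exact
# wGII/CAER/chromothripsis constants are reconstructions of standard
# definitions and all are exposed as arguments.

#' Genomic-instability metrics for one sample
#'
#' * `snv_burden`, `indel_burden`: counts of SNV and INS+DEL records.
#' * `wgii`: weighted genomic instability index — per chromosome, the
#'   fraction of its length covered by segments with `|mean| > threshold`,
#'   averaged over the chromosomes of `genome`.
#' * `caer`: chromosomal arm event ratio — fraction of arms in which at
#'   least `arm_event_fraction` of the arm length is altered in a single
#'   direction (all-gain or all-loss).
#' * `cn_amplitude`: maximum `|segment_mean|` (0 with no segments).
#' * `chromothripsis`: TRUE iff some chromosome's position-ordered segment
#'   states (GAIN/LOSS/NEUTRAL by `threshold`) change at least
#'   `oscillation_min` times.
#'
#' @param segments Segment `data.frame`.
#' @param variants Variant `data.frame` (may be empty).
#' @param sample_id Sample to assess.
#' @param genome Genome description from [toy_genome()].
#' @param threshold SCNA log-ratio threshold (default 0.3).
#' @param arm_event_fraction Arm coverage needed for an arm-level event
#'   (default 0.5).
#' @param oscillation_min Minimum state changes on one chromosome for the
#'   chromothripsis flag (default 10).
#' @return One-row `data.frame` with the metric columns.
#' @export
compute_metrics <- function(segments, variants, sample_id,
                            genome = toy_genome(), threshold = 0.3,
                            arm_event_fraction = 0.5, oscillation_min = 10) {
  segments <- validate_segments(segments)
  if (nrow(genome) == 0 || any(is.na(genome$length))) {
    stop("genome configuration with chromosome lengths is required")
  }
  s <- segments[segments$sample_id == sample_id, , drop = FALSE]
  v <- variants[variants$sample_id == sample_id, , drop = FALSE]

  snv <- sum(v$variant_type == "SNV")
  indel <- sum(v$variant_type %in% c("INS", "DEL"))

  state <- function(m) ifelse(m > threshold, "GAIN",
                              ifelse(m < -threshold, "LOSS", "NEUTRAL"))
  altered <- s[abs(s$segment_mean) > threshold, , drop = FALSE]

  frac_covered <- function(intervals, chrom, lo, hi) {
    x <- intervals[intervals$chrom == chrom, , drop = FALSE]
    if (nrow(x) == 0) return(0)
    cov <- .gr_intersect(.as_granges(x),
                         .as_granges(data.frame(chrom = chrom, start = lo,
                                                end = hi)))
    sum(GenomicRanges::width(cov)) / (hi - lo + 1)
  }
  wgii <- mean(vapply(seq_len(nrow(genome)), function(i) {
    frac_covered(altered, genome$chrom[i], 1, genome$length[i])
  }, numeric(1)))

  arm_bounds <- data.frame(
    chrom = rep(genome$chrom, 2),
    start = c(rep(1, nrow(genome)), genome$p_end + 1),
    end = c(genome$p_end, genome$length)
  )
  gains <- s[s$segment_mean > threshold, , drop = FALSE]
  losses <- s[s$segment_mean < -threshold, , drop = FALSE]
  arm_event <- vapply(seq_len(nrow(arm_bounds)), function(i) {
    a <- arm_bounds[i, ]
    frac_covered(gains, a$chrom, a$start, a$end) >= arm_event_fraction ||
      frac_covered(losses, a$chrom, a$start, a$end) >= arm_event_fraction
  }, logical(1))
  caer <- mean(arm_event)

  amp <- if (nrow(s) == 0) 0 else max(abs(s$segment_mean))

  chromo <- any(vapply(unique(s$chrom), function(ch) {
    x <- s[s$chrom == ch, , drop = FALSE]
    x <- x[order(x$start), , drop = FALSE]
    st <- state(x$segment_mean)
    if (length(st) < 2) return(FALSE)
    sum(st[-1] != st[-length(st)]) >= oscillation_min
  }, logical(1)))

  data.frame(sample_id = sample_id, snv_burden = snv, indel_burden = indel,
             wgii = wgii, caer = caer, cn_amplitude = amp,
             chromothripsis = chromo, stringsAsFactors = FALSE)
}

#' Genomic-instability metrics for every sample
#' @inheritParams compute_metrics
#' @param samples Sample ids (default: all in `segments`).
#' @return `data.frame`, one row per sample.
#' @export
compute_metrics_all <- function(segments, variants, genome = toy_genome(),
                                samples = unique(segments$sample_id), ...) {
  out <- do.call(rbind, lapply(samples, function(sm) {
    compute_metrics(segments, variants, sm, genome = genome, ...)
  }))
  rownames(out) <- NULL
  out
}

#' Compare instability metrics between groups
#'
#' Numeric metrics use a two-sided Wilcoxon rank-sum test for 2 groups or
#' Kruskal-Wallis for 3 or more; the chromothripsis flag uses Fisher's
#' exact test. The direction column names the group with the highest
#' median (numeric metrics) or highest flag rate.
#'
#' @param metrics `data.frame` from [compute_metrics_all()].
#' @param groups Group label per row of `metrics`.
#' @return `data.frame` with `metric`, `test`, `statistic`, `p_value`,
#'   `direction`.
#' @export
compare_groups <- function(metrics, groups) {
  groups <- factor(groups)
  sizes <- table(groups)
  if (length(sizes) < 2 || any(sizes < 2)) {
    stop("need >=2 groups with >=2 samples each; got sizes: ",
         paste(sizes, collapse = ", "))
  }
  num_metrics <- c("snv_burden", "indel_burden", "wgii", "caer",
                   "cn_amplitude")
  res <- lapply(num_metrics, function(mname) {
    x <- metrics[[mname]]
    med <- tapply(x, groups, stats::median)
    dir <- names(med)[which.max(med)]
    if (diff(range(med)) == 0) dir <- NA_character_
    if (nlevels(groups) == 2) {
      g <- levels(groups)
      w <- suppressWarnings(stats::wilcox.test(x[groups == g[1]],
                                               x[groups == g[2]]))
      data.frame(metric = mname, test = "wilcoxon",
                 statistic = unname(w$statistic), p_value = w$p.value,
                 direction = dir, stringsAsFactors = FALSE)
    } else {
      k <- stats::kruskal.test(x, groups)
      data.frame(metric = mname, test = "kruskal-wallis",
                 statistic = unname(k$statistic), p_value = k$p.value,
                 direction = dir, stringsAsFactors = FALSE)
    }
  })
  tab <- table(groups, factor(metrics$chromothripsis, levels = c(FALSE, TRUE)))
  rate <- tab[, 2] / rowSums(tab)
  fdir <- rownames(tab)[which.max(rate)]
  if (diff(range(rate)) == 0) fdir <- NA_character_
  f <- stats::fisher.test(tab)
  res[[length(res) + 1]] <- data.frame(
    metric = "chromothripsis", test = "fisher", statistic = NA_real_,
    p_value = f$p.value, direction = fdir, stringsAsFactors = FALSE)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
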