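# Minimal-common-region discovery over loss segments, gene containment, and
# arm-level loss status.

#' Extract per-sample loss segments
#'
#' Segments whose mean is below `-threshold` (strict), split by sample.
#'
#' @param segments Segment `data.frame`.
#' @param threshold Positive log-ratio threshold (default 0.3).
#' @return Named list (by sample) of `data.frame`s with `chrom`, `start`,
#'   `end`.
#' @export
loss_segments <- function(segments, threshold = 0.3) {
  segments <- validate_segments(segments)
  l <- segments[segments$segment_mean < -threshold, , drop = FALSE]
  split(l[, c("chrom", "start", "end")], l$sample_id)
}

#' Find the minimal common region of copy-number loss
#'
#' Per-sample loss intervals are merged (overlapping or abutting intervals
#' coalesced) and then intersected across all samples: the result is the
#' maximal set of intervals covered by a merged loss segment of every
#' sample. Intervals are 1-based fully closed. Multiple disjoint intervals
#' are reported when support permits; the list is empty if no base is shared.
#'
#' @param loss_by_sample Named list of loss-interval `data.frame`s
#'   (`chrom`, `start`, `end`), e.g. from [loss_segments()].
#' @param samples Sample ids to intersect (default: all names of
#'   `loss_by_sample`). Every one must have at least one loss interval.
#' @param annotation Optional gene annotation; when given,
#'   `genes_contained` is filled via [genes_in_region()].
#' @return Object of class `mcr_result`: list with `intervals`
#'   (`data.frame` chrom/start/end), `n_samples`, `genes_contained`,
#'   `per_sample_support` (named list of each sample's merged loss intervals
#'   overlapping the MCR).
#' @export
find_mcr <- function(loss_by_sample, samples = names(loss_by_sample),
                     annotation = NULL) {
  if (length(samples) == 0) stop("no samples given")
  missing <- samples[!(samples %in% names(loss_by_sample)) |
                       vapply(loss_by_sample[samples],
                              function(d) is.null(d) || nrow(d) == 0,
                              logical(1))]
  if (length(missing)) {
    stop("sample(s) with no loss segments: ", paste(missing, collapse = ", "))
  }
  merged <- lapply(loss_by_sample[samples], function(d) {
    GenomicRanges::reduce(.as_granges(d))
  })
  inter <- Reduce(.gr_intersect, merged)
  intervals <- .gr_to_df(inter)

  support <- lapply(merged, function(gr) {
    if (nrow(intervals) == 0) {
      return(intervals)
    }
    keep <- .fo(gr, inter)
    .gr_to_df(gr[unique(S4Vectors::queryHits(keep))])
  })
  genes <- character(0)
  if (!is.null(annotation) && nrow(intervals) > 0) {
    genes <- genes_in_region(intervals, annotation)
  }
  structure(list(intervals = intervals, n_samples = length(samples),
                 genes_contained = genes, per_sample_support = support),
            class = "mcr_result")
}

#' @export
print.mcr_result <- function(x, ...) {
  cat("MCR over", x$n_samples, "samples:", nrow(x$intervals), "interval(s)\n")
  if (nrow(x$intervals) > 0) {
    apply(x$intervals, 1, function(r) {
      cat("  ", r[["chrom"]], ":", r[["start"]], "-", r[["end"]], "\n",
          sep = "")
    })
  }
  if (length(x$genes_contained)) {
    cat("genes contained:", paste(x$genes_contained, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Genes overlapping a set of intervals
#'
#' Returns genes with at least 1 bp of overlap with any interval, sorted by
#' coordinate. Intervals and annotation are 1-based closed, so a gene
#' starting at `end + 1` does not overlap.
#'
#' @param intervals `data.frame` with `chrom`, `start`, `end`.
#' @param annotation Gene annotation `data.frame`.
#' @return Character vector of gene symbols.
#' @export
genes_in_region <- function(intervals, annotation) {
  validate_annotation(annotation)
  if (nrow(intervals) == 0) return(character(0))
  h <- .fo(.as_granges(annotation),
                                   .as_granges(intervals))
  idx <- sort(unique(S4Vectors::queryHits(h)))
  ann <- annotation[idx, , drop = FALSE]
  ann$gene[order(ann$chrom, ann$start)]
}

#' Chromosome-arm loss status for one sample
#'
#' An arm is flagged "lost" iff at least `arm_loss_fraction` of its length
#' is covered by LOSS segments (mean `< -threshold`).
#'
#' @param segments Segment `data.frame`.
#' @param sample_id Sample to assess.
#' @param genome Genome description from [toy_genome()] (chromosome lengths
#'   and p-arm ends).
#' @param threshold Positive log-ratio threshold (default 0.3).
#' @param arm_loss_fraction Minimum covered fraction (default 0.9).
#' @param arms Arms to assess, e.g. `"chr19q"`; default all arms of
#'   `genome`.
#' @return Named logical vector over arms.
#' @export
chrom_arm_loss_status <- function(segments, sample_id, genome = toy_genome(),
                                  threshold = 0.3, arm_loss_fraction = 0.9,
                                  arms = NULL) {
  segments <- validate_segments(segments)
  s <- segments[segments$sample_id == sample_id, , drop = FALSE]
  all_arms <- data.frame(
    arm = c(paste0(genome$chrom, "p"), paste0(genome$chrom, "q")),
    chrom = rep(genome$chrom, 2),
    start = c(rep(1, nrow(genome)), genome$p_end + 1),
    end = c(genome$p_end, genome$length),
    stringsAsFactors = FALSE
  )
  if (is.null(arms)) arms <- all_arms$arm
  unknown <- setdiff(arms, all_arms$arm)
  if (length(unknown)) stop("unknown arm(s): ", paste(unknown, collapse = ", "))
  arm_df <- all_arms[match(arms, all_arms$arm), , drop = FALSE]

  loss <- s[s$segment_mean < -threshold, , drop = FALSE]
  res <- vapply(seq_len(nrow(arm_df)), function(i) {
    a <- arm_df[i, ]
    l <- loss[loss$chrom == a$chrom, , drop = FALSE]
    if (nrow(l) == 0) return(FALSE)
    cov <- .gr_intersect(.as_granges(l), .as_granges(a))
    covered <- sum(GenomicRanges::width(cov))
    covered / (a$end - a$start + 1) >= arm_loss_fraction
  }, logical(1))
  stats::setNames(res, arm_df$arm)
}
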