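# Gene-level SCNA calling from copy-number segments and per-sample PMN-hit
# annotation.

#' The proximal MYC network gene set
#'
#' The curated 14-gene PMN: E-box transcription activators, inhibitors, and
#' the dimerization partners MAX/MLX, plus FBXW7 among the inhibitors as a
#' critical MYC regulator.
#'
#' @return Object of class `pmn_gene_set`: a list with character vectors
#'   `activators`, `inhibitors`, `dimerizers`.
#' @examples
#' pmn_gene_set()
#' @export
pmn_gene_set <- function() {
  structure(list(
    activators = c("MYC", "MYCN", "MYCL", "MLXIPL", "MLXIP"),
    inhibitors = c("FBXW7", "MGA", "MNT", "MXD4", "MXD3", "MXI1", "MXD1"),
    dimerizers = c("MAX", "MLX")
  ), class = "pmn_gene_set")
}

#' All 14 PMN gene symbols
#' @param pmn A [pmn_gene_set()] object.
#' @return Character vector of the 14 symbols.
#' @export
pmn_genes <- function(pmn = pmn_gene_set()) {
  unname(unlist(pmn))
}

#' Variant classes counted as non-silent
#'
#' Default include-list used when deciding whether a mutation contributes to
#' alteration status; Silent/Intron/UTR classes are excluded.
#'
#' @return Character vector of MAF variant classifications.
#' @export
nonsilent_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
    "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
    "Splice_Site", "Translation_Start_Site")
}

# Per sample+chromosome, segments must not overlap (1-based closed).
.check_segments_disjoint <- function(segments) {
  key <- paste(segments$sample_id, segments$chrom)
  for (k in unique(key)) {
    s <- segments[key == k, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
      stop("validation error: overlapping segments within ", k)
    }
  }
  invisible(TRUE)
}

#' Call gene-level somatic copy-number alterations
#'
#' Projects copy-number segments onto genes. For each (sample, gene) pair
#' with at least one overlapping segment the gene-level value is, by
#' default, the overlap-length-weighted mean of the overlapping segment
#' means (`gene_summary = "weighted_mean"`); `"extreme"` instead takes the
#' overlapping segment mean of largest magnitude. Genes with no overlapping
#' segment get value 0. States use strict inequalities: GAIN iff value
#' `> threshold`, LOSS iff value `< -threshold`, else NEUTRAL.
#'
#' @param segments Segment `data.frame` (see [read_segments()]); per sample
#'   and chromosome the segments must be non-overlapping.
#' @param annotation Gene annotation `data.frame` (see [read_annotation()]).
#' @param threshold Positive log-ratio threshold (default 0.3).
#' @param gene_summary `"weighted_mean"` (default) or `"extreme"`.
#' @return `data.frame` with one row per (sample, gene): `sample_id`,
#'   `gene`, `state` (`"GAIN"|"LOSS"|"NEUTRAL"`), `gene_segment_mean`.
#' @export
call_gene_scna <- function(segments, annotation, threshold = 0.3,
                           gene_summary = c("weighted_mean", "extreme")) {
  gene_summary <- match.arg(gene_summary)
  stopifnot(threshold > 0)
  segments <- validate_segments(segments)
  validate_annotation(annotation)
  .check_segments_disjoint(segments)

  samples <- unique(segments$sample_id)
  genes <- annotation$gene
  gene_gr <- .as_granges(annotation)
  seg_gr <- .as_granges(segments)
  hits <- .fo(gene_gr, seg_gr)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ow <- GenomicRanges::width(suppressWarnings(
    GenomicRanges::pintersect(gene_gr[q], seg_gr[s])))
  means <- segments$segment_mean[s]
  nG <- length(genes)
  # integer key: sample-major blocks of genes
  code <- (match(segments$sample_id[s], samples) - 1L) * nG + q
  if (gene_summary == "weighted_mean") {
    num <- rowsum(ow * means, code)
    den <- rowsum(ow, code)
    val <- as.numeric(num / den)
    idx <- as.integer(rownames(num))
  } else {
    val <- as.numeric(tapply(means, code, function(m) m[which.max(abs(m))]))
    idx <- as.integer(names(tapply(means, code, length)))
  }

  gsm <- rep(0, length(samples) * nG)
  gsm[idx] <- val
  state <- rep("NEUTRAL", length(gsm))
  state[gsm > threshold] <- "GAIN"
  state[gsm < -threshold] <- "LOSS"
  data.frame(sample_id = rep(samples, each = nG),
             gene = rep(genes, times = length(samples)),
             state = state, gene_segment_mean = gsm,
             stringsAsFactors = FALSE)
}

#' Per-sample PMN-hit status
#'
#' A sample is "PMN-hit" iff it has a non-NEUTRAL call in any PMN gene or a
#' non-silent somatic variant in a PMN gene. `hit_genes` lists each
#' contributing `(gene, kind)` with kind GAIN, LOSS or MUTATION.
#'
#' @param calls Gene call `data.frame` from [call_gene_scna()].
#' @param variants Variant `data.frame` (see [read_variants()]); may have
#'   zero rows.
#' @param pmn A [pmn_gene_set()].
#' @param nonsilent Character vector of variant classes counted as
#'   alterations (default [nonsilent_classes()]).
#' @return `data.frame` with `sample_id`, `pmn_hit` (logical) and
#'   `hit_genes` (string like `"MYC(GAIN);FBXW7(MUTATION)"`, `""` if none).
#' @export
pmn_hit_status <- function(calls, variants, pmn = pmn_gene_set(),
                           nonsilent = nonsilent_classes()) {
  pg <- pmn_genes(pmn)
  samples <- unique(calls$sample_id)
  universe <- unique(calls$gene)

  ev <- calls[calls$gene %in% pg & calls$state != "NEUTRAL",
              c("sample_id", "gene", "state")]
  names(ev)[3] <- "kind"

  if (nrow(variants) > 0) {
    unknown <- setdiff(unique(variants$gene), universe)
    if (length(unknown)) {
      warning("skipping variant(s) in gene symbol(s) not in the call ",
              "universe: ", paste(unknown, collapse = ", "))
    }
    mv <- variants[variants$gene %in% pg &
                     !(variants$gene %in% unknown) &
                     variants$variant_class %in% nonsilent,
                   c("sample_id", "gene"), drop = FALSE]
    if (nrow(mv) > 0) {
      mv <- unique(mv)
      mv$kind <- "MUTATION"
      ev <- rbind(ev, mv)
    }
  }
  hit_str <- vapply(samples, function(sm) {
    e <- ev[ev$sample_id == sm, , drop = FALSE]
    if (nrow(e) == 0) return("")
    e <- e[order(e$gene, e$kind), , drop = FALSE]
    paste0(e$gene, "(", e$kind, ")", collapse = ";")
  }, character(1))
  data.frame(sample_id = samples, pmn_hit = nzchar(hit_str),
             hit_genes = hit_str, stringsAsFactors = FALSE, row.names = NULL)
}
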