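# Programmatic fixtures on miniature coordinates.

# Random non-overlapping segmentation of a toy chromosome [1, L] for a set
# of samples; some gaps left uncovered. Small coordinates so the per-base
# oracles stay cheap.
random_segments <- function(n_samples = 2, L = 1000, max_segs = 6,
                            chrom = "chr19") {
  out <- list()
  for (i in seq_len(n_samples)) {
    k <- sample(1:max_segs, 1)
    cuts <- sort(sample(1:L, 2 * k))
    starts <- cuts[seq(1, 2 * k, by = 2)]
    ends <- cuts[seq(2, 2 * k, by = 2)]
    keep <- stats::runif(k) < 0.85   # leave occasional gaps
    if (!any(keep)) keep[1] <- TRUE
    out[[i]] <- data.frame(
      sample_id = sprintf("S%02d", i), chrom = chrom,
      start = starts[keep], end = ends[keep],
      num_probes = pmax(1, (ends - starts + 1)[keep] %/% 10),
      segment_mean = round(stats::rnorm(sum(keep), 0, 0.6), 3),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

random_annotation <- function(n_genes = 5, L = 1000, chrom = "chr19") {
  starts <- sort(sample(1:(L - 20), n_genes))
  data.frame(gene = sprintf("G%02d", seq_len(n_genes)), chrom = chrom,
             start = starts,
             end = pmin(L, starts + sample(5:40, n_genes, replace = TRUE)),
             arm = "q", stringsAsFactors = FALSE)
}

# Random loss-interval lists for MCR tests, guaranteed >=1 interval per
# sample, on [1, L].
random_loss_lists <- function(n_samples = 4, L = 10000, max_iv = 4) {
  out <- lapply(seq_len(n_samples), function(i) {
    k <- sample(1:max_iv, 1)
    s <- sample(1:(L - 10), k)
    data.frame(chrom = "chr19", start = s,
               end = pmin(L, s + sample(10:4000, k, replace = TRUE)),
               stringsAsFactors = FALSE)
  })
  names(out) <- sprintf("S%02d", seq_len(n_samples))
  out
}

# Minimal valid call table from explicit (sample, gene, mean) triples.
calls_from <- function(samples, genes, means, threshold = 0.3) {
  state <- ifelse(means > threshold, "GAIN",
                  ifelse(means < -threshold, "LOSS", "NEUTRAL"))
  data.frame(sample_id = samples, gene = genes, state = state,
             gene_segment_mean = means, stringsAsFactors = FALSE)
}

# A small cell_cn object with explicit values.
small_cell_cn <- function(cn, types = NULL, counts = NULL,
                          regions = NULL) {
  n <- ncol(cn)
  if (is.null(types)) types <- rep("Cancer stem cells", n)
  if (is.null(counts)) counts <- rep(1L, n)
  if (is.null(regions)) {
    regions <- tile_regions("chr19", 55005440, 56958964, nrow(cn))
  }
  colnames(cn) <- sprintf("C%03d", seq_len(n))
  cell_cn(regions, cn,
          data.frame(cell_id = colnames(cn), cell_type = types,
                     myc_count = counts, stringsAsFactors = FALSE))
}
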