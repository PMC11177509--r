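seg_row <- function(sample, chrom, start, end, mean) {
  data.frame(sample_id = sample, chrom = chrom, start = start, end = end,
             num_probes = 10, segment_mean = mean, stringsAsFactors = FALSE)
}

test_that("single-overlap genes inherit the segment mean; boundary is strict", {
  ann <- data.frame(gene = c("GA", "GB"), chrom = "chr19",
                    start = c(100, 500), end = c(199, 600), arm = "q",
                    stringsAsFactors = FALSE)
  seg <- rbind(seg_row("S1", "chr19", 1, 149, 0.6),
               seg_row("S1", "chr19", 150, 400, 0.0),
               seg_row("S1", "chr19", 401, 1000, -0.8))
  calls <- call_gene_scna(seg, ann)
  ga <- calls[calls$gene == "GA", ]
  gb <- calls[calls$gene == "GB", ]
  # GA: 50 bases at 0.6, 50 at 0.0 -> exactly 0.3 -> NEUTRAL (strict)
  expect_equal(ga$gene_segment_mean, 0.3)
  expect_equal(ga$state, "NEUTRAL")
  # GB fully inside the -0.8 segment
  expect_equal(gb$gene_segment_mean, -0.8)
  expect_equal(gb$state, "LOSS")
})

test_that("uncovered genes are NEUTRAL with mean 0", {
  ann <- data.frame(gene = "GA", chrom = "chr8", start = 100, end = 200,
                    arm = "p", stringsAsFactors = FALSE)
  seg <- seg_row("S1", "chr19", 1, 1000, -0.9)
  calls <- call_gene_scna(seg, ann)
  expect_equal(calls$gene_segment_mean, 0)
  expect_equal(calls$state, "NEUTRAL")
})

test_that("overlapping segments within a sample are rejected", {
  seg <- rbind(seg_row("S1", "chr19", 1, 100, 0.5),
               seg_row("S1", "chr19", 100, 200, 0.5))
  ann <- data.frame(gene = "GA", chrom = "chr19", start = 1, end = 50,
                    arm = "q", stringsAsFactors = FALSE)
  expect_error(call_gene_scna(seg, ann), "overlapping segments")
})

test_that("gene-level means match the per-base averaging oracle", {
  set.seed(101)
  for (rep in 1:60) {
    seg <- random_segments(n_samples = 2, L = 1000)
    ann <- random_annotation(n_genes = 4, L = 1000)
    calls <- call_gene_scna(seg, ann)
    for (i in seq_len(nrow(calls))) {
      s <- seg[seg$sample_id == calls$sample_id[i], , drop = FALSE]
      expect_equal(calls$gene_segment_mean[i],
                   oracle_gene_mean(s, ann$start[match(calls$gene[i], ann$gene)],
                                    ann$end[match(calls$gene[i], ann$gene)]),
                   tolerance = 1e-12)
    }
  }
})

test_that("raising the threshold never converts NEUTRAL to GAIN/LOSS", {
  set.seed(102)
  for (rep in 1:20) {
    seg <- random_segments(n_samples = 3, L = 1000)
    ann <- random_annotation(n_genes = 5, L = 1000)
    lo <- call_gene_scna(seg, ann, threshold = 0.2)
    hi <- call_gene_scna(seg, ann, threshold = 0.5)
    was_neutral <- lo$state == "NEUTRAL"
    expect_true(all(hi$state[was_neutral] == "NEUTRAL"))
    # and every non-neutral high-threshold call is non-neutral at low too
    expect_true(all(lo$state[hi$state != "NEUTRAL"] != "NEUTRAL"))
  }
})

test_that("a tiny threshold labels every covered gene with nonzero mean", {
  set.seed(103)
  seg <- random_segments(n_samples = 2, L = 1000)
  ann <- random_annotation(n_genes = 5, L = 1000)
  calls <- call_gene_scna(seg, ann, threshold = 1e-12)
  nz <- abs(calls$gene_segment_mean) > 1e-12
  expect_true(all(calls$state[nz] != "NEUTRAL"))
  expect_true(all(calls$state[!nz] == "NEUTRAL"))
})

test_that("extreme summary picks the largest-magnitude overlapping mean", {
  ann <- data.frame(gene = "GA", chrom = "chr19", start = 100, end = 199,
                    arm = "q", stringsAsFactors = FALSE)
  seg <- rbind(seg_row("S1", "chr19", 1, 149, 0.6),
               seg_row("S1", "chr19", 150, 400, -0.9))
  calls <- call_gene_scna(seg, ann, gene_summary = "extreme")
  expect_equal(calls$gene_segment_mean, -0.9)
  expect_equal(calls$state, "LOSS")
})

test_that("PMN gene set is the fixed 14-gene partition", {
  pmn <- pmn_gene_set()
  expect_length(pmn_genes(pmn), 14)
  expect_length(unique(pmn_genes(pmn)), 14)
  expect_setequal(pmn$dimerizers, c("MAX", "MLX"))
  expect_true("FBXW7" %in% pmn$inhibitors)
})

test_that("PMN-hit status combines SCNAs and non-silent mutations", {
  calls <- calls_from(
    samples = c("S1", "S1", "S2", "S2", "S3", "S3"),
    genes = rep(c("MYC", "FBXW7"), 3),
    means = c(0.8, 0, 0, 0, 0, 0))
  no_var <- data.frame(sample_id = character(0), gene = character(0),
                       chrom = character(0), pos = numeric(0),
                       ref = character(0), alt = character(0),
                       variant_type = character(0),
                       variant_class = character(0))
  hits <- pmn_hit_status(calls, no_var)
  expect_equal(hits$pmn_hit, c(TRUE, FALSE, FALSE))
  expect_equal(hits$hit_genes[1], "MYC(GAIN)")

  silent <- data.frame(sample_id = "S2", gene = "FBXW7", chrom = "chr8",
                       pos = 1, ref = "C", alt = "T", variant_type = "SNV",
                       variant_class = "Silent", stringsAsFactors = FALSE)
  hits2 <- pmn_hit_status(calls, silent)
  expect_false(hits2$pmn_hit[2])   # silent variants never count

  nonsil <- silent
  nonsil$variant_class <- "Missense_Mutation"
  hits3 <- pmn_hit_status(calls, nonsil)
  expect_true(hits3$pmn_hit[2])
  expect_equal(hits3$hit_genes[2], "FBXW7(MUTATION)")
})

test_that("variants in unknown genes are skipped with a warning", {
  calls <- calls_from("S1", "MYC", 0)
  v <- data.frame(sample_id = "S1", gene = "NOSUCH", chrom = "chr8",
                  pos = 1, ref = "C", alt = "T", variant_type = "SNV",
                  variant_class = "Missense_Mutation",
                  stringsAsFactors = FALSE)
  expect_warning(hits <- pmn_hit_status(calls, v), "NOSUCH")
  expect_false(hits$pmn_hit)
})
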