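# Readers/writers for every on-disk format the pipeline touches. All
# coordinates are 1-based fully closed (SEG convention); the only conversion
# happens when exporting BED (0-based half-open).

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) > 0 && length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1])[1]
    stop("parse error in ", path, ": line ", bad,
         " has ", nf[bad], " fields, expected ", nf[1])
  }
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
}

.check_header <- function(df, expected, path) {
  if (!identical(tolower(names(df)[seq_along(expected)]), tolower(expected))) {
    stop("unexpected header in ", path, ": got [",
         paste(names(df), collapse = ", "), "], expected [",
         paste(expected, collapse = ", "), "]")
  }
}

.num_col <- function(x, name, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad) > 0) {
    stop("parse error in ", path, ": non-numeric value '", x[bad[1]],
         "' in column ", name, ", data line ", bad[1],
         " (file line ", bad[1] + 1L, ")")
  }
  out
}

#' Validate a segment table
#'
#' Checks the invariants of copy-number segment records: positive 1-based
#' coordinates, `end >= start`, `num_probes >= 1`, recognized chromosomes.
#'
#' @param segments `data.frame` with columns `sample_id`, `chrom`, `start`,
#'   `end`, `num_probes`, `segment_mean`.
#' @return The input, invisibly, with normalized chromosome names.
#' @export
validate_segments <- function(segments) {
  need <- c("sample_id", "chrom", "start", "end", "num_probes", "segment_mean")
  miss <- setdiff(need, names(segments))
  if (length(miss)) stop("segment table missing column(s): ",
                         paste(miss, collapse = ", "))
  segments$chrom <- normalize_chrom(segments$chrom)
  if (any(segments$start < 1)) stop("validation error: segment start < 1")
  bad <- which(segments$end < segments$start)
  if (length(bad)) {
    stop("validation error: end < start for segment(s) at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (any(segments$num_probes < 1)) {
    stop("validation error: num_probes < 1")
  }
  invisible(segments)
}

#' Read a SEG-format copy-number segment file
#'
#' Tab-delimited with header
#' `Sample, Chromosome, Start, End, Num_Probes, Segment_Mean`. Chromosome
#' names are normalized to `"chrN"` form; coordinates are 1-based closed and
#' `Segment_Mean` is a log2 copy-ratio.
#'
#' @param path Path to the SEG file.
#' @return `data.frame` with columns `sample_id`, `chrom`, `start`, `end`,
#'   `num_probes`, `segment_mean`.
#' @seealso [write_segments()]
#' @export
read_segments <- function(path) {
  df <- .read_tsv(path)
  .check_header(df, c("Sample", "Chromosome", "Start", "End",
                      "Num_Probes", "Segment_Mean"), path)
  out <- data.frame(
    sample_id = as.character(df[[1]]),
    chrom = as.character(df[[2]]),
    start = .num_col(df[[3]], "Start", path),
    end = .num_col(df[[4]], "End", path),
    num_probes = .num_col(df[[5]], "Num_Probes", path),
    segment_mean = .num_col(df[[6]], "Segment_Mean", path),
    stringsAsFactors = FALSE
  )
  out$chrom <- normalize_chrom(out$chrom)
  validate_segments(out)
  out
}

#' Write a SEG-format segment file
#' @param segments Segment `data.frame` (see [read_segments()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  segments <- validate_segments(segments)
  out <- data.frame(Sample = segments$sample_id,
                    Chromosome = segments$chrom,
                    Start = segments$start,
                    End = segments$end,
                    Num_Probes = segments$num_probes,
                    Segment_Mean = segments$segment_mean)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.variant_type_ok <- function(type, ref, alt) {
  len <- function(a) ifelse(a == "-", 0L, nchar(a))
  switch(type,
         SNV = len(ref) == len(alt) & len(ref) >= 1,
         INS = len(alt) > len(ref),
         DEL = len(ref) > len(alt),
         FALSE)
}

#' Read a MAF-lite somatic variant table
#'
#' Tab-delimited with header `Sample, Gene, Chromosome, Position, Ref, Alt,
#' Variant_Type, Variant_Classification`. `Variant_Type` must be one of
#' `SNV`, `INS`, `DEL` and consistent with the ref/alt allele lengths
#' (`"-"` denotes the empty allele).
#'
#' @param path Path to the variant TSV.
#' @return `data.frame` with columns `sample_id`, `gene`, `chrom`, `pos`,
#'   `ref`, `alt`, `variant_type`, `variant_class`.
#' @export
read_variants <- function(path) {
  df <- .read_tsv(path)
  .check_header(df, c("Sample", "Gene", "Chromosome", "Position", "Ref",
                      "Alt", "Variant_Type", "Variant_Classification"), path)
  out <- data.frame(
    sample_id = as.character(df[[1]]),
    gene = as.character(df[[2]]),
    chrom = normalize_chrom(df[[3]]),
    pos = .num_col(df[[4]], "Position", path),
    ref = as.character(df[[5]]),
    alt = as.character(df[[6]]),
    variant_type = as.character(df[[7]]),
    variant_class = as.character(df[[8]]),
    stringsAsFactors = FALSE
  )
  validate_variants(out)
  out
}

#' Validate a variant table
#' @param variants Variant `data.frame` (see [read_variants()]).
#' @return The input, invisibly.
#' @export
validate_variants <- function(variants) {
  if (any(variants$pos < 1)) stop("validation error: variant pos < 1")
  bad_type <- !(variants$variant_type %in% c("SNV", "INS", "DEL"))
  if (any(bad_type)) {
    stop("validation error: unknown variant_type ",
         paste(unique(variants$variant_type[bad_type]), collapse = ", "))
  }
  ok <- mapply(.variant_type_ok, variants$variant_type, variants$ref,
               variants$alt)
  if (!all(ok)) {
    stop("validation error: variant_type inconsistent with ref/alt lengths ",
         "at row(s) ", paste(utils::head(which(!ok), 5), collapse = ", "))
  }
  invisible(variants)
}

#' Write a MAF-lite variant table
#' @param variants Variant `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  validate_variants(variants)
  out <- data.frame(Sample = variants$sample_id, Gene = variants$gene,
                    Chromosome = variants$chrom, Position = variants$pos,
                    Ref = variants$ref, Alt = variants$alt,
                    Variant_Type = variants$variant_type,
                    Variant_Classification = variants$variant_class)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genes-by-samples expression matrix
#'
#' TSV whose first column holds gene symbols and remaining columns one sample
#' each. Values are assumed to be log-scale normalized expression; the
#' package performs no normalization. Duplicate gene symbols and missing
#' cells are rejected.
#'
#' @param path Path to the expression TSV.
#' @return Numeric matrix, rownames = genes, colnames = samples.
#' @export
read_expression <- function(path) {
  df <- .read_tsv(path)
  if (ncol(df) < 2) stop("expression file needs a gene column plus samples")
  genes <- as.character(df[[1]])
  dup <- genes[duplicated(genes)]
  if (length(dup)) {
    stop("validation error: duplicate gene symbol(s): ",
         paste(unique(dup), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  na <- which(is.na(m), arr.ind = TRUE)
  if (nrow(na) > 0) {
    stop("validation error: missing value at gene '", genes[na[1, 1]],
         "', sample '", colnames(m)[na[1, 2]], "'")
  }
  m
}

#' Write a genes-by-samples expression matrix
#' @param expr Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' TSV with header `gene, chrom, start, end, arm`; 1-based closed
#' coordinates; `arm` is `"p"` or `"q"`. Gene symbols must be unique.
#'
#' @param path Path to the annotation TSV.
#' @return `data.frame` with those columns.
#' @export
read_annotation <- function(path) {
  df <- .read_tsv(path)
  .check_header(df, c("gene", "chrom", "start", "end", "arm"), path)
  out <- data.frame(gene = as.character(df$gene),
                    chrom = normalize_chrom(df$chrom),
                    start = .num_col(df$start, "start", path),
                    end = .num_col(df$end, "end", path),
                    arm = as.character(df$arm),
                    stringsAsFactors = FALSE)
  validate_annotation(out)
  out
}

#' Validate a gene annotation table
#' @param annotation Annotation `data.frame` (see [read_annotation()]).
#' @return The input, invisibly.
#' @export
validate_annotation <- function(annotation) {
  dup <- annotation$gene[duplicated(annotation$gene)]
  if (length(dup)) {
    stop("validation error: duplicate gene symbol(s) in annotation: ",
         paste(unique(dup), collapse = ", "))
  }
  if (any(annotation$start > annotation$end)) {
    stop("validation error: annotation start > end")
  }
  if (!all(annotation$arm %in% c("p", "q"))) {
    stop("validation error: arm must be 'p' or 'q'")
  }
  invisible(annotation)
}

#' Write a gene annotation table (native TSV)
#' @param annotation Annotation `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  validate_annotation(annotation)
  utils::write.table(annotation[, c("gene", "chrom", "start", "end", "arm")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export gene annotation as BED
#'
#' The only place the package leaves 1-based closed coordinates: BED is
#' written 0-based half-open (`start - 1`, `end`).
#'
#' @param annotation Annotation `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_bed <- function(annotation, path) {
  validate_annotation(annotation)
  bed <- data.frame(annotation$chrom, annotation$start - 1, annotation$end,
                    annotation$gene)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' TSV with columns `sample_id`, `histologic_grade` (2 or 3),
#' `cdkn2ab_homdel` (logical), `molecular_grade` (2, 3 or 4), `os_time`,
#' `os_event`, `pfi_time`, `pfi_event`. Molecular grade must be 4 exactly
#' when CDKN2A/B is homozygously deleted and equal the histologic grade
#' otherwise.
#'
#' @param path Path to the clinical TSV.
#' @return `data.frame` with those columns.
#' @export
read_clinical <- function(path) {
  df <- .read_tsv(path)
  need <- c("sample_id", "histologic_grade", "cdkn2ab_homdel",
            "molecular_grade", "os_time", "os_event", "pfi_time", "pfi_event")
  .check_header(df, need, path)
  out <- data.frame(
    sample_id = as.character(df$sample_id),
    histologic_grade = .num_col(df$histologic_grade, "histologic_grade", path),
    cdkn2ab_homdel = as.logical(df$cdkn2ab_homdel),
    molecular_grade = .num_col(df$molecular_grade, "molecular_grade", path),
    os_time = .num_col(df$os_time, "os_time", path),
    os_event = as.logical(df$os_event),
    pfi_time = .num_col(df$pfi_time, "pfi_time", path),
    pfi_event = as.logical(df$pfi_event),
    stringsAsFactors = FALSE
  )
  validate_clinical(out)
  out
}

#' Validate a clinical table
#' @param clinical Clinical `data.frame` (see [read_clinical()]).
#' @return The input, invisibly.
#' @export
validate_clinical <- function(clinical) {
  if (!all(clinical$histologic_grade %in% c(2, 3))) {
    stop("validation error: histologic_grade must be 2 or 3")
  }
  expected <- ifelse(clinical$cdkn2ab_homdel, 4, clinical$histologic_grade)
  if (!all(clinical$molecular_grade == expected)) {
    stop("validation error: molecular_grade must be 4 iff CDKN2A/B deleted, ",
         "else the histologic grade")
  }
  if (any(clinical$os_time < 0) || any(clinical$pfi_time < 0)) {
    stop("validation error: negative survival time")
  }
  invisible(clinical)
}

#' Write a clinical table
#' @param clinical Clinical `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  validate_clinical(clinical)
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a per-cell copy-number container
#'
#' Bundles CopyKat-like per-cell copy-number estimates over genomic windows
#' with per-cell metadata (cell type and raw MYC count). Regions must be
#' sorted and non-overlapping within a chromosome; MYC counts must be
#' non-negative integers.
#'
#' @param regions `data.frame` with `chrom`, `start`, `end` (1-based closed).
#' @param cn Numeric matrix, rows = regions, columns = cells (log-ratio
#'   copy-number estimates).
#' @param cell_meta `data.frame` with `cell_id`, `cell_type`, `myc_count`.
#' @return An object of class `cell_cn`.
#' @export
cell_cn <- function(regions, cn, cell_meta) {
  stopifnot(is.data.frame(regions), is.matrix(cn), is.data.frame(cell_meta))
  regions$chrom <- normalize_chrom(regions$chrom)
  if (nrow(regions) != nrow(cn)) stop("regions/cn row mismatch")
  if (nrow(cell_meta) != ncol(cn)) stop("cell_meta/cn column mismatch")
  if (is.null(colnames(cn))) colnames(cn) <- cell_meta$cell_id
  if (!identical(colnames(cn), as.character(cell_meta$cell_id))) {
    stop("validation error: cell ids of cn matrix and metadata differ")
  }
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    if (is.unsorted(r$start)) stop("regions not sorted within ", ch)
    if (nrow(r) > 1 && any(r$start[-1] <= r$end[-nrow(r)])) {
      stop("validation error: overlapping regions within ", ch)
    }
  }
  mc <- cell_meta$myc_count
  if (any(mc < 0) || any(mc != round(mc))) {
    stop("validation error: myc_count must be non-negative integers")
  }
  structure(list(regions = regions, cn = cn,
                 cell_meta = data.frame(cell_id = as.character(cell_meta$cell_id),
                                        cell_type = as.character(cell_meta$cell_type),
                                        myc_count = as.integer(mc),
                                        stringsAsFactors = FALSE)),
            class = "cell_cn")
}

#' @export
print.cell_cn <- function(x, ...) {
  cat("cell_cn:", nrow(x$regions), "regions x", ncol(x$cn), "cells\n")
  cat("cell types:", paste(names(table(x$cell_meta$cell_type)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.cell_cn <- function(x) dim(x$cn)

#' Subset a cell_cn object by cell
#' @param x `cell_cn` object.
#' @param cells Logical, integer or character index over cells.
#' @return `cell_cn` restricted to those cells.
#' @export
subset_cells <- function(x, cells) {
  stopifnot(inherits(x, "cell_cn"))
  if (is.character(cells)) cells <- match(cells, x$cell_meta$cell_id)
  cell_cn(x$regions, x$cn[, cells, drop = FALSE],
          x$cell_meta[cells, , drop = FALSE])
}

#' Read a per-cell copy-number matrix with metadata
#'
#' The CN file is a TSV whose rows are genomic windows (`chrom`, `start`,
#' `end`, then one column per cell); the metadata TSV has columns `cell_id`,
#' `cell_type`, `myc_count`. The two files must describe exactly the same
#' cells; metadata rows are aligned to the CN column order.
#'
#' @param path_cn Path to the CN TSV.
#' @param path_meta Path to the cell metadata TSV.
#' @return A [cell_cn()] object.
#' @export
read_cell_cn <- function(path_cn, path_meta) {
  cn_df <- .read_tsv(path_cn)
  .check_header(cn_df, c("chrom", "start", "end"), path_cn)
  meta <- .read_tsv(path_meta)
  .check_header(meta, c("cell_id", "cell_type", "myc_count"), path_meta)
  regions <- data.frame(chrom = normalize_chrom(cn_df$chrom),
                        start = .num_col(cn_df$start, "start", path_cn),
                        end = .num_col(cn_df$end, "end", path_cn),
                        stringsAsFactors = FALSE)
  cn <- as.matrix(cn_df[, -(1:3), drop = FALSE])
  storage.mode(cn) <- "double"
  ids_cn <- colnames(cn)
  ids_meta <- as.character(meta$cell_id)
  missing_meta <- setdiff(ids_cn, ids_meta)
  missing_cn <- setdiff(ids_meta, ids_cn)
  if (length(missing_meta) || length(missing_cn)) {
    stop("validation error: cell-id mismatch between files; ",
         if (length(missing_meta)) paste0("missing from metadata: ",
           paste(missing_meta, collapse = ", "), "; ") else "",
         if (length(missing_cn)) paste0("missing from CN matrix: ",
           paste(missing_cn, collapse = ", ")) else "")
  }
  meta <- meta[match(ids_cn, ids_meta), , drop = FALSE]
  cell_cn(regions, cn, meta)
}

#' Write a per-cell copy-number matrix with metadata
#' @param x A [cell_cn()] object.
#' @param path_cn Output path for the CN TSV.
#' @param path_meta Output path for the metadata TSV.
#' @return `c(path_cn, path_meta)`, invisibly.
#' @export
write_cell_cn <- function(x, path_cn, path_meta) {
  stopifnot(inherits(x, "cell_cn"))
  df <- data.frame(x$regions, x$cn, check.names = FALSE)
  utils::write.table(df, path_cn, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$cell_meta, path_meta, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path_cn, path_meta))
}
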