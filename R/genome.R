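#' @keywords internal
"_PACKAGE"

# Recognized chromosome names after normalization ("chr" prefix).
.known_chroms <- paste0("chr", c(1:22, "X", "Y", "M"))

#' Normalize chromosome names to "chrN" form
#'
#' Adds a `"chr"` prefix where missing and maps `"MT"` to `"chrM"`. The
#' operation is idempotent. Unrecognized names raise an error.
#'
#' @param x Character vector of chromosome names (e.g. `"19"`, `"chr19"`).
#' @return Character vector of normalized names.
#' @examples
#' normalize_chrom(c("19", "chr8", "MT"))
#' @export
normalize_chrom <- function(x) {
  x <- as.character(x)
  if (length(x) == 0) return(character(0))
  x <- sub("^chr", "", x)
  x[x == "MT"] <- "M"
  out <- paste0("chr", x)
  bad <- !(out %in% .known_chroms)
  if (any(bad)) {
    stop("unknown chromosome name(s): ",
         paste(unique(x[bad]), collapse = ", "))
  }
  out
}

#' Miniature two-chromosome reference genome
#'
#' Chromosome sizes and p-arm boundaries for the synthetic genome used by the
#' data generator and, by default, by the instability metrics. Coordinates are
#' 1-based and fully closed, the convention used throughout the package.
#' `p_end` is the last base of the p arm; the q arm spans `p_end + 1 .. length`.
#'
#' @param chroms Character vector of chromosome names to include.
#' @param lengths Integer vector of chromosome lengths in bp.
#' @param p_ends Integer vector, last base of each p arm.
#' @return A `data.frame` with columns `chrom`, `length`, `p_end`.
#' @examples
#' toy_genome()
#' @export
toy_genome <- function(chroms = c("chr8", "chr19"),
                       lengths = c(145e6, 59e6),
                       p_ends = c(45e6, 26e6)) {
  stopifnot(length(chroms) == length(lengths),
            length(chroms) == length(p_ends),
            all(p_ends > 0), all(p_ends < lengths))
  data.frame(chrom = normalize_chrom(chroms),
             length = as.numeric(lengths),
             p_end = as.numeric(p_ends),
             stringsAsFactors = FALSE)
}

# GRanges from a data.frame with chrom/start/end columns (1-based closed,
# which is the native GRanges convention).
.as_granges <- function(df, chrom = "chrom", start = "start", end = "end") {
  GenomicRanges::GRanges(
    seqnames = as.character(df[[chrom]]),
    ranges = IRanges::IRanges(start = as.numeric(df[[start]]),
                              end = as.numeric(df[[end]]))
  )
}

# findOverlaps without the "no sequence levels in common" warning (disjoint
# chromosome sets are a legitimate no-overlap case here).
.fo <- function(a, b) {
  suppressWarnings(GenomicRanges::findOverlaps(a, b))
}

# Intersection of two GRanges written out explicitly (overlap + pairwise
# intersection + merge) so the package controls the semantics.
.gr_intersect <- function(a, b) {
  h <- .fo(a, b)
  if (length(h) == 0L) {
    return(GenomicRanges::GRanges())
  }
  p <- suppressWarnings(
    GenomicRanges::pintersect(a[S4Vectors::queryHits(h)],
                              b[S4Vectors::subjectHits(h)]))
  GenomicRanges::reduce(p)
}

.gr_to_df <- function(gr) {
  if (length(gr) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE))
  }
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$start), , drop = FALSE]
}
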