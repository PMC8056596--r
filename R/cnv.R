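# Genomic intervals: gene vs genomic-disorder region intersection, and
# filtering of proband CNVs to gene-focal events.

#' Build a genomic-interval table
#'
#' Internal convention: 0-based half-open `[start, end)`, `chr` prefixes
#' stripped. 1-based inclusive input (tabular clinical coordinates) is
#' converted via `dialect = "onebased"`.
#'
#' @param chrom chromosome names.
#' @param start,end coordinates per `dialect`.
#' @param name interval names.
#' @param haploinsufficient optional logical flag per interval.
#' @param dialect `"bed"` (0-based half-open, default) or `"onebased"`
#'   (1-based inclusive).
#' @return data.frame of normalized intervals.
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL,
                              haploinsufficient = NULL,
                              dialect = c("bed", "onebased")) {
  dialect <- match.arg(dialect)
  if (dialect == "onebased") {
    start <- start - 1L
  }
  bad <- which(!(start < end))
  if (length(bad) > 0)
    stop("malformed interval (start >= end) at record(s): ",
         paste(if (!is.null(name)) name[bad] else bad, collapse = ", "))
  data.frame(chrom = sub("^chr", "", as.character(chrom)),
             start = as.integer(start), end = as.integer(end),
             name = name %||% paste0("iv", seq_along(chrom)),
             haploinsufficient = haploinsufficient %||%
               rep(NA, length(chrom)),
             stringsAsFactors = FALSE)
}

#' Read a BED file of intervals
#'
#' Plain 3-6 column BED (no track lines); name from column 4 when present.
#'
#' @param path BED file.
#' @return normalized interval data.frame (see [genomic_intervals()]).
#' @export
read_bed <- function(path) {
  b <- read.table(path, header = FALSE, sep = "\t",
                  stringsAsFactors = FALSE)
  genomic_intervals(b[[1]], b[[2]], b[[3]],
                    name = if (ncol(b) >= 4) b[[4]] else NULL,
                    dialect = "bed")
}

to_granges <- function(iv, seqlevels = unique(iv$chrom)) {
  GenomicRanges::GRanges(
    seqnames = factor(iv$chrom, levels = seqlevels),
    ranges = IRanges::IRanges(start = iv$start + 1L, end = iv$end),
    name = iv$name)
}

#' Intersect gene intervals with genomic-disorder regions
#'
#' Any-overlap join (at least one shared base by default; `containment =
#' TRUE` requires the whole gene inside the region) with overlap length
#' reported.
#'
#' @param genes,regions normalized interval data.frames
#'   ([genomic_intervals()] / [read_bed()]).
#' @param containment require whole-gene containment instead of any
#'   overlap.
#' @return data.frame: gene, region, chrom, overlap_bp.
#' @export
intersect_genes_regions <- function(genes, regions, containment = FALSE) {
  lv <- unique(c(genes$chrom, regions$chrom))
  gg <- to_granges(genes, lv)
  rr <- to_granges(regions, lv)
  ty <- if (containment) "within" else "any"
  hits <- GenomicRanges::findOverlaps(gg, rr, type = ty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::pintersect(gg[qi], rr[si])
  data.frame(gene = genes$name[qi], region = regions$name[si],
             chrom = genes$chrom[qi],
             overlap_bp = GenomicRanges::width(ov),
             stringsAsFactors = FALSE)
}

#' Filter proband CNVs to gene-focal events
#'
#' Keeps CNVs that overlap the target gene and whose other overlapped genes
#' are all flagged non-haploinsufficient: a deletion spanning only the
#' target (or dosage-insensitive neighbors) is informative about the
#' target, one removing a haploinsufficient neighbor is not. A neighbor
#' with a missing flag makes the CNV indeterminate; indeterminate CNVs are
#' excluded by default.
#'
#' @param cnvs CNV interval data.frame.
#' @param target_gene name of the target gene in `neighbor_genes`.
#' @param neighbor_genes interval data.frame including the target and its
#'   neighbors, with the `haploinsufficient` column filled for neighbors.
#' @param keep_indeterminate keep CNVs overlapping a neighbor with a
#'   missing flag (default FALSE).
#' @return list: `kept` (CNV names), `dropped` (data.frame with reasons).
#' @export
filter_focal_cnvs <- function(cnvs, target_gene, neighbor_genes,
                              keep_indeterminate = FALSE) {
  ov <- intersect_genes_regions(neighbor_genes, cnvs)
  kept <- character(0)
  dropped <- list()
  for (cn in cnvs$name) {
    genes_hit <- ov$gene[ov$region == cn]
    if (!target_gene %in% genes_hit) {
      dropped[[length(dropped) + 1]] <-
        data.frame(cnv = cn, reason = "does_not_overlap_target")
      next
    }
    others <- setdiff(genes_hit, target_gene)
    flags <- neighbor_genes$haploinsufficient[
      match(others, neighbor_genes$name)]
    if (any(!is.na(flags) & flags)) {
      dropped[[length(dropped) + 1]] <-
        data.frame(cnv = cn, reason = "haploinsufficient_neighbor")
    } else if (any(is.na(flags)) && !keep_indeterminate) {
      dropped[[length(dropped) + 1]] <-
        data.frame(cnv = cn, reason = "indeterminate_neighbor_flag")
    } else {
      kept <- c(kept, cn)
    }
  }
  list(kept = kept,
       dropped = if (length(dropped) > 0) do.call(rbind, dropped) else
         data.frame(cnv = character(0), reason = character(0)))
}
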