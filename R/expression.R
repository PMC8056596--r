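# Expression analyses: cell-type enrichment (Wilcoxon), fold-change
# Z-scores, expression-profile correlations, region-set enrichment
# (Fisher + BH), family-vs-external comparisons.

#' Construct an expression matrix container
#'
#' @param values cells x genes numeric matrix (nonnegative, normalized
#'   units), with gene column names.
#' @param cell_type cell-type label per cell (length nrow(values)).
#' @return list of class `expression_matrix` with `values` and `cell_type`.
#' @export
expression_matrix <- function(values, cell_type) {
  values <- as.matrix(values)
  if (length(cell_type) != nrow(values))
    stop("one cell-type label required per cell")
  if (anyNA(cell_type)) stop("cell-type labels must not be missing")
  cell_type <- as.character(cell_type)
  if (length(unique(cell_type)) < 2) stop("need at least 2 cell types")
  structure(list(values = values, cell_type = cell_type),
            class = "expression_matrix")
}

#' Read an expression matrix from dense TSV or sparse triplets
#'
#' Dense: cells x genes TSV with header (gene names) and first column cell
#' ids. Sparse: a triplet TSV (`cell`, `gene`, `value`). Either way a
#' metadata TSV maps `cell` to `cell_type`.
#'
#' @param path matrix TSV.
#' @param metadata_path metadata TSV with columns `cell`, `cell_type`.
#' @param sparse is `path` a triplet file?
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, metadata_path, sparse = FALSE) {
  meta <- read.table(metadata_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  if (sparse) {
    tr <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    cells <- sort(unique(tr$cell))
    genes <- sort(unique(tr$gene))
    m <- matrix(0, length(cells), length(genes),
                dimnames = list(cells, genes))
    m[cbind(match(tr$cell, cells), match(tr$gene, genes))] <- tr$value
  } else {
    df <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                     stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(df)
  }
  expression_matrix(m, meta$cell_type[match(rownames(m), meta$cell)])
}

#' Cell-type enrichment of gene expression
#'
#' For each requested gene and cell type: two-sample Wilcoxon rank-sum test
#' of the gene's expression in cells of that type against all other cells,
#' fold change of means with pseudocount `eps`, and Bonferroni-corrected
#' q = min(1, p * n_types). All-zero (constant) genes are flagged with
#' undefined fold change and p = 1.
#'
#' @param m an [expression_matrix()].
#' @param genes gene names (default: all).
#' @param eps pseudocount for the fold change (default 1e-9).
#' @return data.frame: gene, cell_type, mean_in, mean_out, fold_change, p,
#'   q, undefined flag.
#' @export
celltype_enrichment <- function(m, genes = colnames(m$values), eps = 1e-9) {
  types <- sort(unique(m$cell_type))
  if (any(table(m$cell_type) < 2))
    stop("every cell type needs at least 2 cells")
  n_types <- length(types)
  out <- list()
  for (g in genes) {
    v <- m$values[, g]
    constant <- sd(v) == 0
    for (ty in types) {
      inside <- m$cell_type == ty
      if (constant) {
        p <- 1; fc <- NA_real_
      } else {
        p <- suppressWarnings(
          wilcox.test(v[inside], v[!inside], exact = FALSE)$p.value)
        if (is.na(p)) p <- 1 # all ranks tied
        fc <- (mean(v[inside]) + eps) / (mean(v[!inside]) + eps)
      }
      out[[length(out) + 1]] <- data.frame(
        gene = g, cell_type = ty, mean_in = mean(v[inside]),
        mean_out = mean(v[!inside]), fold_change = fc, p = p,
        q = min(1, p * n_types), undefined = constant,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fold-change Z-scores across cell types
#'
#' Z = (log2 fold change - mean) / SD across cell types for one gene: the
#' per-type deviation of expression enrichment from the gene's own average.
#' A zero-SD profile gives all-zero Z with a flag.
#'
#' @param enrichment_row data.frame of one gene's [celltype_enrichment()]
#'   rows (>= 3 cell types).
#' @return data.frame with `cell_type`, `log2_fc`, `z`; attribute
#'   `degenerate` when SD is zero.
#' @export
foldchange_z <- function(enrichment_row) {
  if (nrow(enrichment_row) < 3) stop("need at least 3 cell types")
  if (length(unique(enrichment_row$gene)) != 1)
    stop("rows must belong to a single gene")
  lfc <- log2(enrichment_row$fold_change)
  s <- sd(lfc)
  degenerate <- is.na(s) || s == 0
  z <- if (degenerate) rep(0, length(lfc)) else (lfc - mean(lfc)) / s
  out <- data.frame(cell_type = enrichment_row$cell_type, log2_fc = lfc,
                    z = z, stringsAsFactors = FALSE)
  attr(out, "degenerate") <- degenerate
  out
}

#' Mean expression profile per cell type
#'
#' @param m an [expression_matrix()].
#' @param genes gene names (default all).
#' @return genes x cell-types matrix of mean expression.
#' @export
type_profiles <- function(m, genes = colnames(m$values)) {
  types <- sort(unique(m$cell_type))
  prof <- vapply(types, function(ty)
    colMeans(m$values[m$cell_type == ty, genes, drop = FALSE]),
    numeric(length(genes)))
  if (length(genes) == 1)
    prof <- matrix(prof, nrow = 1, dimnames = list(genes, types))
  prof
}

#' Pairwise Pearson correlation of expression profiles
#'
#' Per-gene profiles are mean expression per cell type; pairwise Pearson R
#' with p-values corrected by a Bonferroni factor, by default n_genes *
#' n_types (the factor is configurable because different correction
#' conventions exist for profile correlations).
#'
#' @param m an [expression_matrix()].
#' @param genes gene names (>= 2).
#' @param correction_factor Bonferroni multiplier; default
#'   `length(genes) * n_types`.
#' @return list with `R` (correlation matrix), `p` (corrected p matrix),
#'   `profiles`; constant profiles give NA entries, listed in attribute
#'   `undefined` of `R`.
#' @export
expression_correlation <- function(m, genes = colnames(m$values),
                                   correction_factor = NULL) {
  prof <- type_profiles(m, genes)
  n_types <- ncol(prof)
  if (is.null(correction_factor))
    correction_factor <- length(genes) * n_types
  n <- length(genes)
  R <- matrix(1, n, n, dimnames = list(genes, genes))
  P <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
  undefined <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      xi <- prof[i, ]; xj <- prof[j, ]
      if (sd(xi) == 0 || sd(xj) == 0) {
        R[i, j] <- R[j, i] <- NA_real_
        undefined <- c(undefined, paste(genes[i], genes[j], sep = ":"))
        next
      }
      ct <- cor.test(xi, xj)
      R[i, j] <- R[j, i] <- unname(ct$estimate)
      P[i, j] <- P[j, i] <- min(1, ct$p.value * correction_factor)
    }
  }
  attr(R, "undefined") <- undefined
  list(R = R, p = P, profiles = prof)
}

#' Region-set enrichment of a gene set (Fisher + BH)
#'
#' One-sided Fisher exact test (enrichment) of the overlap between the
#' query gene set and each named region gene set against the background
#' universe, with Benjamini-Hochberg correction across all region sets.
#'
#' @param gene_set query genes (subset of `universe`).
#' @param regions named list of gene sets (e.g. brain region x
#'   developmental window).
#' @param universe background gene universe.
#' @return data.frame: region, overlap, set_size, p, q.
#' @export
region_enrichment <- function(gene_set, regions, universe) {
  if (length(universe) == 0) stop("empty gene universe")
  if (!all(gene_set %in% universe))
    stop("gene_set must be a subset of the universe")
  rows <- lapply(names(regions), function(rn) {
    rs <- intersect(regions[[rn]], universe)
    a <- length(intersect(gene_set, rs))
    b <- length(setdiff(gene_set, rs))
    c_ <- length(setdiff(rs, gene_set))
    d <- length(universe) - a - b - c_
    p <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                     alternative = "greater")$p.value
    data.frame(region = rn, overlap = a, set_size = length(rs), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out
}

#' Within-family vs external expression similarity
#'
#' For each family gene, its mean profile correlation to the other family
#' genes is compared with its mean correlation to external (non-family)
#' genes; paired one-sided t-test with alternative within > between.
#'
#' @param m an [expression_matrix()].
#' @param family_genes,external_genes disjoint gene sets (each >= 2).
#' @return list: per-gene data.frame (`within_r`, `external_r`), `t`, `p`.
#' @export
family_vs_external <- function(m, family_genes, external_genes) {
  if (length(intersect(family_genes, external_genes)) > 0)
    stop("family and external gene sets must be disjoint")
  if (length(family_genes) < 2 || length(external_genes) < 2)
    stop("both gene sets need at least 2 genes")
  all_genes <- c(family_genes, external_genes)
  R <- expression_correlation(m, all_genes)$R
  per <- data.frame(
    gene = family_genes,
    within_r = vapply(family_genes, function(g)
      mean(R[g, setdiff(family_genes, g)]), numeric(1)),
    external_r = vapply(family_genes, function(g)
      mean(R[g, external_genes]), numeric(1)),
    stringsAsFactors = FALSE)
  tt <- t.test(per$within_r, per$external_r, paired = TRUE,
               alternative = "greater")
  list(per_gene = per, t = unname(tt$statistic), p = tt$p.value)
}

#' Two-way ANOVA on a long-format expression table
#'
#' Generic groups x tissues comparison (e.g. gene-group by tissue for
#' adult-tissue expression): `value ~ group * tissue`.
#'
#' @param long data.frame with columns `value`, `group`, `tissue`.
#' @return ANOVA table (data.frame) with terms, df, F and p.
#' @export
expression_anova <- function(long) {
  fit <- aov(value ~ group * tissue, data = long)
  s <- summary(fit)[[1]]
  data.frame(term = trimws(rownames(s)), df = s$Df, F = s$`F value`,
             p = s$`Pr(>F)`, stringsAsFactors = FALSE)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (name, description, genes... per tab-separated
#'   line).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1], "")
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(n)
    paste(c(n, "na", sets[[n]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
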