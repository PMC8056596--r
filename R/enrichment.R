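# De novo burden testing: expected counts from per-gene mutation-rate
# models, exact Poisson upper tails, family-wise error correction, tiers.

#' Expected de novo count under a mutation-rate model
#'
#' lambda = 2 * n_trios * mu: each trio contributes two haploid genomes at
#' per-haploid per-generation rate mu.
#'
#' @param mu per-gene, per-class mutation rate (vectorised, >= 0).
#' @param n_trios number of parent-child trios.
#' @return expected count lambda.
#' @export
expected_count <- function(mu, n_trios) {
  if (any(is.na(mu)) || any(mu < 0)) stop("mutation rates must be >= 0")
  if (n_trios <= 0) stop("n_trios must be positive")
  2 * n_trios * mu
}

#' Exact Poisson upper-tail probability
#'
#' p = P(X >= o) for X ~ Poisson(lambda), computed with the exact survival
#' function (no normal approximation; lambda is often far below 1 for
#' per-gene de novo expectations). o = 0 gives p = 1.
#'
#' @param o observed count (vectorised, >= 0).
#' @param lambda expected count (>= 0, recycled).
#' @return upper-tail probability in (0, 1\].
#' @export
poisson_upper_p <- function(o, lambda) {
  if (any(o < 0)) stop("observed counts must be >= 0")
  if (any(lambda < 0)) stop("lambda must be >= 0")
  ppois(o - 1, lambda, lower.tail = FALSE)
}

#' Family-wise error threshold over genes, classes and models
#'
#' Bonferroni threshold alpha / (G * n_classes * n_models): each gene is
#' tested for n_classes mutation classes under n_models rate models.
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_genes number of genes in the rate model.
#' @param n_classes tests per gene (default 3: LGD, missense, all protein).
#' @param n_models rate models per class (default 2).
#' @return significance threshold.
#' @export
fwer_threshold <- function(alpha = 0.05, n_genes, n_classes = 3,
                           n_models = 2) {
  if (alpha <= 0 || n_genes <= 0 || n_classes <= 0 || n_models <= 0)
    stop("alpha and all multiplicities must be positive")
  alpha / (n_genes * n_classes * n_models)
}

#' Build a mutation-rate table
#'
#' @param gene gene names.
#' @param mu_lgd,mu_missense per-class per-haploid rates; `mu_protein`
#'   defaults to their sum when not supplied.
#' @param model_name label for the model.
#' @param n_genes_model size of the gene universe the model was fit on
#'   (used for the family-wise threshold); defaults to `length(gene)`.
#' @return data.frame with attributes `model_name`, `n_genes_model`.
#' @export
rate_table <- function(gene, mu_lgd, mu_missense, mu_protein = NULL,
                       model_name = "model", n_genes_model = length(gene)) {
  if (any(c(mu_lgd, mu_missense) < 0)) stop("rates must be >= 0")
  if (is.null(mu_protein)) mu_protein <- mu_lgd + mu_missense
  if (any(mu_protein + 1e-15 < pmax(mu_lgd, mu_missense)))
    stop("mu_protein must be >= max(mu_lgd, mu_missense)")
  rt <- data.frame(gene = gene, mu_lgd = mu_lgd, mu_missense = mu_missense,
                   mu_protein = mu_protein, stringsAsFactors = FALSE)
  attr(rt, "model_name") <- model_name
  attr(rt, "n_genes_model") <- n_genes_model
  rt
}

#' Read a mutation-rate table from TSV
#'
#' Columns `gene`, `mu_lgd`, `mu_missense`, optional `mu_protein`.
#'
#' @param path TSV file.
#' @inheritParams rate_table
#' @export
read_rate_table <- function(path, model_name = basename(path),
                            n_genes_model = NULL) {
  rt <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  rate_table(rt$gene, rt$mu_lgd, rt$mu_missense, rt$mu_protein,
             model_name = model_name,
             n_genes_model = n_genes_model %||% nrow(rt))
}

count_denovo_by_class <- function(variants, genes = NULL) {
  v <- variants[variants$inheritance %in% c("de_novo", "mosaic"), ,
                drop = FALSE]
  if (is.null(genes)) genes <- sort(unique(v$gene))
  o_lgd <- as.integer(table(factor(v$gene[v$variant_class == "LGD"],
                                   levels = genes)))
  o_mis <- as.integer(table(
    factor(v$gene[v$variant_class %in% c("MIS20", "MIS30")],
           levels = genes)))
  data.frame(gene = genes, LGD = o_lgd, missense = o_mis,
             protein = o_lgd + o_mis, stringsAsFactors = FALSE)
}

#' Per-gene de novo enrichment under one or more rate models
#'
#' For every gene x mutation class (LGD, severe missense, all protein
#' changes) x rate model: the observed de novo count o (mosaic counted as
#' de novo; missense restricted to CADD >= 20 tiers), the expected count
#' lambda = 2 * n_trios * mu, the exact Poisson upper-tail p, and a
#' significance tier. `exome_wide` uses strict p < alpha / (G * n_classes *
#' n_models) with G the model's gene universe; `nominal` is p < alpha.
#' The protein-class observed count is LGD + missense; its rate comes from
#' the table's `mu_protein` column. Genes absent from a rate table are
#' flagged and skipped for that model.
#'
#' @param variants classified variant data.frame (needs `gene`,
#'   `variant_class`, `inheritance`).
#' @param rate_tables list of [rate_table()]s (typically two models).
#' @param n_trios trio cohort size.
#' @param alpha family-wise error rate (default 0.05).
#' @param n_models_correction number of models in the correction factor;
#'   defaults to `length(rate_tables)`.
#' @param genes genes to test: default the genes carrying de novo variants;
#'   `"all"` tests every rate-table gene (zero-count genes get p = 1, as a
#'   null simulation requires); or an explicit character vector.
#' @return data.frame: gene, class, model, observed, expected, p, threshold,
#'   tier; attribute `skipped` lists gene/model pairs missing rates.
#' @export
run_enrichment <- function(variants, rate_tables, n_trios, alpha = 0.05,
                           n_models_correction = length(rate_tables),
                           genes = NULL) {
  if (!is.list(rate_tables) || is.data.frame(rate_tables))
    rate_tables <- list(rate_tables)
  if (identical(genes, "all"))
    genes <- sort(unique(unlist(lapply(rate_tables, `[[`, "gene"))))
  obs <- count_denovo_by_class(variants, genes)
  mu_col <- c(LGD = "mu_lgd", missense = "mu_missense",
              protein = "mu_protein")
  out <- list()
  skipped <- character(0)
  for (rt in rate_tables) {
    model <- attr(rt, "model_name") %||% "model"
    thr <- fwer_threshold(alpha, attr(rt, "n_genes_model") %||% nrow(rt),
                          n_classes = 3, n_models = n_models_correction)
    idx <- match(obs$gene, rt$gene)
    absent <- is.na(idx)
    if (any(absent))
      skipped <- c(skipped, paste(obs$gene[absent], model, sep = "/"))
    og <- obs[!absent, , drop = FALSE]
    ri <- idx[!absent]
    if (nrow(og) == 0) next
    for (cl in c("LGD", "missense", "protein")) {
      o <- og[[cl]]
      lam <- expected_count(rt[[mu_col[[cl]]]][ri], n_trios)
      p <- poisson_upper_p(o, lam)
      tier <- ifelse(p < thr, "exome_wide",
                     ifelse(p < alpha, "nominal", "none"))
      out[[length(out) + 1]] <- data.frame(
        gene = og$gene, class = cl, model = model, observed = o,
        expected = lam, p = p, threshold = thr, tier = tier,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(gene = character(0), class = character(0),
               model = character(0), observed = integer(0),
               expected = numeric(0), p = numeric(0), threshold = numeric(0),
               tier = character(0))
  rownames(res) <- NULL
  attr(res, "skipped") <- unique(skipped)
  res
}
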