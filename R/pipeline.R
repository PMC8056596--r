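# Orchestration: configuration and an end-to-end pipeline over synthetic
# or user-supplied inputs, writing plain TSV tables and a JSON summary.

#' Default pipeline configuration
#'
#' Thresholds mirror the analysis defaults: CADD tiers 20/30,
#' characteristic-phenotype cutoff tau = 0.20, alpha = 0.05, homology /
#' phenotype concordance cut R = 0.5. Per-stage seeds are derived from the
#' single `seed` by fixed offsets so stages can be regenerated
#' independently.
#'
#' @param seed master seed.
#' @param out_dir output directory.
#' @param n_trios trio-cohort size for the burden stage.
#' @param n_genes number of synthetic genes in the rate model.
#' @param spike_gene,spike_multiplier planted enrichment (NULL disables).
#' @param min_probands candidate-gene rule.
#' @param tau characteristic-phenotype threshold.
#' @param alpha family-wise error rate.
#' @param r_cut homology-concordance threshold.
#' @return named list.
#' @export
pipeline_config <- function(seed = 1, out_dir = tempfile("famburden_"),
                            n_trios = 5000, n_genes = 200,
                            spike_gene = "g0001", spike_multiplier = 50,
                            min_probands = 3, tau = 0.20, alpha = 0.05,
                            r_cut = 0.5) {
  list(seed = seed, out_dir = out_dir, n_trios = n_trios,
       n_genes = n_genes, spike_gene = spike_gene,
       spike_multiplier = spike_multiplier, min_probands = min_probands,
       tau = tau, alpha = alpha, r_cut = r_cut,
       rate_tables = NULL, variants = NULL)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the end-to-end analysis pipeline
#'
#' Stages: simulate (or load) inputs; ingest and classify variants; select
#' candidate genes; de novo burden under two rate models; missense
#' clustering of the spiked gene; protein-family homology grouping;
#' phenotype frequencies, characteristic filter and correlations; report.
#' Deterministic given the config seed. Outputs are TSV tables plus a
#' machine-readable JSON summary in `out_dir`.
#'
#' @param config a [pipeline_config()] list. Supply `config$variants` and
#'   `config$rate_tables` to run on user data instead of simulating;
#'   `rate_tables` must then be a non-empty list of [rate_table()]s.
#' @return invisibly, a list with the per-stage results and output paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  rates <- stage("rates", {
    if (!is.null(cfg$rate_tables)) {
      if (!is.list(cfg$rate_tables) || length(cfg$rate_tables) == 0)
        stop("rate_tables must be a non-empty list of rate tables")
      cfg$rate_tables
    } else {
      base <- sim_rate_table(cfg$n_genes, seed = cfg$seed,
                             model_name = "modelA")
      list(base,
           sim_rate_table(seed = cfg$seed + 1000L, model_name = "modelB",
                          jitter_sd = 0.05, base = base))
    }
  })

  variants <- stage("ingest", {
    if (!is.null(cfg$variants)) {
      v <- cfg$variants
      if (is.null(v$variant_class))
        v$variant_class <- classify_variant(v$consequence, v$cadd)
      v
    } else {
      mult <- if (is.null(cfg$spike_gene)) NULL else
        setNames(cfg$spike_multiplier, cfg$spike_gene)
      gen_dnv_cohort(rates[[1]], cfg$n_trios, multipliers = mult,
                     seed = cfg$seed + 2000L)
    }
  })

  inh_table <- stage("inheritance", tabulate_inheritance(variants))
  candidates <- stage("candidates",
                      select_candidate_genes(variants, cfg$min_probands))
  burden <- stage("burden",
                  run_enrichment(variants, rates, cfg$n_trios, cfg$alpha))

  clump <- stage("clump", {
    L <- 400
    case <- gen_positions(L, 20, sigma = 0.01 * L, weight = 0.8,
                          seed = cfg$seed + 3000L, gene = "spike",
                          cohort = "case")
    ctrl <- gen_positions(L, 160, weight = 0, seed = cfg$seed + 3001L,
                          gene = "spike", cohort = "control")
    case_control_permutation(case, ctrl, n_perm = 1000, seed = cfg$seed +
                               3002L)
  })

  homology <- stage("homology", {
    seqs <- gen_protein_family(3, 5, seed = cfg$seed + 4000L)
    idm <- pairwise_identity(seqs)
    grp <- cluster_groups(profile_correlation(idm), k = 3)
    list(identity = idm, groups = grp)
  })

  pheno <- stage("phenotype", {
    terms <- sprintf("term%02d", 1:20)
    m <- gen_phenotype_cohorts(
      cohort_sizes = setNames(rep(25L, 6), sprintf("gene%d", 1:6)),
      base = setNames(runif(20, 0.1, 0.7), terms), w = 0.7,
      seed = cfg$seed + 5000L)
    retained <- characteristic_filter(m, cfg$tau)
    list(matrix = m, retained = retained,
         frequencies = cohort_frequencies(m, retained),
         correlation = phenotype_correlation(m, retained))
  })

  paths <- stage("report", {
    p <- list(
      inheritance = file.path(cfg$out_dir, "inheritance_table.tsv"),
      burden = file.path(cfg$out_dir, "burden.tsv"),
      candidates = file.path(cfg$out_dir, "candidates.tsv"),
      frequencies = file.path(cfg$out_dir, "phenotype_frequencies.tsv"),
      summary = file.path(cfg$out_dir, "summary.json"))
    write.table(data.frame(class = rownames(inh_table), inh_table),
                p$inheritance, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(burden, p$burden, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(gene = candidates), p$candidates, sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(pheno$frequencies, p$frequencies, sep = "\t",
                quote = FALSE, row.names = FALSE)
    top <- burden[burden$class == "protein", ]
    top <- top[order(top$p), ]
    summary <- list(
      seed = cfg$seed,
      config = cfg[c("n_trios", "n_genes", "spike_gene",
                     "spike_multiplier", "min_probands", "tau", "alpha",
                     "r_cut")],
      n_variants = nrow(variants),
      n_candidates = length(candidates),
      candidates = candidates,
      top_burden_gene = if (nrow(top) > 0) top$gene[1] else NA,
      exome_wide_genes = sort(unique(burden$gene[burden$tier ==
                                                   "exome_wide"])),
      clump_p = clump$p,
      homology_n_groups = homology$groups$n_groups,
      n_retained_phenotypes = length(pheno$retained))
    jsonlite::write_json(summary, p$summary, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    p
  })

  invisible(list(config = cfg, rates = rates, variants = variants,
                 inheritance = inh_table, candidates = candidates,
                 burden = burden, clump = clump, homology = homology,
                 phenotype = pheno, paths = paths))
}
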