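# Synthetic-data generators: every pipeline input with known ground truth,
# reproducible from a single integer seed. Stream-splitting: the pipeline
# derives per-stage seeds as seed + fixed offsets, so any stage can be
# regenerated independently.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

#' Generate a synthetic per-gene mutation-rate table
#'
#' Per-class per-haploid rates drawn uniformly on `mu_range` (defaults span
#' typical per-gene coding de novo rates); `mu_protein` is the sum. An
#' optional multiplicative jitter emulates a second, independently fitted
#' rate model for the same genes.
#'
#' @param n_genes number of genes.
#' @param seed RNG seed.
#' @param mu_range range of per-class rates (default 1e-6 to 1e-5).
#' @param model_name label.
#' @param jitter_sd lognormal SD of per-gene rate jitter (default 0: none).
#' @param base optional [rate_table()] to jitter instead of drawing anew.
#' @return a [rate_table()] with genes `g0001`, ...
#' @export
sim_rate_table <- function(n_genes = 1000, seed = 1,
                           mu_range = c(1e-6, 1e-5),
                           model_name = "synthetic", jitter_sd = 0,
                           base = NULL) {
  set.seed(seed)
  if (is.null(base)) {
    genes <- sprintf("g%04d", seq_len(n_genes))
    mu_lgd <- runif(n_genes, mu_range[1], mu_range[2])
    mu_mis <- runif(n_genes, mu_range[1], mu_range[2])
  } else {
    genes <- base$gene
    mu_lgd <- base$mu_lgd
    mu_mis <- base$mu_missense
    n_genes <- length(genes)
  }
  if (jitter_sd > 0) {
    mu_lgd <- mu_lgd * exp(rnorm(n_genes, 0, jitter_sd))
    mu_mis <- mu_mis * exp(rnorm(n_genes, 0, jitter_sd))
  }
  rate_table(genes, mu_lgd, mu_mis, model_name = model_name,
             n_genes_model = n_genes)
}

#' Simulate a trio cohort's de novo variant table
#'
#' Per gene and class, the de novo count is Poisson with mean
#' 2 * n_trios * mu * multiplier. Counts are expanded to variant records:
#' LGD consequences drawn from the gene-disruptive set, missense CADD drawn
#' uniformly on \[20, 40\] (severe missense by construction), inheritance
#' de novo.
#'
#' @param rates a [rate_table()] giving the true per-gene rates.
#' @param n_trios cohort size.
#' @param multipliers named per-gene enrichment multipliers (default 1 for
#'   all genes); applied to both classes.
#' @param seed RNG seed.
#' @return data.frame of variant records (possibly 0 rows).
#' @export
gen_dnv_cohort <- function(rates, n_trios, multipliers = NULL, seed = 1) {
  set.seed(seed)
  mult <- setNames(rep(1, nrow(rates)), rates$gene)
  if (!is.null(multipliers)) mult[names(multipliers)] <- multipliers
  out <- list()
  pid <- 0
  for (i in seq_len(nrow(rates))) {
    g <- rates$gene[i]
    n_lgd <- rpois(1, expected_count(rates$mu_lgd[i] * mult[g], n_trios))
    n_mis <- rpois(1, expected_count(rates$mu_missense[i] * mult[g],
                                     n_trios))
    if (n_lgd + n_mis == 0) next
    cons <- c(sample(LGD_CONSEQUENCES, n_lgd, replace = TRUE),
              rep("missense", n_mis))
    cadd <- c(rep(NA_real_, n_lgd), runif(n_mis, 20, 40))
    out[[length(out) + 1]] <- data.frame(
      proband_id = sprintf("sim%06d", pid + seq_len(n_lgd + n_mis)),
      gene = g, cohort = "sim", position = NA_integer_,
      consequence = cons, cadd = cadd, inheritance = "de_novo",
      stringsAsFactors = FALSE)
    pid <- pid + n_lgd + n_mis
  }
  v <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(proband_id = character(0), gene = character(0),
               cohort = character(0), position = integer(0),
               consequence = character(0), cadd = numeric(0),
               inheritance = character(0))
  if (nrow(v) > 0) v$variant_class <- classify_variant(v$consequence, v$cadd)
  attr(v, "seed") <- seed
  v
}

#' Simulate missense positions from a uniform/hotspot mixture
#'
#' Each position comes from the hotspot (normal around `center` with SD
#' `sigma`, rounded and clamped to \[1, L\]) with probability `weight`, and
#' from the discrete uniform on \[1, L\] otherwise.
#'
#' @param L protein length.
#' @param m number of positions (>= 1).
#' @param center hotspot center (default L / 2).
#' @param sigma hotspot SD in residues (default 0.01 * L).
#' @param weight hotspot mixture weight in \[0, 1\].
#' @param seed RNG seed.
#' @param ... passed to [position_set()] (gene, cohort, blacklist...).
#' @return a [position_set()].
#' @export
gen_positions <- function(L, m, center = L / 2, sigma = 0.01 * L,
                          weight = 0, seed = 1, ...) {
  if (m < 1) stop("m must be >= 1")
  if (weight < 0 || weight > 1) stop("weight must lie in [0, 1]")
  set.seed(seed)
  hot <- runif(m) < weight
  pos <- integer(m)
  pos[!hot] <- sample.int(L, sum(!hot), replace = TRUE)
  pos[hot] <- pmin(L, pmax(1L, as.integer(round(
    rnorm(sum(hot), center, sigma)))))
  position_set(pos, L, ...)
}

#' Simulate a cells x genes expression matrix with planted markers
#'
#' Lognormal base expression per gene; cells of an enriched type have the
#' gene's values multiplied by `fold`.
#'
#' @param n_types number of cell types.
#' @param cells_per_type cells per type.
#' @param genes gene names.
#' @param meanlog,sdlog lognormal base parameters (defaults 0 and 0.5).
#' @param enriched named list: gene -> character vector of enriched types
#'   (types are labelled `type01`, ...).
#' @param fold enrichment fold (default 5).
#' @param seed RNG seed.
#' @return an [expression_matrix()].
#' @export
gen_expression <- function(n_types = 8, cells_per_type = 200,
                           genes = sprintf("gene%02d", 1:10),
                           meanlog = 0, sdlog = 0.5, enriched = list(),
                           fold = 5, seed = 1) {
  set.seed(seed)
  types <- sprintf("type%02d", seq_len(n_types))
  cell_type <- rep(types, each = cells_per_type)
  n_cells <- length(cell_type)
  vals <- matrix(rlnorm(n_cells * length(genes), meanlog, sdlog),
                 n_cells, length(genes),
                 dimnames = list(sprintf("cell%05d", seq_len(n_cells)),
                                 genes))
  for (g in names(enriched)) {
    sel <- cell_type %in% enriched[[g]]
    vals[sel, g] <- vals[sel, g] * fold
  }
  expression_matrix(vals, cell_type)
}

#' Simulate proband x phenotype cohorts with planted profile sharing
#'
#' Status of term t for a proband in gene cohort g is Bernoulli with
#' success probability `w * base[t] + (1 - w) * gene_effect[g, t]`:
#' `w = 1` makes all cohorts share the base profile, `w = 0` makes them
#' independent. Missingness is applied uniformly at `missing_rate`.
#'
#' @param cohort_sizes named integer vector (gene -> probands).
#' @param base base prevalence per term (named vector; names become terms).
#' @param gene_effects cohort x term matrix of cohort-specific
#'   prevalences; drawn uniform on \[0.05, 0.6\] when NULL.
#' @param w shared-profile weight in \[0, 1\].
#' @param missing_rate fraction of entries set missing (default 0).
#' @param mutation_class_prob probability a proband is labelled LGD
#'   (vs missense; default 0.6).
#' @param seed RNG seed.
#' @return a `phenotype_matrix` (see [build_matrix()]); attribute
#'   `true_prob` holds the cohort x term probability matrix.
#' @export
gen_phenotype_cohorts <- function(cohort_sizes, base, gene_effects = NULL,
                                  w = 0.5, missing_rate = 0,
                                  mutation_class_prob = 0.6, seed = 1) {
  if (w < 0 || w > 1) stop("w must lie in [0, 1]")
  set.seed(seed)
  cohorts <- names(cohort_sizes)
  terms <- names(base)
  if (is.null(gene_effects)) {
    gene_effects <- matrix(runif(length(cohorts) * length(terms), 0.05,
                                 0.6),
                           length(cohorts), length(terms),
                           dimnames = list(cohorts, terms))
  }
  prob <- sweep(gene_effects * (1 - w), 2, base * w, "+")
  ids <- character(0); coh <- character(0)
  status <- list()
  for (g in cohorts) {
    for (i in seq_len(cohort_sizes[[g]])) {
      id <- sprintf("%s_p%03d", g, i)
      ids <- c(ids, id); coh <- c(coh, g)
      pres <- rbinom(length(terms), 1, prob[g, ])
      st <- ifelse(pres == 1, "present", "absent")
      if (missing_rate > 0)
        st[runif(length(terms)) < missing_rate] <- "missing"
      status[[length(status) + 1]] <- data.frame(
        proband = id, term = terms, status = st, stringsAsFactors = FALSE)
    }
  }
  probands <- data.frame(
    proband = ids, cohort = coh,
    mutation_class = ifelse(runif(length(ids)) < mutation_class_prob,
                            "LGD", "missense"),
    stringsAsFactors = FALSE)
  m <- build_matrix(do.call(rbind, status), probands)
  attr(m, "true_prob") <- prob
  attr(m, "seed") <- seed
  m
}

#' Simulate protein families by mutation from group ancestors
#'
#' Each group gets a random ancestor sequence; members substitute each
#' residue independently with probability `sub_prob` (to a uniformly drawn
#' different residue). Between-group sequences are unrelated random
#' ancestors, so between-group identity sits near the random-alignment
#' baseline.
#'
#' @param n_groups number of families.
#' @param members_per_group members per family (recycled).
#' @param ancestor_length sequence length (default 120).
#' @param sub_prob per-residue substitution probability within a family
#'   (default 0.1, i.e. ~90\% within-family identity).
#' @param seed RNG seed.
#' @return named character vector of sequences; attribute `groups` holds
#'   the true group assignment.
#' @export
gen_protein_family <- function(n_groups = 3, members_per_group = 5,
                               ancestor_length = 120, sub_prob = 0.1,
                               seed = 1) {
  set.seed(seed)
  sizes <- rep_len(members_per_group, n_groups)
  seqs <- character(0)
  truth <- integer(0)
  for (g in seq_len(n_groups)) {
    anc <- sample(AA20, ancestor_length, replace = TRUE)
    for (j in seq_len(sizes[g])) {
      s <- anc
      mut <- runif(ancestor_length) < sub_prob
      if (any(mut)) {
        s[mut] <- vapply(s[mut], function(a)
          sample(setdiff(AA20, a), 1), "")
      }
      nm <- sprintf("grp%02d_seq%02d", g, j)
      seqs[nm] <- paste(s, collapse = "")
      truth[nm] <- g
    }
  }
  attr(seqs, "groups") <- truth
  attr(seqs, "seed") <- seed
  seqs
}
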