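# Missense position-clustering statistic (CLUMP-style): exact 1-D
# k-medoids score, case/control permutation test, phenotype-stratified
# runs, domain-overlap summaries.

#' Construct a position set
#'
#' Missense mutation positions (1-based residue coordinates, multiplicity
#' allowed: a recurrent residue is evidence of clustering) on a protein of
#' length `L`. Positions falling in `blacklist` intervals (e.g. exons with
#' inadequate control coverage) are dropped.
#'
#' @param positions integer residue positions.
#' @param L protein length.
#' @param gene gene label.
#' @param cohort `"case"` or `"control"`.
#' @param proband optional per-position proband ids (for phenotype
#'   stratification).
#' @param blacklist optional data.frame/matrix of `start`, `end` residue
#'   intervals (closed) to mask.
#' @return list of class `position_set`.
#' @export
position_set <- function(positions, L, gene = "gene",
                         cohort = c("case", "control"), proband = NULL,
                         blacklist = NULL) {
  cohort <- match.arg(cohort)
  if (length(positions) < 1) stop("empty position set")
  if (L < 1) stop("protein length must be >= 1")
  positions <- as.integer(round(positions))
  if (any(positions < 1 | positions > L))
    stop("positions must lie in [1, L]")
  if (!is.null(proband) && length(proband) != length(positions))
    stop("proband labels must match positions")
  if (!is.null(blacklist) && nrow(blacklist) > 0) {
    masked <- rep(FALSE, length(positions))
    for (i in seq_len(nrow(blacklist))) {
      masked <- masked | (positions >= blacklist[i, "start"] &
                            positions <= blacklist[i, "end"])
    }
    positions <- positions[!masked]
    if (!is.null(proband)) proband <- proband[!masked]
    if (length(positions) == 0) stop("all positions masked by blacklist")
  }
  structure(list(gene = gene, L = L, positions = positions,
                 cohort = cohort, proband = proband),
            class = "position_set")
}

#' Position-clustering score (exact 1-D k-medoids)
#'
#' Positions are normalized to x = position / L. An exact 1-D k-medoids
#' solution is computed for k = 1..min(k_max, m, #unique); k is selected by
#' maximum mean silhouette width over the induced partitions (k = 1 is the
#' baseline with silhouette 0, and is forced when m < 3; ties go to the
#' smallest k). The score S is the mean absolute distance of each position
#' to its nearest medoid: lower S means tighter clustering, S = 0 when all
#' positions coincide. S is invariant under shifting all positions by a
#' constant.
#'
#' @param ps a [position_set()] (or a list with `positions` and `L`).
#' @param k_max maximum number of medoids considered (default 3; pathogenic
#'   missense clustering concentrates in one or a few domains, and larger
#'   k overfits small position sets).
#' @return list with `S`, `k`, and per-k `costs` and `silhouettes`.
#' @export
clump_score <- function(ps, k_max = 3) {
  x <- ps$positions / ps$L
  res <- .clump_core(x, as.integer(k_max))
  # guard against floating-point noise around exact zero
  res$S <- max(0, res$S)
  res$costs <- pmax(0, res$costs)
  res[c("S", "k", "costs", "silhouettes")]
}

#' Case/control permutation test of clustering difference
#'
#' delta = S(control) - S(case); positive delta means the case positions
#' are more tightly clustered than controls. Positions are pooled and
#' re-split preserving group sizes `n_perm` times; one-sided p with the
#' +1 correction: p = (1 + #\{delta_perm >= delta_obs\}) / (1 + n_perm).
#' Seed the R RNG (`set.seed`) for reproducibility.
#'
#' @param case,control [position_set()]s for the same gene and length.
#' @param n_perm number of permutations (a warning flag is recorded below
#'   100).
#' @param k_max passed to the scorer.
#' @param seed optional integer seed applied via `set.seed` before
#'   permuting.
#' @return list with `delta`, `p`, `case_score`, `control_score`,
#'   `n_permutations`, `low_n_perm` flag.
#' @export
case_control_permutation <- function(case, control, n_perm = 1000,
                                     k_max = 3, seed = NULL) {
  if (case$L != control$L || !identical(case$gene, control$gene))
    stop("case and control sets must share gene and protein length")
  if (!is.null(seed)) set.seed(seed)
  res <- .clump_perm(case$positions / case$L, control$positions / control$L,
                     as.integer(n_perm), as.integer(k_max))
  list(gene = case$gene, delta = res$delta, p = res$p,
       case_score = res$case_score, control_score = res$control_score,
       n_permutations = n_perm, low_n_perm = n_perm < 100)
}

#' Paired family-level test of case vs control clustering scores
#'
#' Paired t-test on per-gene (case, control) score pairs, one-sided with
#' alternative case < control (cases more clustered).
#'
#' @param per_gene data.frame with columns `case_score`, `control_score`
#'   (one row per gene; >= 3 rows).
#' @return list with `t`, `p`, `df`, `mean_difference`, `degenerate` flag
#'   (all differences zero).
#' @export
family_paired_test <- function(per_gene) {
  if (nrow(per_gene) < 3) stop("need at least 3 gene pairs")
  d <- per_gene$case_score - per_gene$control_score
  if (all(d == 0) || sd(d) == 0) {
    return(list(t = NA_real_, p = NA_real_, df = NA_real_,
                mean_difference = mean(d), degenerate = TRUE))
  }
  tt <- t.test(per_gene$case_score, per_gene$control_score, paired = TRUE,
               alternative = "less")
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_difference = mean(d), degenerate = FALSE)
}

#' Phenotype-stratified clustering tests
#'
#' Restricts the case position set to positions whose probands carry a
#' phenotype term and reruns the permutation test against the full control
#' set. Strata with fewer than 2 case positions are skipped with a reason.
#'
#' @param case a [position_set()] with `proband` labels.
#' @param pheno_matrix proband x term matrix/data.frame of 0/1/NA.
#' @param terms phenotype term(s) to stratify on (default: all columns).
#' @param control control [position_set()].
#' @param ... passed to [case_control_permutation()].
#' @return named list per term: either the permutation result or a
#'   `skipped = TRUE` record with the reason.
#' @export
phenotype_stratified <- function(case, pheno_matrix, terms = NULL, control,
                                 ...) {
  if (is.null(case$proband)) stop("case position set lacks proband labels")
  if (is.null(terms)) terms <- colnames(pheno_matrix)
  out <- list()
  for (term in terms) {
    status <- pheno_matrix[case$proband, term]
    keep <- !is.na(status) & status == 1
    if (sum(keep) < 2) {
      out[[term]] <- list(skipped = TRUE,
                          reason = "fewer than 2 case positions in stratum",
                          n_positions = sum(keep))
      next
    }
    sub <- position_set(case$positions[keep], case$L, gene = case$gene,
                        cohort = "case", proband = case$proband[keep])
    out[[term]] <- c(case_control_permutation(sub, control, ...),
                     list(skipped = FALSE, n_positions = sum(keep)))
  }
  out
}

#' Fraction of positions inside protein domains
#'
#' Closed residue intervals; positions count with multiplicity. Reports the
#' fraction inside each named domain and inside the union of all domains.
#'
#' @param ps a [position_set()].
#' @param domains data.frame with `name`, `start`, `end` (1-based closed,
#'   within \[1, L\]).
#' @return list with per-domain named fractions and `union_fraction`.
#' @export
domain_overlap <- function(ps, domains) {
  m <- length(ps$positions)
  if (is.null(domains) || nrow(domains) == 0)
    return(list(per_domain = setNames(numeric(0), character(0)),
                union_fraction = 0))
  if (any(domains$start > domains$end))
    stop("inverted domain interval (start > end)")
  if (any(domains$start < 1 | domains$end > ps$L))
    stop("domain intervals must lie within [1, L]")
  inside_any <- rep(FALSE, m)
  per <- numeric(nrow(domains))
  for (i in seq_len(nrow(domains))) {
    inside <- ps$positions >= domains$start[i] &
      ps$positions <= domains$end[i]
    per[i] <- sum(inside) / m
    inside_any <- inside_any | inside
  }
  names(per) <- domains$name
  list(per_domain = per, union_fraction = sum(inside_any) / m)
}
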