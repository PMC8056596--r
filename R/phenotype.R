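# Phenotype-convergence analysis: proband x term matrices, the
# characteristic-phenotype filter, cohort frequencies, correlations,
# pairwise Fisher tests with layered Bonferroni, LGD-vs-missense
# contrasts, homology-phenotype concordance, shared-HPO comparisons.

#' Build a proband x phenotype binary matrix
#'
#' From a long table of term statuses (present / absent / missing) and
#' optional quantitative measurements mapped to terms via extreme
#' percentiles: a measurement at or below the 3rd percentile maps to the
#' `low_term`, at or above the 97th to the `high_term`; in between is
#' absent; a missing measurement stays missing (missing is never treated
#' as absent).
#'
#' @param statuses data.frame with `proband`, `term`,
#'   `status` in `c("present", "absent", "missing")`.
#' @param probands data.frame with `proband`, `cohort` (gene cohort) and
#'   optionally `mutation_class` (`"LGD"` / `"missense"`); every proband
#'   must carry a cohort label.
#' @param quantitative optional data.frame with `proband`, `percentile`,
#'   `low_term`, `high_term` rows.
#' @param low_cut,high_cut percentile cutoffs (defaults 3 and 97,
#'   inclusive).
#' @return a `phenotype_matrix`: list with `status` (probands x terms
#'   matrix of 1/0/NA), `cohort`, `mutation_class` (named vectors).
#' @export
build_matrix <- function(statuses, probands, quantitative = NULL,
                         low_cut = 3, high_cut = 97) {
  if (anyNA(probands$cohort) || any(probands$cohort == ""))
    stop("every proband needs a gene-cohort label")
  extra <- list()
  if (!is.null(quantitative) && nrow(quantitative) > 0) {
    for (i in seq_len(nrow(quantitative))) {
      q <- quantitative[i, ]
      if (is.na(q$percentile)) next # missing measurement: stays missing
      st_low <- if (q$percentile <= low_cut) "present" else "absent"
      st_high <- if (q$percentile >= high_cut) "present" else "absent"
      extra[[length(extra) + 1]] <- data.frame(
        proband = q$proband, term = c(q$low_term, q$high_term),
        status = c(st_low, st_high), stringsAsFactors = FALSE)
    }
  }
  statuses <- rbind(statuses[, c("proband", "term", "status")],
                    do.call(rbind, extra))
  bad <- setdiff(unique(statuses$status), c("present", "absent", "missing"))
  if (length(bad) > 0) stop("unknown status value(s): ",
                            paste(bad, collapse = ", "))
  ids <- probands$proband
  terms <- sort(unique(statuses$term))
  mat <- matrix(NA_real_, length(ids), length(terms),
                dimnames = list(ids, terms))
  known <- statuses[statuses$status != "missing", , drop = FALSE]
  known <- known[known$proband %in% ids, , drop = FALSE]
  mat[cbind(match(known$proband, ids), match(known$term, terms))] <-
    as.numeric(known$status == "present")
  mc <- probands$mutation_class %||% rep(NA_character_, length(ids))
  structure(list(status = mat,
                 cohort = setNames(as.character(probands$cohort), ids),
                 mutation_class = setNames(as.character(mc), ids)),
            class = "phenotype_matrix")
}

#' Per-cohort phenotype frequencies
#'
#' Counts per gene cohort x term using assessed (non-missing) probands only,
#' plus a pooled `all` row. Empty denominators give `NA` prevalence.
#'
#' @param m a `phenotype_matrix`.
#' @param terms term subset (default all).
#' @return data.frame: cohort, term, count_with, count_assessed, prevalence.
#' @export
cohort_frequencies <- function(m, terms = colnames(m$status)) {
  cohorts <- c(sort(unique(m$cohort)), "all")
  rows <- list()
  for (co in cohorts) {
    sel <- if (co == "all") rep(TRUE, nrow(m$status)) else m$cohort == co
    sub <- m$status[sel, terms, drop = FALSE]
    assessed <- colSums(!is.na(sub))
    with_ <- colSums(sub == 1, na.rm = TRUE)
    rows[[co]] <- data.frame(
      cohort = co, term = terms, count_with = unname(with_),
      count_assessed = unname(assessed),
      prevalence = unname(ifelse(assessed > 0, with_ / assessed, NA_real_)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Characteristic-phenotype filter
#'
#' Retains terms whose prevalence among assessed probands reaches `tau`
#' (boundary inclusive) in at least one gene cohort. Terms below the cutoff
#' everywhere are considered non-syndromic noise and dropped.
#'
#' @param m a `phenotype_matrix`.
#' @param tau prevalence threshold (default 0.20).
#' @return character vector of retained terms.
#' @export
characteristic_filter <- function(m, tau = 0.20) {
  fr <- cohort_frequencies(m)
  fr <- fr[fr$cohort != "all" & !is.na(fr$prevalence), , drop = FALSE]
  sort(unique(fr$term[fr$prevalence >= tau]))
}

#' Gene-cohort phenotype-profile correlations
#'
#' Pearson correlation between cohort prevalence vectors over the retained
#' terms, with Bonferroni-corrected p-values. The default correction factor
#' is n_cohorts x n_terms (configurable; conventions differ).
#'
#' @param m a `phenotype_matrix`.
#' @param terms retained terms (>= 3), e.g. from [characteristic_filter()].
#' @param correction_factor Bonferroni multiplier; default
#'   `n_cohorts * length(terms)`.
#' @return list with `R`, `p` (corrected), `frequencies` (cohort x term
#'   prevalence matrix). Constant prevalence vectors give NA with the pair
#'   listed in attribute `undefined` of `R`.
#' @export
phenotype_correlation <- function(m, terms, correction_factor = NULL) {
  if (length(terms) < 3) stop("need at least 3 retained terms")
  fr <- cohort_frequencies(m, terms)
  fr <- fr[fr$cohort != "all", , drop = FALSE]
  cohorts <- sort(unique(fr$cohort))
  fm <- matrix(NA_real_, length(cohorts), length(terms),
               dimnames = list(cohorts, terms))
  fm[cbind(match(fr$cohort, cohorts), match(fr$term, terms))] <-
    fr$prevalence
  if (is.null(correction_factor))
    correction_factor <- length(cohorts) * length(terms)
  n <- length(cohorts)
  R <- matrix(1, n, n, dimnames = list(cohorts, cohorts))
  P <- matrix(NA_real_, n, n, dimnames = list(cohorts, cohorts))
  undefined <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      keep <- !is.na(fm[i, ]) & !is.na(fm[j, ])
      xi <- fm[i, keep]; xj <- fm[j, keep]
      if (sum(keep) < 3 || sd(xi) == 0 || sd(xj) == 0) {
        R[i, j] <- R[j, i] <- NA_real_
        undefined <- c(undefined, paste(cohorts[i], cohorts[j], sep = ":"))
        next
      }
      ct <- cor.test(xi, xj)
      R[i, j] <- R[j, i] <- unname(ct$estimate)
      P[i, j] <- P[j, i] <- min(1, ct$p.value * correction_factor)
    }
  }
  attr(R, "undefined") <- undefined
  list(R = R, p = P, frequencies = fm)
}

odds_ratio_ci <- function(tab, conf = 0.95) {
  # Haldane-Anscombe 0.5 continuity correction when any cell is zero;
  # Woolf (log-OR normal-approximation) confidence interval
  t2 <- tab
  if (any(tab == 0)) t2 <- tab + 0.5
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  se <- sqrt(sum(1 / t2))
  z <- qnorm(1 - (1 - conf) / 2)
  list(or = or, ci = c(or * exp(-z * se), or * exp(z * se)),
       corrected_cells = any(tab == 0))
}

#' Pairwise Fisher test of one phenotype between two cohorts
#'
#' Two-sided Fisher exact test on the present/absent x cohort 2x2 table
#' (assessed probands only), with layered Bonferroni correction: corrected
#' p = min(1, p x n_genes x n_phenotypes x n_categories). Odds ratio uses
#' the Haldane-Anscombe 0.5 correction when a cell is zero; the exact p is
#' unaffected. CI is Woolf-type on the (corrected) table.
#'
#' @param m a `phenotype_matrix`.
#' @param term phenotype term.
#' @param cohort_a,cohort_b gene-cohort labels.
#' @param factors named numeric vector `c(genes = , phenotypes = ,
#'   categories = )`; default `c(12, 88, 3)`.
#' @return list: term, cohorts, 2x2 `table`, `or`, `ci`, `p_raw`,
#'   `p_corrected`; or a `skipped` record when a cohort has no assessed
#'   probands for the term.
#' @export
pairwise_fisher <- function(m, term, cohort_a, cohort_b,
                            factors = c(genes = 12, phenotypes = 88,
                                        categories = 3)) {
  va <- m$status[m$cohort == cohort_a, term]
  vb <- m$status[m$cohort == cohort_b, term]
  va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
  if (length(va) == 0 || length(vb) == 0) {
    return(list(skipped = TRUE,
                reason = "no assessed probands in one cohort"))
  }
  tab <- matrix(c(sum(va == 1), sum(va == 0), sum(vb == 1), sum(vb == 0)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c(cohort_a, cohort_b),
                                c("present", "absent")))
  p <- fisher.test(tab)$p.value
  orci <- odds_ratio_ci(tab)
  list(skipped = FALSE, term = term, cohorts = c(cohort_a, cohort_b),
       table = tab, or = orci$or, ci = orci$ci, p_raw = p,
       p_corrected = min(1, p * prod(factors)),
       correction_factor = prod(factors))
}

#' LGD vs missense contrast for one phenotype
#'
#' Two-sided Fisher exact test of phenotype presence between probands with
#' LGD and with missense variants, within an optional gene scope.
#'
#' @param m a `phenotype_matrix` with `mutation_class` labels.
#' @param term phenotype term.
#' @param gene_scope optional cohort subset to restrict to.
#' @param factors correction factors as in [pairwise_fisher()]; default 1
#'   (single contrast).
#' @return as [pairwise_fisher()]; `skipped` when a class is unrepresented.
#' @export
lgd_vs_missense <- function(m, term, gene_scope = NULL, factors = 1) {
  sel <- if (is.null(gene_scope)) rep(TRUE, nrow(m$status)) else
    m$cohort %in% gene_scope
  cls <- m$mutation_class[sel]
  v <- m$status[sel, term]
  keep <- !is.na(v) & cls %in% c("LGD", "missense")
  v <- v[keep]; cls <- cls[keep]
  if (length(unique(cls)) < 2) {
    return(list(skipped = TRUE, reason = "single mutation class in scope"))
  }
  tab <- matrix(c(sum(v[cls == "LGD"] == 1), sum(v[cls == "LGD"] == 0),
                  sum(v[cls == "missense"] == 1),
                  sum(v[cls == "missense"] == 0)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("LGD", "missense"),
                                c("present", "absent")))
  p <- fisher.test(tab)$p.value
  orci <- odds_ratio_ci(tab)
  list(skipped = FALSE, term = term, table = tab, or = orci$or,
       ci = orci$ci, p_raw = p, p_corrected = min(1, p * prod(factors)))
}

#' Homology vs phenotype concordance
#'
#' Compares a protein-similarity correlation matrix with a phenotype
#' correlation matrix over the same genes: reports gene pairs exceeding the
#' threshold in both, the Pearson correlation between the matrices' upper
#' triangles, and a Mantel-style label-permutation p (via vegan).
#'
#' @param protein_r,phenotype_r symmetric correlation matrices with
#'   identical gene sets.
#' @param threshold pair-reporting threshold on R (default 0.5).
#' @param n_perm Mantel permutations (default 999).
#' @return list: `pairs` (data.frame of concordant pairs), `triangle_r`,
#'   `mantel_p`.
#' @export
homology_phenotype_concordance <- function(protein_r, phenotype_r,
                                           threshold = 0.5, n_perm = 999) {
  genes <- rownames(protein_r)
  if (!setequal(genes, rownames(phenotype_r)))
    stop("matrices must cover the same gene universe")
  phenotype_r <- phenotype_r[genes, genes]
  ut <- upper.tri(protein_r)
  both <- which(protein_r > threshold & phenotype_r > threshold & ut,
                arr.ind = TRUE)
  pairs <- data.frame(gene_a = genes[both[, 1]], gene_b = genes[both[, 2]],
                      protein_r = protein_r[both],
                      phenotype_r = phenotype_r[both],
                      stringsAsFactors = FALSE)
  tri_r <- cor(protein_r[ut], phenotype_r[ut])
  mt <- vegan::mantel(as.dist(1 - protein_r), as.dist(1 - phenotype_r),
                      method = "pearson", permutations = n_perm)
  list(pairs = pairs, triangle_r = tri_r, mantel_r = unname(mt$statistic),
       mantel_p = mt$signif)
}

#' Shared characteristic-term comparison to external disorders
#'
#' For each family disorder's characteristic term set, the mean number of
#' shared terms (or Jaccard index) with the other family disorders is
#' compared to the mean with external disorders; paired one-sided t-test,
#' alternative within > between.
#'
#' @param family_sets named list of characteristic term sets (>= 3).
#' @param external_sets named list of external disorder term sets (>= 1).
#' @param method `"count"` (shared-term count, default) or `"jaccard"`.
#' @return list: per-disorder data.frame (`within`, `between`), `t`, `p`.
#' @export
shared_hpo_comparison <- function(family_sets, external_sets,
                                  method = c("count", "jaccard")) {
  method <- match.arg(method)
  if (length(family_sets) < 3) stop("need at least 3 family disorders")
  if (length(external_sets) < 1) stop("need at least 1 external disorder")
  sim <- function(a, b) {
    shared <- length(intersect(a, b))
    if (method == "count") shared else shared / length(union(a, b))
  }
  per <- data.frame(
    disorder = names(family_sets),
    within = vapply(names(family_sets), function(n) {
      others <- family_sets[setdiff(names(family_sets), n)]
      mean(vapply(others, sim, numeric(1), a = family_sets[[n]]))
    }, numeric(1)),
    between = vapply(names(family_sets), function(n) {
      mean(vapply(external_sets, sim, numeric(1), a = family_sets[[n]]))
    }, numeric(1)),
    stringsAsFactors = FALSE)
  tt <- t.test(per$within, per$between, paired = TRUE,
               alternative = "greater")
  list(per_disorder = per, t = unname(tt$statistic), p = tt$p.value)
}

#' Read a long phenotype-status table (TSV)
#'
#' Columns `proband`, `term`, `status` in present/absent/missing.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_phenotype_statuses <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             quote = "")
}
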