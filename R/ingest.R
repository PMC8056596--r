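# Variant/proband ingest: classification, exclusion rules, inheritance
# tabulation, candidate-gene selection, constraint-score comparison.

LGD_CONSEQUENCES <- c("stop_gained", "frameshift", "splice_disrupting")
VALID_CONSEQUENCES <- c(LGD_CONSEQUENCES, "start_lost", "missense", "other")
INHERITANCE_LEVELS <- c("de_novo", "inherited", "unknown", "mosaic")

#' Classify a variant into LGD / severe-missense tiers
#'
#' Gene-disruptive consequences (stop gain, frameshift, splice disruption;
#' start loss by default, see `start_loss_lgd`) are classed LGD regardless of
#' CADD. Missense variants are tiered by CADD deleteriousness score:
#' `MIS30` at CADD >= 30 (top 0.1\% of predicted pathogenic variants),
#' `MIS20` at 20 <= CADD < 30 (top 1\%), `MIS_noCADD` when the score is
#' missing, and `excluded` below 20. Both thresholds are inclusive.
#'
#' @param consequence one of `stop_gained`, `frameshift`, `splice_disrupting`,
#'   `start_lost`, `missense`, `other` (vectorised).
#' @param cadd CADD score, `NA` allowed (vectorised, recycled).
#' @param start_loss_lgd treat `start_lost` as LGD (default `TRUE`); when
#'   `FALSE` it is classed `excluded`.
#' @return character vector of classes in
#'   `c("LGD", "MIS20", "MIS30", "MIS_noCADD", "excluded")`.
#' @export
classify_variant <- function(consequence, cadd = NA_real_,
                             start_loss_lgd = TRUE) {
  bad <- setdiff(unique(consequence), VALID_CONSEQUENCES)
  if (length(bad) > 0)
    stop("unknown consequence value(s): ", paste(bad, collapse = ", "))
  n <- max(length(consequence), length(cadd))
  consequence <- rep_len(consequence, n)
  cadd <- rep_len(as.numeric(cadd), n)
  lgd_set <- if (start_loss_lgd) c(LGD_CONSEQUENCES, "start_lost") else
    LGD_CONSEQUENCES
  cls <- rep("excluded", n)
  cls[consequence %in% lgd_set] <- "LGD"
  mis <- consequence == "missense"
  cls[mis & is.na(cadd)] <- "MIS_noCADD"
  cls[mis & !is.na(cadd) & cadd >= 30] <- "MIS30"
  cls[mis & !is.na(cadd) & cadd >= 20 & cadd < 30] <- "MIS20"
  cls[mis & !is.na(cadd) & cadd < 20] <- "excluded"
  cls
}

#' Read a variant table (TSV)
#'
#' Expects a header with at least `proband_id`, `gene`, `consequence`;
#' optional `cohort`, `position`, `cadd`, `inheritance`. Empty cells are
#' missing. A `variant_class` column is added via [classify_variant()].
#'
#' @param path TSV file path.
#' @param ... passed to [classify_variant()].
#' @return data.frame of variant records.
#' @export
read_variants <- function(path, ...) {
  v <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  na.strings = c("", "NA"), quote = "")
  need <- c("proband_id", "gene", "consequence")
  miss <- setdiff(need, names(v))
  if (length(miss) > 0)
    stop("variant table missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(v$cadd)) v$cadd <- NA_real_
  if (is.null(v$inheritance)) v$inheritance <- "unknown"
  v$inheritance[is.na(v$inheritance)] <- "unknown"
  bad <- setdiff(unique(v$inheritance), INHERITANCE_LEVELS)
  if (length(bad) > 0)
    stop("unknown inheritance value(s): ", paste(bad, collapse = ", "))
  v$variant_class <- classify_variant(v$consequence, v$cadd, ...)
  v
}

#' Apply proband exclusion rules
#'
#' A proband is dropped if any of seven criteria holds: a causative variant
#' in another NDD gene; an inherited (non-mosaic) family-gene variant; the
#' variant is present in a population database; a missense variant with
#' CADD < 20; consanguineous parents; prematurity (gestation < 37 weeks);
#' or age under 1 year (too young to assess developmental delay). Missing
#' fields never trigger a criterion: cohort metadata is often incomplete and
#' absence of evidence is not treated as an exclusion.
#'
#' @param p a list or one-row data.frame with any of the fields
#'   `other_causative_variant`, `inherited_variant`, `in_population_db`,
#'   `consequence`, `cadd`, `consanguineous`, `gestational_weeks`,
#'   `age_years`.
#' @return list with `keep` (logical) and `reasons` (character vector of
#'   triggered criteria, empty when kept).
#' @export
apply_exclusions <- function(p) {
  p <- as.list(p)
  flag <- function(x) !is.null(x) && !is.na(x) && isTRUE(as.logical(x))
  num <- function(x) if (is.null(x) || is.na(x)) NA_real_ else as.numeric(x)
  reasons <- character(0)
  if (flag(p$other_causative_variant)) reasons <- c(reasons, "other_causative")
  if (flag(p$inherited_variant)) reasons <- c(reasons, "inherited")
  if (flag(p$in_population_db)) reasons <- c(reasons, "population_db")
  cadd <- num(p$cadd)
  if (!is.null(p$consequence) && !is.na(p$consequence) &&
      p$consequence == "missense" && !is.na(cadd) && cadd < 20)
    reasons <- c(reasons, "low_cadd_missense")
  if (flag(p$consanguineous)) reasons <- c(reasons, "consanguinity")
  gw <- num(p$gestational_weeks)
  if (!is.na(gw) && gw < 37) reasons <- c(reasons, "premature")
  age <- num(p$age_years)
  if (!is.na(age) && age < 1) reasons <- c(reasons, "too_young")
  list(keep = length(reasons) == 0, reasons = reasons)
}

INHERITANCE_TABLE_ROWS <- c("LGD", "all_MIS", "MIS_noCADD", "MIS20", "MIS30",
                            "all")

#' Tabulate inheritance by variant class
#'
#' Counts de novo, inherited and unknown inheritance per variant class,
#' with subtotal rows `all_MIS` (all missense tiers) and `all`. Mosaic
#' variants are tallied with de novo (a mosaic event is a post-zygotic new
#' mutation) but are not relabelled in the input. Only classes LGD,
#' MIS_noCADD, MIS20, MIS30 enter the table; `excluded` records are ignored.
#'
#' @param variants data.frame with `variant_class` and `inheritance` columns.
#' @return data.frame with rows LGD, all_MIS, MIS_noCADD, MIS20, MIS30, all
#'   and columns `de_novo`, `inherited`, `unknown`, `total` plus percentage
#'   columns `pct_de_novo`, `pct_inherited`, `pct_unknown`.
#' @export
tabulate_inheritance <- function(variants) {
  base <- c("LGD", "MIS_noCADD", "MIS20", "MIS30")
  tab <- matrix(0L, nrow = length(INHERITANCE_TABLE_ROWS), ncol = 3,
                dimnames = list(INHERITANCE_TABLE_ROWS,
                                c("de_novo", "inherited", "unknown")))
  if (nrow(variants) > 0) {
    v <- variants[variants$variant_class %in% base, , drop = FALSE]
    inh <- v$inheritance
    inh[inh == "mosaic"] <- "de_novo"
    for (cl in base) {
      sel <- v$variant_class == cl
      tab[cl, ] <- c(sum(sel & inh == "de_novo"),
                     sum(sel & inh == "inherited"),
                     sum(sel & inh == "unknown"))
    }
    tab["all_MIS", ] <- colSums(tab[c("MIS_noCADD", "MIS20", "MIS30"), ,
                                    drop = FALSE])
    tab["all", ] <- tab["LGD", ] + tab["all_MIS", ]
  }
  out <- as.data.frame(tab)
  out$total <- rowSums(tab)
  for (col in c("de_novo", "inherited", "unknown")) {
    out[[paste0("pct_", col)]] <-
      ifelse(out$total > 0, 100 * out[[col]] / out$total, NA_real_)
  }
  out
}

#' Headline fractions from an inheritance table
#'
#' From a [tabulate_inheritance()] result (or an equivalent count table),
#' computes the fraction of variants with known inheritance, the de novo
#' share among variants of known inheritance (mosaic counted as de novo),
#' and the LGD share of all variants, as percentages.
#'
#' @param tab inheritance table with rows `LGD` and `all` and columns
#'   `de_novo`, `inherited`, `unknown`, `total`.
#' @return named list: `pct_known_inheritance`, `pct_de_novo_among_known`,
#'   `pct_lgd_share`.
#' @export
inheritance_summary <- function(tab) {
  all_row <- tab["all", ]
  known <- all_row$de_novo + all_row$inherited
  list(
    pct_known_inheritance = 100 * known / all_row$total,
    pct_de_novo_among_known = 100 * all_row$de_novo / known,
    pct_lgd_share = 100 * tab["LGD", "total"] / all_row$total
  )
}

#' Expand a per-class inheritance tally into one row per variant
#'
#' Utility for driving [tabulate_inheritance()] from a printed count table
#' (class x inheritance counts) rather than variant-level records.
#'
#' @param tally data.frame with columns `variant_class`, `de_novo`,
#'   `inherited`, `unknown` (counts; base classes only, no subtotal rows).
#' @return data.frame of synthetic variant records with `variant_class`
#'   and `inheritance`.
#' @export
expand_inheritance_tally <- function(tally) {
  rows <- lapply(seq_len(nrow(tally)), function(i) {
    r <- tally[i, ]
    data.frame(
      variant_class = r$variant_class,
      inheritance = rep(c("de_novo", "inherited", "unknown"),
                        times = c(r$de_novo, r$inherited, r$unknown)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$proband_id <- sprintf("P%04d", seq_len(nrow(out)))
  out
}

#' Select candidate genes by minimum distinct-proband count
#'
#' A gene qualifies when at least `min_probands` distinct probands carry a
#' retained (non-`excluded`) variant in it. A proband with several variants
#' in one gene counts once.
#'
#' @param variants data.frame with `gene`, `proband_id` and optionally
#'   `variant_class` columns.
#' @param min_probands minimum number of distinct probands (default 3).
#' @return sorted character vector of qualifying genes.
#' @export
select_candidate_genes <- function(variants, min_probands = 3) {
  if (min_probands < 1) stop("min_probands must be >= 1")
  v <- variants
  if (!is.null(v$variant_class))
    v <- v[v$variant_class != "excluded", , drop = FALSE]
  if (nrow(v) == 0) return(character(0))
  counts <- tapply(v$proband_id, v$gene,
                   function(p) length(unique(p)))
  sort(names(counts)[counts >= min_probands])
}

#' Compare a constraint metric between NDD and non-NDD genes
#'
#' Welch two-sample t-test, one-sided with alternative NDD > non-NDD, on a
#' gene-level constraint metric (pLI, missense Z, LOEUF/VIRLoF percentile).
#'
#' @param table data.frame with an `is_ndd` logical column and the metric
#'   column.
#' @param metric column name to compare.
#' @return list with `t`, `p`, `df`, group means and `degenerate` flag
#'   (`TRUE` when both groups are constant and the statistic is undefined;
#'   `t` and `p` are then `NA`).
#' @export
compare_constraint <- function(table, metric) {
  if (!metric %in% names(table)) stop("no such metric column: ", metric)
  x <- table[[metric]][table$is_ndd]
  y <- table[[metric]][!table$is_ndd]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("both groups need at least 2 non-missing values")
  if (sd(x) == 0 && sd(y) == 0) {
    return(list(t = NA_real_, p = NA_real_, df = NA_real_,
                mean_ndd = mean(x), mean_other = mean(y), degenerate = TRUE))
  }
  tt <- t.test(x, y, alternative = "greater", var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_ndd = mean(x), mean_other = mean(y),
       degenerate = FALSE)
}
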