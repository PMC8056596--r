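toy_matrix <- function() {
  statuses <- data.frame(
    proband = c("p1", "p1", "p2", "p2", "p3", "p3", "p4", "p5", "p6"),
    term = c("seizures", "dd", "seizures", "dd", "seizures", "dd",
             "seizures", "seizures", "dd"),
    status = c("present", "present", "absent", "present", "present",
               "missing", "absent", "present", "absent"))
  probands <- data.frame(proband = sprintf("p%d", 1:6),
                         cohort = rep(c("GENEA", "GENEB"), each = 3),
                         mutation_class = c("LGD", "LGD", "missense",
                                            "LGD", "missense", "missense"))
  build_matrix(statuses, probands)
}

test_that("matrix construction: missing is not absent, cohorts required", {
  m <- toy_matrix()
  expect_equal(m$status["p1", "seizures"], 1)
  expect_equal(m$status["p2", "seizures"], 0)
  expect_true(is.na(m$status["p3", "dd"]))   # explicit missing
  expect_true(is.na(m$status["p4", "dd"]))   # never assessed
  bad <- data.frame(proband = "p1", cohort = NA)
  expect_error(build_matrix(data.frame(proband = "p1", term = "t",
                                       status = "present"), bad),
               "cohort")
})

test_that("quantitative measures map through extreme percentiles", {
  statuses <- data.frame(proband = character(0), term = character(0),
                         status = character(0))
  probands <- data.frame(proband = c("p1", "p2", "p3"), cohort = "G")
  quant <- data.frame(proband = c("p1", "p2", "p3"),
                      percentile = c(2, 50, NA),
                      low_term = "microcephaly", high_term = "macrocephaly")
  m <- build_matrix(statuses, probands, quantitative = quant)
  expect_equal(m$status["p1", "microcephaly"], 1)
  expect_equal(m$status["p1", "macrocephaly"], 0)
  expect_equal(m$status["p2", "microcephaly"], 0)
  expect_true(is.na(m$status["p3", "microcephaly"]))
  # boundary: 3rd and 97th percentiles inclusive
  q2 <- data.frame(proband = c("p1", "p2"), percentile = c(3, 97),
                   low_term = "low", high_term = "high")
  m2 <- build_matrix(statuses, probands[1:2, , drop = FALSE],
                     quantitative = q2)
  expect_equal(m2$status["p1", "low"], 1)
  expect_equal(m2$status["p2", "high"], 1)
})

test_that("cohort frequencies use assessed denominators and pool", {
  m <- toy_matrix()
  fr <- cohort_frequencies(m)
  ga_seiz <- fr[fr$cohort == "GENEA" & fr$term == "seizures", ]
  expect_equal(ga_seiz$count_with, 2)
  expect_equal(ga_seiz$count_assessed, 3)
  ga_dd <- fr[fr$cohort == "GENEA" & fr$term == "dd", ]
  expect_equal(ga_dd$count_assessed, 2) # p3 missing excluded per-term
  pooled <- fr[fr$cohort == "all" & fr$term == "seizures", ]
  expect_equal(pooled$count_with, 3)
  expect_equal(pooled$count_assessed, 5)
  expect_true(all(fr$count_with <= fr$count_assessed))
  expect_true(all(fr$count_assessed <= 6))
})

test_that("characteristic filter is boundary-inclusive and monotone", {
  statuses <- do.call(rbind, lapply(1:5, function(i) {
    data.frame(proband = paste0("p", i), term = "rare",
               status = ifelse(i == 1, "present", "absent"))
  }))
  probands <- data.frame(proband = sprintf("p%d", 1:5), cohort = "G")
  m <- build_matrix(statuses, probands)
  expect_identical(characteristic_filter(m, tau = 0.20), "rare") # 1/5
  expect_length(characteristic_filter(m, tau = 0.21), 0)
  # monotone in tau; tau = 0 keeps every observed term
  m2 <- gen_phenotype_cohorts(setNames(c(20L, 20L), c("A", "B")),
                              base = setNames(runif(10, 0.05, 0.5),
                                              sprintf("t%02d", 1:10)),
                              w = 0.5, seed = 81)
  taus <- c(0, 0.1, 0.2, 0.4, 0.8)
  kept <- lapply(taus, function(t) characteristic_filter(m2, t))
  for (i in seq_len(length(taus) - 1)) {
    expect_true(all(kept[[i + 1]] %in% kept[[i]]))
  }
  expect_setequal(kept[[1]], colnames(m2$status))
})

test_that("pairwise Fisher matches the exact-test oracle and corrects", {
  m <- toy_matrix()
  res <- pairwise_fisher(m, "seizures", "GENEA", "GENEB",
                         factors = c(genes = 2, phenotypes = 2,
                                     categories = 1))
  expect_false(res$skipped)
  expect_equal(res$p_raw, fisher.test(res$table)$p.value)
  expect_equal(res$p_corrected, min(1, res$p_raw * 4))
  expect_gte(res$p_corrected, res$p_raw)
  # hand 2x2 vs enumeration oracle
  tab <- matrix(c(9, 1, 1, 9), 2, byrow = TRUE)
  expect_equal(fisher.test(tab)$p.value, oracle_fisher_two_sided(tab),
               tolerance = 1e-9)
  # identical cohorts: p = 1
  statuses <- rbind(
    data.frame(proband = sprintf("a%d", 1:4), term = "t",
               status = rep(c("present", "absent"), 2)),
    data.frame(proband = sprintf("b%d", 1:4), term = "t",
               status = rep(c("present", "absent"), 2)))
  probands <- data.frame(proband = c(sprintf("a%d", 1:4),
                                     sprintf("b%d", 1:4)),
                         cohort = rep(c("A", "B"), each = 4))
  meq <- build_matrix(statuses, probands)
  expect_equal(pairwise_fisher(meq, "t", "A", "B")$p_raw, 1)
})

test_that("zero cells get the Haldane-Anscombe OR, exact p unaffected", {
  statuses <- rbind(
    data.frame(proband = sprintf("a%d", 1:4), term = "t",
               status = "present"),
    data.frame(proband = sprintf("b%d", 1:4), term = "t",
               status = c("present", "absent", "absent", "absent")))
  probands <- data.frame(proband = c(sprintf("a%d", 1:4),
                                     sprintf("b%d", 1:4)),
                         cohort = rep(c("A", "B"), each = 4))
  m <- build_matrix(statuses, probands)
  res <- pairwise_fisher(m, "t", "A", "B")
  # table (4,0 / 1,3): corrected OR = (4.5*3.5)/(0.5*1.5)
  expect_equal(res$or, (4.5 * 3.5) / (0.5 * 1.5))
  expect_equal(res$p_raw, fisher.test(matrix(c(4, 0, 1, 3), 2,
                                             byrow = TRUE))$p.value)
})

test_that("LGD vs missense contrast: OR arithmetic and skip rules", {
  # counts (30,10 / 20,40) -> OR = (30*40)/(10*20) = 6
  statuses <- rbind(
    data.frame(proband = sprintf("l%02d", 1:40), term = "t",
               status = rep(c("present", "absent"), c(30, 10))),
    data.frame(proband = sprintf("m%02d", 1:60), term = "t",
               status = rep(c("present", "absent"), c(20, 40))))
  probands <- data.frame(
    proband = c(sprintf("l%02d", 1:40), sprintf("m%02d", 1:60)),
    cohort = "G",
    mutation_class = rep(c("LGD", "missense"), c(40, 60)))
  m <- build_matrix(statuses, probands)
  res <- lgd_vs_missense(m, "t")
  expect_equal(res$or, 6)
  expect_true(res$ci[1] < 6 && res$ci[2] > 6)
  # symmetric table: OR = 1
  probands2 <- probands[1:80, ]
  probands2$mutation_class <- rep(c("LGD", "missense"), each = 40)
  statuses2 <- data.frame(proband = probands2$proband, term = "t",
                          status = rep(rep(c("present", "absent"),
                                           c(20, 20)), 2))
  expect_equal(lgd_vs_missense(build_matrix(statuses2, probands2),
                               "t")$or, 1)
  # single class in scope: skipped
  mono <- build_matrix(statuses2[1:40, ], probands2[1:40, ])
  expect_true(lgd_vs_missense(mono, "t")$skipped)
})

test_that("planted shared-profile cohorts correlate; independent do not", {
  terms <- sprintf("t%02d", 1:30)
  base <- setNames(runif(30, 0.1, 0.8), terms)
  shared <- gen_phenotype_cohorts(setNames(rep(40L, 5), paste0("G", 1:5)),
                                  base = base, w = 0.85, seed = 82)
  ret <- characteristic_filter(shared)
  pc <- phenotype_correlation(shared, ret)
  expect_true(all(pc$R[upper.tri(pc$R)] > 0.4))
  indep <- gen_phenotype_cohorts(setNames(rep(40L, 5), paste0("G", 1:5)),
                                 base = base, w = 0, seed = 83)
  pci <- phenotype_correlation(indep, colnames(indep$status))
  expect_lt(mean(abs(pci$R[upper.tri(pci$R)])), 0.35)
  expect_gt(mean(pc$R[upper.tri(pc$R)]),
            mean(pci$R[upper.tri(pci$R)]))
})

test_that("planted cohort-similarity ranking is recovered", {
  terms <- sprintf("t%02d", 1:40)
  rho <- vapply(1:10, function(s) {
    set.seed(8300 + s)
    base <- setNames(runif(40, 0.1, 0.8), terms)
    ws <- c(A = 0.9, B = 0.6, C = 0.3)
    # three cohorts at decreasing similarity to a reference cohort
    mats <- lapply(names(ws), function(g) {
      gen_phenotype_cohorts(setNames(60L, g), base = base, w = ws[[g]],
                            seed = 8400 + s + match(g, names(ws)))
    })
    ref <- gen_phenotype_cohorts(c(REF = 60L), base = base, w = 1,
                                 seed = 8500 + s)
    status <- do.call(rbind, c(lapply(mats, `[[`, "status"),
                               list(ref$status)))
    cohort <- c(unlist(lapply(mats, `[[`, "cohort")), ref$cohort)
    m <- structure(list(status = status, cohort = cohort,
                        mutation_class = rep(NA_character_, nrow(status))),
                   class = "phenotype_matrix")
    pc <- phenotype_correlation(m, terms)
    cor(pc$R["REF", c("A", "B", "C")], ws, method = "spearman")
  }, numeric(1))
  expect_gte(mean(rho >= 0.8), 0.8)
})

test_that("homology-phenotype concordance: identical matrices correlate
          perfectly, planted structure is detected", {
  seqs <- gen_protein_family(3, 4, seed = 84)
  pr <- pairwise_identity(seqs) / 100
  diag(pr) <- 1
  self <- homology_phenotype_concordance(pr, pr)
  expect_equal(self$triangle_r, 1)
  expect_lt(self$mantel_p, 0.05)
  # phenotype similarity derived from homology groups + noise
  set.seed(85)
  ph <- pr + matrix(rnorm(length(pr), 0, 0.05), nrow(pr))
  ph[ph > 1] <- 1
  ph[ph < -1] <- -1
  ph[lower.tri(ph)] <- t(ph)[lower.tri(ph)]
  diag(ph) <- 1
  res <- homology_phenotype_concordance(pr, ph)
  expect_gt(res$triangle_r, 0.5)
  expect_lt(res$mantel_p, 0.05)
  expect_true(all(res$pairs$protein_r > 0.5 &
                    res$pairs$phenotype_r > 0.5))
  expect_error(homology_phenotype_concordance(pr, ph[1:10, 1:10]),
               "universe")
})

test_that("independent matrices give a non-significant Mantel test most
          of the time", {
  set.seed(86)
  ps <- replicate(10, {
    r1 <- cor(matrix(rnorm(12 * 8), 12))
    r2 <- cor(matrix(rnorm(12 * 8), 12))
    dimnames(r1) <- dimnames(r2) <- list(letters[1:8], letters[1:8])
    homology_phenotype_concordance(r1, r2, n_perm = 199)$mantel_p
  })
  expect_gt(mean(ps > 0.05), 0.6)
})

test_that("shared-HPO comparison separates pooled family sets from
          disjoint external sets", {
  set.seed(87)
  pool <- sprintf("HP:%04d", 1:30)
  fam <- lapply(1:5, function(i) sample(pool, 15))
  names(fam) <- paste0("fam", 1:5)
  ext <- lapply(1:4, function(i) sprintf("HP:9%03d", sample(1:200, 15)))
  names(ext) <- paste0("ext", 1:4)
  res <- shared_hpo_comparison(fam, ext)
  expect_lt(res$p, 0.05)
  expect_true(all(res$per_disorder$within > res$per_disorder$between))
  # identical external sets: no separation
  res0 <- shared_hpo_comparison(fam, fam)
  expect_gt(res0$p, 0.2)
  expect_error(shared_hpo_comparison(fam[1:2], ext), "3 family")
  expect_error(shared_hpo_comparison(fam, list()), "external")
  # jaccard variant bounded in [0, 1]
  resj <- shared_hpo_comparison(fam, ext, method = "jaccard")
  expect_true(all(resj$per_disorder$within <= 1 &
                    resj$per_disorder$within >= 0))
})
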