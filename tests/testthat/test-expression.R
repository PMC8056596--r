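test_that("planted marker gene is enriched in its cell type only", {
  m <- gen_expression(n_types = 6, cells_per_type = 100,
                      genes = c("mk", "bg"),
                      enriched = list(mk = "type03"), fold = 5, seed = 61)
  e <- celltype_enrichment(m, "mk")
  hit <- e[e$cell_type == "type03", ]
  expect_lt(hit$q, 0.05)
  expect_gt(hit$fold_change, 2)
  # depleted (fold < 1) in the other types
  expect_true(all(e$fold_change[e$cell_type != "type03"] < 1))
})

test_that("rank test p-values are invariant under monotone transforms", {
  m <- gen_expression(n_types = 4, cells_per_type = 50, genes = "g",
                      enriched = list(g = "type02"), fold = 3, seed = 62)
  e1 <- celltype_enrichment(m, "g")
  m2 <- m
  m2$values <- log1p(m$values)
  e2 <- celltype_enrichment(m2, "g")
  expect_equal(e1$p, e2$p)
})

test_that("constant genes are flagged with p = 1", {
  vals <- matrix(1, 40, 2, dimnames = list(NULL, c("flat", "ok")))
  set.seed(63)
  vals[, "ok"] <- rlnorm(40)
  m <- expression_matrix(vals, rep(c("a", "b"), each = 20))
  e <- celltype_enrichment(m, "flat")
  expect_true(all(e$p == 1))
  expect_true(all(e$undefined))
  expect_true(all(is.na(e$fold_change)))
})

test_that("label permutation yields uniform-ish p-values", {
  set.seed(64)
  base <- gen_expression(n_types = 4, cells_per_type = 40, genes = "g",
                         seed = 64)
  ps <- replicate(40, {
    m2 <- base
    m2$cell_type <- sample(base$cell_type)
    min(celltype_enrichment(m2, "g")$p)
  })
  # min over 4 types, so compare against the null min-of-4 distribution
  expect_gt(mean(ps), 0.1)
  expect_lt(mean(ps <= 0.0125), 0.2)
})

test_that("fold-change Z-scores center and flag degenerate profiles", {
  e <- data.frame(gene = "g", cell_type = sprintf("t%d", 1:10),
                  fold_change = c(5, rep(0.9, 9)))
  z <- foldchange_z(e)
  expect_equal(sum(z$z), 0, tolerance = 1e-12)
  expect_equal(which.max(abs(z$z)), 1)
  flat <- data.frame(gene = "g", cell_type = sprintf("t%d", 1:6),
                     fold_change = rep(2, 6))
  zf <- foldchange_z(flat)
  expect_true(all(zf$z == 0))
  expect_true(attr(zf, "degenerate"))
  # symmetric +/- pattern sums to zero by construction
  sym <- data.frame(gene = "g", cell_type = sprintf("t%d", 1:6),
                    fold_change = rep(c(2, 0.5), 3))
  expect_equal(sum(foldchange_z(sym)$z), 0, tolerance = 1e-12)
})

test_that("expression correlation: duplicated genes give R = 1 and toy
          profiles match the closed form", {
  set.seed(65)
  vals <- matrix(rlnorm(60 * 3), 60, 3,
                 dimnames = list(NULL, c("g1", "g2", "g3")))
  vals[, "g2"] <- vals[, "g1"]
  m <- expression_matrix(vals, rep(c("a", "b", "c"), each = 20))
  ec <- expression_correlation(m)
  expect_equal(ec$R["g1", "g2"], 1)
  prof <- type_profiles(m)
  expect_equal(ec$R["g1", "g3"], cor(prof["g1", ], prof["g3", ]))
  expect_true(all(ec$p >= 0 & ec$p <= 1, na.rm = TRUE))
})

test_that("independent profiles have near-zero mean off-diagonal R", {
  set.seed(66)
  rs <- replicate(15, {
    m <- gen_expression(n_types = 10, cells_per_type = 15,
                        genes = sprintf("g%d", 1:6),
                        seed = sample.int(1e6, 1))
    R <- expression_correlation(m)$R
    mean(R[upper.tri(R)])
  })
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("region enrichment equals the hypergeometric tail oracle", {
  # toy 2x2: overlap 8, query-only 2, set-only 10, neither 80
  universe <- sprintf("u%03d", 1:100)
  region <- universe[1:18]          # 8 overlap + 10 set-only
  gene_set <- universe[c(1:8, 19:20)] # 8 overlap + 2 outside
  res <- region_enrichment(gene_set, list(toy = region), universe)
  expect_equal(res$p, oracle_hyper_tail(8, K = 18, n_other = 82,
                                        set_size = 10),
               tolerance = 1e-12)
  # disjoint set: one-sided p = 1
  res0 <- region_enrichment(universe[30:35], list(r = universe[1:5]),
                            universe)
  expect_equal(res0$p, 1)
  # gene_set = region = universe: p = 1
  resU <- region_enrichment(universe, list(r = universe), universe)
  expect_equal(resU$p, 1)
  expect_error(region_enrichment("zzz", list(r = universe), universe),
               "subset")
  expect_error(region_enrichment("a", list(r = "a"), character(0)),
               "universe")
})

test_that("BH q-values are monotone in p and bounded by 1", {
  set.seed(67)
  universe <- sprintf("u%03d", 1:200)
  regions <- lapply(1:12, function(i) sample(universe, 30))
  names(regions) <- sprintf("r%02d", 1:12)
  res <- region_enrichment(sample(universe, 40), regions, universe)
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-12))
  expect_true(all(res$q <= 1))
  expect_true(all(res$q >= res$p))
})

test_that("family profiles generated from a shared latent profile separate
          from independent external genes", {
  set.seed(68)
  n_types <- 10; cells <- 12
  types <- sprintf("t%02d", 1:n_types)
  latent <- runif(n_types, 0.5, 3)
  mk <- function(base) {
    unlist(lapply(base, function(mu) rlnorm(cells, log(mu), 0.4)))
  }
  fam <- sapply(1:4, function(i) mk(latent * runif(1, 0.8, 1.2)))
  ext <- sapply(1:4, function(i) mk(runif(n_types, 0.5, 3)))
  vals <- cbind(fam, ext)
  colnames(vals) <- c(sprintf("fam%d", 1:4), sprintf("ext%d", 1:4))
  m <- expression_matrix(vals, rep(types, each = cells))
  res <- family_vs_external(m, sprintf("fam%d", 1:4),
                            sprintf("ext%d", 1:4))
  expect_lt(res$p, 0.05)
  expect_true(all(res$per_gene$within_r > res$per_gene$external_r))
  expect_error(family_vs_external(m, c("fam1", "ext1"), c("ext1", "ext2")),
               "disjoint")
  expect_error(family_vs_external(m, "fam1", c("ext1", "ext2")),
               "at least 2")
})

test_that("external copies of family profiles show no separation", {
  set.seed(69)
  n_types <- 8; cells <- 10
  types <- sprintf("t%02d", 1:n_types)
  latent <- runif(n_types, 0.5, 3)
  mk <- function() unlist(lapply(latent, function(mu)
    rlnorm(cells, log(mu), 0.4)))
  vals <- sapply(1:8, function(i) mk())
  colnames(vals) <- c(sprintf("fam%d", 1:4), sprintf("ext%d", 1:4))
  m <- expression_matrix(vals, rep(types, each = cells))
  res <- family_vs_external(m, sprintf("fam%d", 1:4),
                            sprintf("ext%d", 1:4))
  expect_gt(res$p, 0.05)
})

test_that("two-way ANOVA surfaces group and tissue effects", {
  set.seed(70)
  long <- expand.grid(group = c("ndd", "other"),
                      tissue = sprintf("t%d", 1:5), rep = 1:6)
  long$value <- rnorm(nrow(long)) +
    ifelse(long$tissue == "t1", 2, 0) # tissue effect only
  res <- expression_anova(long)
  expect_lt(res$p[res$term == "tissue"], 0.01)
  expect_gt(res$p[res$term == "group"], 0.05)
})

test_that("expression matrix IO round-trips dense, sparse and GMT", {
  m <- gen_expression(n_types = 2, cells_per_type = 3,
                      genes = c("g1", "g2"), seed = 71)
  td <- tempfile(); dir.create(td)
  dense <- file.path(td, "dense.tsv")
  meta <- file.path(td, "meta.tsv")
  write.table(data.frame(cell = rownames(m$values), m$values),
              dense, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(cell = rownames(m$values),
                         cell_type = m$cell_type),
              meta, sep = "\t", quote = FALSE, row.names = FALSE)
  # read.table sets the first column as rownames when header is one short
  m2 <- read_expression(dense, meta)
  expect_equal(unname(m2$values[, "g1"]), unname(m$values[, "g1"]))
  expect_equal(m2$cell_type, m$cell_type)
  # sparse triplets
  tr <- file.path(td, "trip.tsv")
  idx <- which(m$values != 0, arr.ind = TRUE)
  write.table(data.frame(cell = rownames(m$values)[idx[, 1]],
                         gene = colnames(m$values)[idx[, 2]],
                         value = m$values[idx]),
              tr, sep = "\t", quote = FALSE, row.names = FALSE)
  m3 <- read_expression(tr, meta, sparse = TRUE)
  expect_equal(m3$values[rownames(m$values), colnames(m$values)],
               m$values)
  # gmt round trip
  g <- file.path(td, "sets.gmt")
  sets <- list(s1 = c("a", "b"), s2 = c("c"))
  write_gmt(sets, g)
  expect_equal(read_gmt(g), sets)
})
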