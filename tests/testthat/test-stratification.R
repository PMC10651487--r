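test_that("compute_composition is a plain count ratio", {
  ct <- toy_cell_table(c("T", "T", "NK", "myeloid"))
  comp <- compute_composition(ct)
  expect_equal(unname(comp["S1", ]), c(0.5, 0, 0.25, 0.25, 0, 0))
  ct2 <- toy_cell_table(rep("stromal", 5))
  expect_equal(unname(compute_composition(ct2)["S1", ]),
               c(0, 0, 0, 0, 1, 0))
  expect_error(compute_composition(toy_cell_table("Fibroblast")),
               "unknown cell type")
})

test_that("pooled atlas-scale pseudo-sample gives the forced T proportion", {
  counts <- c(94046L, 30691L, 8495L, 76181L, 79555L, 25043L)
  ct <- data.frame(cell_id = seq_len(sum(counts)), sample_id = "pool",
                   cell_type = rep(canonical_types(), counts))
  comp <- compute_composition(ct)
  expect_equal(sum(comp["pool", ]), 1)
  expect_equal(unname(comp["pool", "T"]), 94046 / 314011)
})

test_that("low-yield samples are excluded with a warning", {
  ct <- rbind(toy_cell_table(rep("T", 150), "big"),
              toy_cell_table(rep("T", 10), "small"))
  expect_warning(comp <- compute_composition(ct, min_cells = 100L), "small")
  expect_equal(rownames(comp), "big")
})

test_that("three simplex corners cluster perfectly at k = 3", {
  types <- canonical_types()
  m <- matrix(0, 3, 6, dimnames = list(c("a", "b", "c"), types))
  m[1, 1] <- 1; m[2, 3] <- 1; m[3, 5] <- 1
  comp <- as_composition(m)
  model <- suppressWarnings(  # corner cohort has zero-sd types in naming
    cluster_samples(comp, k_range = 3L, n_boot = 50L, min_size = 1L,
                    n_cells = rep(5000L, 3),
                    resample_samples = FALSE, seed = 1L))
  expect_equal(model$k, 3L)
  expect_equal(length(unique(model$labels)), 3L)
  expect_equal(unname(model$stability["3"]), 1)
})

test_that("duplicated composition rows always co-cluster", {
  co <- small_cohort(n_samples = 10L, cells = c(100L, 120L), seed = 15L)
  comp <- unclass(co$truth$composition)
  comp <- rbind(comp, dup1 = comp[1, ])
  rownames(comp)[1] <- "dup0"
  hc <- stats::hclust(stats::dist(comp), method = "ward.D2")
  for (k in 2:(nrow(comp) - 1)) {
    labs <- stats::cutree(hc, k)
    expect_length(unique(labs[c("dup0", "dup1")]), 1L)
  }
})

test_that("preset cohort recovers the planted six phenotypes and names", {
  co <- small_cohort(n_samples = 60L, cells = c(600L, 800L), seed = 1L)
  comp <- compute_composition(co$cell_table)
  model <- cluster_samples(comp, n_boot = 100L, seed = 2L)
  expect_equal(model$k, 6L)
  expect_gte(adjusted_rand_index(model$labels,
                                 co$truth$phenotype[rownames(comp)]), 0.9)
  expect_setequal(model$names, c("EFM", "F", "TF", "TB", "TM", "M"))
})

test_that("clustering is invariant to sample row order", {
  co <- small_cohort(n_samples = 24L, cells = c(200L, 250L), seed = 33L)
  comp <- compute_composition(co$cell_table)
  model <- cluster_samples(comp, k = 4L, seed = 5L)
  set.seed(77)
  perm <- sample(nrow(comp))
  comp2 <- comp[perm, ]
  attr(comp2, "n_cells") <- attr(comp, "n_cells")[perm]
  model2 <- cluster_samples(as_composition(unclass(comp2)), k = 4L, seed = 5L)
  same <- adjusted_rand_index(model$labels[rownames(comp)[perm]],
                              model2$labels)
  expect_equal(same, 1)
})

test_that("infeasible k_range errors", {
  co <- small_cohort(n_samples = 8L, cells = c(80L, 90L), seed = 3L)
  comp <- compute_composition(co$cell_table)
  expect_error(cluster_samples(comp, k_range = 2:7, min_size = 3L),
               "infeasible")
})

test_that("naming follows the z rule with the fallback", {
  types <- canonical_types()
  set.seed(1)
  base <- matrix(rep(c(.2, .1, .05, .2, .3, .15), 8), 8, 6, byrow = TRUE)
  m <- pmax(base + matrix(stats::rnorm(48, 0, 0.01), 8, 6), 1e-4)
  # cluster 1 = strongly T/B enriched, cluster 2 = the rest
  m[1:3, ] <- matrix(rep(c(.45, .25, .05, .1, .1, .05), 3), 3, 6,
                     byrow = TRUE) +
    matrix(stats::rnorm(18, 0, 0.005), 3, 6)
  dimnames(m) <- list(paste0("s", 1:8), types)
  comp <- as_composition(close_rows(pmax(m, 1e-4)))
  model <- list(k = 2L, labels = stats::setNames(c(1, 1, 1, 2, 2, 2, 2, 2),
                                                 rownames(comp)),
                types = types)
  nm <- name_ctaps(model, comp, z_threshold = 0.5)
  expect_equal(nm[1], "TB")  # T and B both pass; conventional order T first
  # fallback: cluster mean equal to cohort mean -> single max-z letter
  flat <- matrix(rep(colMeans(unclass(comp)), 4), 4, 6, byrow = TRUE)
  rownames(flat) <- paste0("f", 1:4); colnames(flat) <- types
  both <- as_composition(close_rows(rbind(unclass(comp), flat)))
  model2 <- list(k = 2L,
                 labels = stats::setNames(c(rep(1, 8), rep(2, 4)),
                                          rownames(both)),
                 types = types)
  nm2 <- name_ctaps(model2, both)
  expect_equal(nchar(nm2[2]), 1L)
})

test_that("project_samples assigns nearest centroid with tie flag", {
  types <- canonical_types()
  cent <- matrix(0, 2, 6, dimnames = list(NULL, types))
  cent[1, 1] <- 1
  cent[2, 3] <- 1
  model <- list(k = 2L, centroids = cent, names = c("A", "B"), types = types)
  exact <- cent[1, , drop = FALSE]
  rownames(exact) <- "x"
  res <- project_samples(model, exact)
  expect_equal(res$ctap, "A")
  expect_equal(res$distance, 0)
  expect_false(res$tie)
  mid <- matrix(c(.5, 0, .5, 0, 0, 0), 1, dimnames = list("m", types))
  res2 <- project_samples(model, mid)
  expect_equal(res2$ctap, "A")  # lowest index wins the tie
  expect_true(res2$tie)
  bad <- exact[, c(2:6, 1), drop = FALSE]
  expect_error(project_samples(model, bad), "column order mismatch")
})

test_that("held-out preset samples project to their generating phenotype", {
  co <- small_cohort(n_samples = 72L, cells = c(400L, 500L), seed = 19L)
  comp <- compute_composition(co$cell_table)
  train <- rownames(comp)[1:48]
  test <- setdiff(rownames(comp), train)
  model <- cluster_samples(comp[train, ], n_boot = 60L, seed = 3L,
                           n_cells = attr(comp, "n_cells")[1:48])
  # map each recovered cluster to its dominant truth phenotype
  truth <- co$truth$phenotype
  clus2ph <- vapply(seq_len(model$k), function(g) {
    names(which.max(table(truth[train][model$labels == g])))
  }, character(1))
  proj <- project_samples(model, comp[test, ])
  pred_ph <- clus2ph[match(proj$ctap, model$names)]
  expect_gte(mean(pred_ph == truth[test]), 0.9)
})

test_that("composition PCA reproduces centred geometry", {
  co <- small_cohort(n_samples = 12L, cells = c(100L, 120L), seed = 22L)
  comp <- unclass(co$truth$composition)
  pc <- composition_pca(comp)
  expect_equal(sum(pc$var_frac), 1, tolerance = 1e-9)
  centred <- scale(comp, scale = FALSE)
  expect_equal(as.matrix(stats::dist(pc$scores)),
               as.matrix(stats::dist(centred)), tolerance = 1e-8)
  two <- composition_pca(comp[1:2, ])
  expect_equal(two$var_frac[1], 1, tolerance = 1e-9)
  expect_error(composition_pca(comp[1, , drop = FALSE]), "at least 2")
})

test_that("preset CTAP labels separate in PC1-2 (positive silhouette)", {
  co <- small_cohort(n_samples = 48L, cells = c(400L, 500L), seed = 28L)
  comp <- compute_composition(co$cell_table)
  pc <- composition_pca(comp)
  labs <- as.integer(factor(co$truth$phenotype[rownames(comp)]))
  sil <- cluster::silhouette(labs, stats::dist(pc$scores[, 1:2]))
  expect_gt(mean(sil[, "sil_width"]), 0)
})

test_that("cytokine categorization agrees with planted phenotypes", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  set.seed(41)
  null_ari <- replicate(200, adjusted_rand_index(
    sample(rep(1:3, 8)), rep(1:3, 8)))
  expect_lt(abs(mean(null_ari)), 0.05)

  co <- small_cohort(n_samples = 36L, cells = c(500L, 600L), seed = 12L,
                     counts = TRUE)
  bulk <- mix_pseudobulk(co, 0)
  truth <- co$truth$phenotype[colnames(bulk)]
  res <- cytokine_categorize(bulk, co$config$cytokine_genes, k = 6L, truth)
  set.seed(9)
  null95 <- stats::quantile(replicate(100, {
    cytokine_categorize(bulk, co$config$cytokine_genes, k = 6L,
                        sample(unname(truth)))$ari
  }), 0.95)
  expect_gt(res$ari, null95)
  expect_error(cytokine_categorize(bulk, c("nope1", "nope2"), 6L, truth),
               "fewer than 2")
})

test_that("Ward linkage matches the Lance-Williams brute-force oracle", {
  set.seed(55)
  for (rep in 1:5) {
    x <- matrix(stats::rnorm(8), 4, 2)
    hc <- stats::hclust(stats::dist(x), method = "ward.D2")
    oracle <- ward_oracle(x)
    expect_equal(hc$height, oracle$heights, tolerance = 1e-10)
  }
})

test_that("stability is within [-1, 1] and hits 1 for noiseless corners", {
  co <- small_cohort(n_samples = 21L, cells = c(150L, 200L), seed = 44L)
  comp <- compute_composition(co$cell_table)
  model <- cluster_samples(comp, k_range = 2:5, n_boot = 40L, seed = 1L)
  expect_true(all(model$stability >= -1 & model$stability <= 1))
})
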