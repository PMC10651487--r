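# shared fixtures, built in code at test time

# small preset cohort without counts (compositions/embeddings only)
small_cohort <- function(n_samples = 30L, cells = c(150L, 200L), seed = 42L,
                         counts = FALSE, n_genes = 300L) {
  cfg <- default_sim_config(n_samples = n_samples, cells_per_sample = cells,
                            n_genes = n_genes, seed = seed)
  generate_cohort(cfg, counts = counts)
}

# hand-built cell table over the canonical types
toy_cell_table <- function(types, sample_id = "S1") {
  data.frame(cell_id = sprintf("%s_c%02d", sample_id, seq_along(types)),
             sample_id = sample_id, cell_type = types,
             state = paste0(types, "_state"),
             stringsAsFactors = FALSE)
}

# single-phenotype degenerate configuration (everything type T)
degenerate_config <- function(n_samples = 3L, seed = 7L) {
  types <- canonical_types()
  theta <- stats::setNames(
    lapply(types, function(ty) stats::setNames(1, paste0(ty, "_s"))), types)
  sim_config(
    n_samples = n_samples,
    phenotypes = list(pureT = list(
      pi = stats::setNames(c(1, 0, 0, 0, 0, 0), types),
      alpha = 1e9, theta = theta)),
    cells_per_sample = c(50L, 50L), n_genes = 30L,
    marker_spec = data.frame(gene = "gene_001", state = "T_s", log_fc = 2),
    seed = seed)
}

# per-sample covariate matrix used in association tests
assoc_covariates <- function(cohort, samples, cell_sel) {
  meta <- cohort$sample_meta[match(samples, cohort$sample_meta$sample_id), ]
  cbind(age = meta$age, sex = as.integer(meta$sex == "F"),
        log_n_cells = log(as.numeric(table(
          factor(cohort$cell_table$sample_id[cell_sel], samples)))))
}

# brute-force agglomerative Ward clustering via the Lance-Williams update,
# on squared Euclidean distances (ward.D2 convention: heights are sqrt of
# the merge criterion); independent oracle for hclust
ward_oracle <- function(x) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  active <- seq_len(n)
  sizes <- rep(1L, n)
  heights <- numeric(n - 1L)
  merges <- matrix(0L, n - 1L, 2L)
  id <- -seq_len(n)  # hclust convention: negative = singleton
  for (step in seq_len(n - 1L)) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(active)[-length(active)]) {
      for (b in seq((a + 1L), length(active))) {
        if (d2[active[a], active[b]] < best[1])
          best <- c(d2[active[a], active[b]], a, b)
      }
    }
    a <- best[2]; b <- best[3]
    ia <- active[a]; ib <- active[b]
    heights[step] <- sqrt(best[1])
    merges[step, ] <- sort(c(id[ia], id[ib]))
    # Lance-Williams Ward update against every other active cluster
    for (k in seq_along(active)) {
      ik <- active[k]
      if (ik %in% c(ia, ib)) next
      nk <- sizes[ik]; ni <- sizes[ia]; nj <- sizes[ib]
      d2[ia, ik] <- d2[ik, ia] <-
        ((ni + nk) * d2[ia, ik] + (nj + nk) * d2[ib, ik] -
           nk * d2[ia, ib]) / (ni + nj + nk)
    }
    sizes[ia] <- sizes[ia] + sizes[ib]
    id[ia] <- step
    active <- active[-b]
  }
  list(heights = heights, merges = merges)
}

# brute-force NAM by explicit dense matrix powers
nam_oracle <- function(adjacency, sample_ids, steps) {
  W <- as.matrix(adjacency) / rowSums(as.matrix(adjacency))
  samples <- unique(sample_ids)
  D <- t(vapply(samples, function(s) {
    v <- as.numeric(sample_ids == s)
    v / sum(v)
  }, numeric(length(sample_ids))))
  M <- D
  for (i in seq_len(steps)) M <- M %*% W
  M
}
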