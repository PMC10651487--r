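#' Per-sample cell-type composition from a cell table
#'
#' Counts cells of each canonical lineage within each sample and divides by
#' the sample's cell total. Samples with fewer than `min_cells` cells are
#' excluded with a warning (low-yield biopsies give unreliable proportions).
#'
#' @param cell_table Data frame with `sample_id` and `cell_type` columns;
#'   cell types must be canonical ([canonical_types()]).
#' @param min_cells Minimum cells per retained sample (default 1; the
#'   pipeline default for real-scale data is 100).
#' @return A [as_composition()] matrix with an `n_cells` attribute.
#' @export
compute_composition <- function(cell_table, min_cells = 1L) {
  types <- canonical_types()
  bad <- setdiff(unique(cell_table$cell_type), types)
  if (length(bad))
    stop("unknown cell type(s): ", paste(bad, collapse = ", "),
         "; expected ", paste(types, collapse = ", "))
  tab <- table(cell_table$sample_id, factor(cell_table$cell_type, types))
  n_cells <- rowSums(tab)
  drop <- n_cells < min_cells
  if (any(drop)) {
    warning("excluding ", sum(drop), " sample(s) with < ", min_cells,
            " cells: ", paste(rownames(tab)[drop], collapse = ", "))
    tab <- tab[!drop, , drop = FALSE]
    n_cells <- n_cells[!drop]
  }
  if (!nrow(tab)) stop("no samples left after the cell-count filter")
  comp <- as_composition(sweep(unclass(tab), 1, rowSums(tab), "/"))
  attr(comp, "n_cells") <- n_cells
  comp
}

# Ward (ward.D2) clustering of composition rows, cut at k
cut_ward <- function(comp, k) {
  hc <- stats::hclust(stats::dist(unclass(comp)), method = "ward.D2")
  list(tree = hc, labels = stats::cutree(hc, k))
}

#' Stratify samples into CTAPs by bootstrap-stable hierarchical clustering
#'
#' Ward-linkage agglomerative clustering (Euclidean distance on proportion
#' rows) is cut at every candidate `k`. For each `k`, stability is the mean
#' adjusted Rand index between the reference partition and the partitions of
#' `n_boot` bootstrap cohorts in which each sample's cells are resampled
#' with replacement (multinomial on its composition) and the matrix is
#' re-clustered. The chosen `k` maximizes stability among candidates whose
#' reference clusters all have at least `min_size` samples; ties go to the
#' smaller `k`. Clusters are then named with [name_ctaps()].
#'
#' @param comp Composition matrix (see [compute_composition()]).
#' @param k_range Candidate cluster numbers (default 2:8).
#' @param n_boot Bootstrap replicates (default 200).
#' @param min_size Minimum cluster size for an admissible `k` (default 3).
#' @param n_cells Per-sample cell counts used for the multinomial bootstrap;
#'   defaults to `attr(comp, "n_cells")`, else 2000 with a warning.
#' @param resample_samples Logical; the default `TRUE` draws bootstrap
#'   cohorts by resampling samples with replacement in addition to the
#'   within-sample cell resampling (samples are the replication unit that
#'   makes coarse merges unstable). `FALSE` keeps the sample set fixed and
#'   perturbs compositions only through cell resampling.
#' @param k Optional override: skip selection and cut at this `k`.
#' @param z_threshold Passed to [name_ctaps()].
#' @param seed Seed for the bootstrap.
#' @return Object of class `ctap_model`: linkage tree, stability profile,
#'   chosen `k`, per-sample labels, per-CTAP centroids and names.
#' @export
cluster_samples <- function(comp, k_range = 2:8, n_boot = 200L, min_size = 3L,
                            n_cells = NULL, resample_samples = TRUE, k = NULL,
                            z_threshold = 0.5, seed = 1L) {
  comp <- as_composition(unclass(comp), tol = 1e-6)
  n <- nrow(comp)
  if (is.null(k)) {
    if (n < max(k_range)) stop("need at least max(k_range) samples")
    if (n_boot < 1L) stop("n_boot must be >= 1")
    if (max(k_range) * min_size > n)
      stop("k_range infeasible: ", max(k_range), " clusters of >= ", min_size,
           " samples need more than ", n, " samples")
  }
  if (is.null(n_cells)) n_cells <- attr(comp, "n_cells")
  if (is.null(n_cells)) {
    warning("no per-sample cell counts supplied; bootstrap assumes 2000 cells")
    n_cells <- rep(2000L, n)
  }
  n_cells <- rep_len(n_cells, n)

  hc <- stats::hclust(stats::dist(unclass(comp)), method = "ward.D2")
  stability <- NULL
  if (is.null(k)) {
    # bootstrap cohorts: samples resampled with replacement, and each
    # resampled sample's cells resampled (multinomial on its composition);
    # the reference partition restricted to the drawn samples is compared
    # with the re-clustered bootstrap partition
    set.seed(seed)
    boot_idx <- vector("list", n_boot)
    boot_parts <- vector("list", n_boot)
    for (b in seq_len(n_boot)) {
      idx <- if (resample_samples) sample.int(n, replace = TRUE) else
        seq_len(n)
      bc <- t(vapply(idx, function(i) {
        drop(stats::rmultinom(1, n_cells[i], comp[i, ])) / n_cells[i]
      }, numeric(ncol(comp))))
      boot_idx[[b]] <- idx
      boot_parts[[b]] <- stats::hclust(stats::dist(bc), method = "ward.D2")
    }
    stability <- vapply(k_range, function(kk) {
      ref <- stats::cutree(hc, kk)
      mean(vapply(seq_len(n_boot), function(b)
        adjusted_rand_index(ref[boot_idx[[b]]],
                            stats::cutree(boot_parts[[b]], kk)),
        numeric(1)))
    }, numeric(1))
    names(stability) <- as.character(k_range)
    feasible <- vapply(k_range, function(kk)
      min(table(stats::cutree(hc, kk))) >= min_size, logical(1))
    if (!any(feasible))
      stop("no candidate k satisfies the minimum cluster size ", min_size)
    cand <- k_range[feasible]
    st <- stability[feasible]
    k <- cand[which(st == max(st))[1]]  # candidates ascending: tie -> smaller k
  }
  labels <- stats::cutree(hc, k)
  centroids <- do.call(rbind, lapply(seq_len(k), function(g)
    colMeans(comp[labels == g, , drop = FALSE])))
  rownames(centroids) <- paste0("cluster_", seq_len(k))
  model <- structure(list(linkage = hc, stability = stability, k = k,
                          labels = labels, centroids = centroids,
                          names = NULL, z_threshold = z_threshold,
                          types = colnames(comp)),
                     class = "ctap_model")
  model$names <- name_ctaps(model, comp, z_threshold)
  rownames(model$centroids) <- model$names
  model
}

#' Name CTAPs by relatively enriched lineages
#'
#' For each cluster and lettered lineage (E = endothelial, F = stromal,
#' M = myeloid, T = T, B = B/plasma; NK carries no letter), the enrichment
#' z-score is (cluster mean - cohort mean) / cohort sd of the proportion.
#' Letters with z above `z_threshold` form the name; if none pass, the
#' single highest-z letter is used. Selected letters are displayed in the
#' conventional precedence T, E, F, M, B.
#'
#' @param model A `ctap_model`.
#' @param comp The composition matrix the model was fitted on.
#' @param z_threshold Enrichment threshold (default 0.5).
#' @return Character vector of cluster names (length `model$k`).
#' @export
name_ctaps <- function(model, comp, z_threshold = 0.5) {
  letters_map <- type_letters()
  lettered <- names(letters_map)
  lettered <- lettered[lettered %in% colnames(comp)]
  mu <- colMeans(comp)
  sdv <- apply(comp, 2, stats::sd)
  degenerate <- lettered[sdv[lettered] == 0]
  if (length(degenerate)) {
    warning("zero cohort sd for type(s) ", paste(degenerate, collapse = ", "),
            "; skipped in naming")
    lettered <- setdiff(lettered, degenerate)
  }
  prec <- letter_precedence()
  vapply(seq_len(model$k), function(g) {
    cm <- colMeans(comp[model$labels == g, , drop = FALSE])
    z <- (cm[lettered] - mu[lettered]) / sdv[lettered]
    sel <- lettered[z > z_threshold]
    if (!length(sel)) sel <- lettered[which.max(z)]
    lt <- letters_map[sel]
    paste(lt[order(match(lt, prec))], collapse = "")
  }, character(1))
}

#' Assign new samples to the nearest CTAP centroid
#'
#' Euclidean distance in proportion space; ties are broken toward the
#' lowest-index CTAP and flagged.
#'
#' @param model A `ctap_model`.
#' @param comp_new Composition matrix with the model's cell-type columns in
#'   the model's order.
#' @return Data frame with `sample_id`, `ctap`, `distance`, `tie`; the full
#'   distance matrix is attached as attribute `"distances"`.
#' @export
project_samples <- function(model, comp_new) {
  comp_new <- unclass(comp_new)
  if (!identical(colnames(comp_new), model$types))
    stop("column order mismatch: expected ",
         paste(model$types, collapse = ", "))
  cent <- model$centroids
  d2 <- outer(rowSums(comp_new^2), rep(1, nrow(cent))) -
    2 * comp_new %*% t(cent) +
    outer(rep(1, nrow(comp_new)), rowSums(cent^2))
  d <- sqrt(pmax(d2, 0))
  best <- apply(d, 1, which.min)
  tie <- vapply(seq_len(nrow(d)), function(i)
    sum(abs(d[i, ] - d[i, best[i]]) < 1e-12) > 1L, logical(1))
  out <- data.frame(sample_id = rownames(comp_new),
                    ctap = model$names[best],
                    distance = d[cbind(seq_len(nrow(d)), best)],
                    tie = tie, stringsAsFactors = FALSE)
  attr(out, "distances") <- structure(d, dimnames = list(rownames(comp_new),
                                                         model$names))
  out
}

#' PCA of the composition matrix
#'
#' Principal components of the column-centred proportion matrix (no
#' scaling), as used to visualize sample-level composition structure.
#'
#' @param comp Composition matrix.
#' @return List with `scores` (samples x PCs), `loadings`, `var_frac`.
#' @export
composition_pca <- function(comp) {
  comp <- unclass(comp)
  if (nrow(comp) < 2L) stop("need at least 2 samples for PCA")
  pc <- stats::prcomp(comp, center = TRUE, scale. = FALSE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, var_frac = var_frac)
}

#' Categorize samples by cytokine pseudobulk expression
#'
#' Restricts a pseudobulk matrix to a cytokine gene panel, log1p-transforms
#' CPM, z-scores each gene across samples, Ward-clusters the samples at `k`,
#' and reports agreement (adjusted Rand index) with reference CTAP labels.
#'
#' @param pseudobulk Genes x samples matrix (CPM or raw; re-normalized to
#'   CPM internally).
#' @param cytokine_genes Gene ids of the panel (>= 2 must be present).
#' @param k Number of clusters.
#' @param ctap_labels Reference labels (named by sample or in column order).
#' @return List with `labels` (cytokine partition) and `ari`.
#' @export
cytokine_categorize <- function(pseudobulk, cytokine_genes, k, ctap_labels) {
  present <- intersect(cytokine_genes, rownames(pseudobulk))
  if (length(present) < 2L)
    stop("fewer than 2 of the listed cytokine genes are present")
  m <- sweep(pseudobulk, 2, colSums(pseudobulk), "/") * 1e6
  m <- log1p(m[present, , drop = FALSE])
  sdv <- apply(m, 1, stats::sd)
  m <- m[sdv > 0, , drop = FALSE]
  z <- t(scale(t(m)))
  hc <- stats::hclust(stats::dist(t(z)), method = "ward.D2")
  labels <- stats::cutree(hc, k)
  if (!is.null(names(ctap_labels)))
    ctap_labels <- ctap_labels[colnames(pseudobulk)]
  list(labels = labels, ari = adjusted_rand_index(labels, ctap_labels))
}

#' @export
print.ctap_model <- function(x, ...) {
  cat("ctap_model: k =", x$k, "(", paste(x$names, collapse = ", "), ")\n")
  if (!is.null(x$stability)) {
    cat("stability profile:\n")
    print(round(x$stability, 3))
  }
  cat("cluster sizes:", paste(tabulate(x$labels, x$k), collapse = ", "), "\n")
  invisible(x)
}
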