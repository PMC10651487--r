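#' Nearest-neighbour CTAP classifier for composition panels
#'
#' Assigns each test sample the label of its nearest training sample
#' (Euclidean distance in proportion space; `n_neighbors > 1` uses a
#' majority vote). Ties go to the smaller training index and are flagged.
#'
#' @param train_comp,test_comp Composition matrices sharing cell-type
#'   columns in the same order.
#' @param train_labels Labels aligned with `train_comp` rows.
#' @param n_neighbors Number of neighbours (default 1).
#' @return Data frame with `sample_id`, `label`, `tie`.
#' @export
flow_nn_classify <- function(train_comp, train_labels, test_comp,
                             n_neighbors = 1L) {
  train_comp <- unclass(train_comp); test_comp <- unclass(test_comp)
  if (!nrow(train_comp)) stop("empty training set")
  if (!identical(colnames(train_comp), colnames(test_comp)))
    stop("train and test must share cell-type columns in the same order")
  if (length(train_labels) != nrow(train_comp))
    stop("train_labels length mismatch")
  d <- sqrt(pmax(outer(rowSums(test_comp^2), rep(1, nrow(train_comp))) -
                   2 * test_comp %*% t(train_comp) +
                   outer(rep(1, nrow(test_comp)), rowSums(train_comp^2)), 0))
  out <- lapply(seq_len(nrow(d)), function(i) {
    ord <- order(d[i, ])
    nn <- ord[seq_len(n_neighbors)]
    votes <- table(train_labels[nn])
    win <- names(votes)[votes == max(votes)]
    tie <- length(win) > 1L ||
      (n_neighbors == 1L &&
         sum(abs(d[i, ] - d[i, nn[1]]) < 1e-12) > 1L)
    lab <- if (length(win) > 1L) {
      train_labels[nn][match(TRUE, train_labels[nn] %in% win)]
    } else win
    data.frame(label = lab, tie = tie, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  data.frame(sample_id = rownames(test_comp) %||% seq_len(nrow(d)),
             label = out$label, tie = out$tie, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Leave-one-out accuracy of the composition nearest-neighbour classifier
#'
#' @inheritParams flow_nn_classify
#' @return Fraction of training samples whose held-out prediction matches
#'   their label.
#' @export
flow_loo_accuracy <- function(train_comp, train_labels, n_neighbors = 1L) {
  train_comp <- unclass(train_comp)
  if (!nrow(train_comp)) stop("empty training set")
  preds <- vapply(seq_len(nrow(train_comp)), function(i) {
    flow_nn_classify(train_comp[-i, , drop = FALSE], train_labels[-i],
                     train_comp[i, , drop = FALSE],
                     n_neighbors = n_neighbors)$label
  }, character(1))
  mean(preds == train_labels)
}

#' Derive per-lineage expression signatures from single-cell counts
#'
#' Each cell is normalized to counts per million; the signature profile of
#' a lineage is the mean CPM vector over its cells (so each profile sums to
#' one million). Markers are the top genes per lineage by one-vs-rest
#' log2 fold change among genes above an expression floor.
#'
#' @param counts Sparse genes x cells counts.
#' @param cell_table Data frame with `cell_type` per cell (column order
#'   matching `counts`).
#' @param n_markers Markers per lineage (default 50).
#' @param expr_floor Minimum profile CPM for marker eligibility (default 1).
#' @param min_lfc Minimum one-vs-rest log2 fold change for marker
#'   eligibility (default 1, i.e. two-fold); keeps non-discriminative genes
#'   out of the deconvolution basis.
#' @return Object of class `ctap_signatures`: `profiles` (genes x types),
#'   `markers` (named list per type).
#' @export
derive_signatures <- function(counts, cell_table, n_markers = 50L,
                              expr_floor = 1, min_lfc = 1) {
  types <- intersect(canonical_types(), unique(cell_table$cell_type))
  lib <- Matrix::colSums(counts)
  if (any(lib == 0)) stop("cells with zero total counts")
  cpm <- counts %*% Matrix::Diagonal(x = 1e6 / lib)
  profiles <- vapply(types, function(ty) {
    sel <- cell_table$cell_type == ty
    if (sum(sel) < 20L)
      warning("cell type ", ty, " has fewer than 20 cells; profile is noisy")
    Matrix::rowSums(cpm[, sel, drop = FALSE]) / sum(sel)
  }, numeric(nrow(counts)))
  rownames(profiles) <- rownames(counts)
  lib_size <- vapply(types, function(ty)
    mean(lib[cell_table$cell_type == ty]), numeric(1))
  markers <- lapply(types, function(ty) {
    others <- rowMeans(profiles[, setdiff(types, ty), drop = FALSE])
    lfc <- log2((profiles[, ty] + 1) / (others + 1))
    eligible <- profiles[, ty] >= expr_floor & lfc >= min_lfc
    if (!any(eligible)) eligible <- profiles[, ty] >= expr_floor
    top <- order(ifelse(eligible, lfc, -Inf), decreasing = TRUE)
    rownames(profiles)[top[seq_len(min(n_markers, sum(eligible)))]]
  })
  names(markers) <- types
  # fine-state profiles (when labelled) let the deconvolution absorb
  # within-lineage state-mixture shifts between samples
  state_profiles <- NULL; state_type <- NULL; state_lib <- NULL
  if ("state" %in% names(cell_table)) {
    states <- unique(cell_table$state)
    state_profiles <- vapply(states, function(s) {
      sel <- cell_table$state == s
      Matrix::rowSums(cpm[, sel, drop = FALSE]) / sum(sel)
    }, numeric(nrow(counts)))
    rownames(state_profiles) <- rownames(counts)
    state_type <- vapply(states, function(s)
      cell_table$cell_type[match(s, cell_table$state)], character(1))
    state_lib <- vapply(states, function(s)
      mean(lib[cell_table$state == s]), numeric(1))
  }
  structure(list(profiles = profiles, markers = markers,
                 lib_size = lib_size, state_profiles = state_profiles,
                 state_type = state_type, state_lib_size = state_lib),
            class = "ctap_signatures")
}

# Lawson-Hanson non-negative least squares (active set); A is small here
# (markers x 6), so the dense normal-equation solves are cheap.
nnls_fit <- function(A, b, tol = 1e-10, max_iter = NULL) {
  p <- ncol(A)
  if (is.null(max_iter)) max_iter <- 3L * p
  x <- rep(0, p)
  passive <- rep(FALSE, p)
  w <- crossprod(A, b - A %*% x)
  iter <- 0L
  while (any(!passive) && any(w[!passive] > tol) && iter < max_iter * 10L) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- rep(0, p)
      Ap <- A[, passive, drop = FALSE]
      s[passive] <- drop(solve(crossprod(Ap), crossprod(Ap, b)))
      if (all(s[passive] > tol)) { x <- s; break }
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  x
}

#' Estimate lineage compositions from bulk expression by NNLS deconvolution
#'
#' Restricts the bulk matrix and the signature profiles to their shared
#' marker genes, CPM-normalizes each bulk sample, solves a non-negative
#' least-squares regression of the sample on the lineage profiles, and
#' closes the coefficients to sum 1. When the signatures carry per-type
#' mean library sizes the RNA-fraction coefficients are converted to cell
#' fractions (divided by mean library size, then re-closed): lineages with
#' more RNA per cell otherwise look over-abundant in bulk mixtures.
#'
#' @param bulk Genes x samples matrix (raw counts or CPM).
#' @param signatures A [derive_signatures()] result.
#' @param min_shared Minimum shared marker genes required (default 50).
#' @return Estimated [as_composition()] matrix (samples x types).
#' @export
bulk_deconvolve <- function(bulk, signatures, min_shared = 50L) {
  markers <- unique(unlist(signatures$markers))
  shared <- intersect(markers, rownames(bulk))
  if (length(shared) < min_shared)
    stop("only ", length(shared), " marker genes shared with the bulk matrix",
         " (need >= ", min_shared, ")")
  tot <- colSums(bulk)
  zero <- colnames(bulk)[tot == 0]
  if (length(zero))
    stop("all-zero bulk column(s): ", paste(zero, collapse = ", "))
  cpm <- sweep(bulk, 2, tot, "/") * 1e6
  fine <- !is.null(signatures$state_profiles)
  A <- if (fine) signatures$state_profiles[shared, , drop = FALSE] else
    signatures$profiles[shared, , drop = FALSE]
  lib <- if (fine) signatures$state_lib_size else signatures$lib_size
  est <- t(apply(cpm[shared, , drop = FALSE], 2, function(b) {
    x <- nnls_fit(A, b)
    if (sum(x) == 0) stop("deconvolution produced an all-zero fit")
    if (!is.null(lib)) x <- x / lib[colnames(A)]
    if (fine) x <- vapply(colnames(signatures$profiles), function(ty)
      sum(x[signatures$state_type[colnames(A)] == ty]), numeric(1))
    x / sum(x)
  }))
  colnames(est) <- colnames(signatures$profiles)
  full <- matrix(0, nrow(est), length(canonical_types()),
                 dimnames = list(rownames(est), canonical_types()))
  full[, colnames(est)] <- est
  as_composition(full)
}

#' Classify bulk RNA-seq samples into CTAPs
#'
#' [bulk_deconvolve()] followed by [project_samples()] against the fitted
#' CTAP centroids.
#'
#' @inheritParams bulk_deconvolve
#' @param ctap_model A `ctap_model`.
#' @return The [project_samples()] data frame.
#' @export
bulk_classify <- function(bulk, signatures, ctap_model, min_shared = 50L) {
  est <- bulk_deconvolve(bulk, signatures, min_shared = min_shared)
  project_samples(ctap_model, est[, ctap_model$types, drop = FALSE])
}

# percentages are reported half-up (62.5 -> 63), the usual print convention
round_half_up <- function(x) floor(x + 0.5)

#' Summarize CTAP transitions between two timepoints
#'
#' Pairs samples by id, tabulates baseline x follow-up CTAP counts and the
#' fraction of pairs that changed CTAP (percentages rounded to integers).
#' Among changed pairs, the modal follow-up CTAP and its rounded percentage
#' are reported; with `arm`, per-arm breakdowns are included.
#'
#' @param labels_t0,labels_t1 Named label vectors (names = sample ids).
#' @param arm Optional named treatment-arm vector.
#' @return Object of class `ctap_transitions`: `matrix`, `n_pairs`,
#'   `n_changed`, `percent_changed`, `modal_followup`,
#'   `modal_followup_n`, `modal_followup_percent`, `by_arm`.
#' @export
transition_summary <- function(labels_t0, labels_t1, arm = NULL) {
  if (is.null(names(labels_t0)) || is.null(names(labels_t1)))
    stop("labels must be named by sample id")
  ids <- intersect(names(labels_t0), names(labels_t1))
  unmatched <- c(setdiff(names(labels_t0), ids), setdiff(names(labels_t1), ids))
  if (length(unmatched))
    warning("excluding unmatched sample(s): ", paste(unmatched, collapse = ", "))
  if (!length(ids)) stop("no paired ids present at both timepoints")
  t0 <- as.character(labels_t0[ids]); t1 <- as.character(labels_t1[ids])
  lev <- sort(unique(c(t0, t1)))
  tab <- table(factor(t0, lev), factor(t1, lev), dnn = c("baseline", "followup"))
  changed <- t0 != t1
  n_changed <- sum(changed)
  modal <- NA_character_; modal_n <- 0L; modal_pct <- NA_real_
  if (n_changed) {
    ft <- table(t1[changed])
    modal <- names(ft)[which.max(ft)]
    modal_n <- as.integer(max(ft))
    modal_pct <- round_half_up(100 * modal_n / n_changed)
  }
  by_arm <- NULL
  if (!is.null(arm)) {
    arm <- arm[ids]
    by_arm <- lapply(split(seq_along(ids), arm), function(idx) {
      nc <- sum(changed[idx])
      list(n_pairs = length(idx), n_changed = nc,
           percent_changed = round_half_up(100 * nc / length(idx)))
    })
  }
  structure(list(matrix = unclass(tab), n_pairs = length(ids),
                 n_changed = n_changed,
                 percent_changed = round_half_up(100 * n_changed / length(ids)),
                 modal_followup = modal, modal_followup_n = modal_n,
                 modal_followup_percent = modal_pct, by_arm = by_arm),
            class = "ctap_transitions")
}

#' @export
print.ctap_transitions <- function(x, ...) {
  cat("ctap_transitions:", x$n_changed, "of", x$n_pairs, "pairs changed (",
      x$percent_changed, "%)\n")
  if (!is.na(x$modal_followup))
    cat("modal follow-up among changed:", x$modal_followup,
        paste0("(", x$modal_followup_percent, "%)\n"))
  invisible(x)
}
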