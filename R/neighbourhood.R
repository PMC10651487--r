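#' Build a symmetric kNN neighbourhood graph on an embedding
#'
#' k nearest neighbours (Euclidean) symmetrized by union, with self-loops;
#' the transition matrix is the row-normalized adjacency. Connected
#' components are reported so callers can detect disconnected manifolds.
#'
#' @param embedding Numeric matrix cells x d with unique rownames (cell
#'   ids) and finite coordinates.
#' @param k Number of neighbours (>= 1, < number of cells).
#' @return Object of class `ctap_graph`: `cell_ids`, `adjacency` (sparse,
#'   0/1 with self-loops), `transition` (row-stochastic), `n_components`,
#'   `component` (per-cell component id).
#' @export
build_graph <- function(embedding, k = 30L) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  ids <- rownames(embedding)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (anyDuplicated(ids)) stop("duplicate cell ids in embedding rownames")
  if (!all(is.finite(embedding))) stop("embedding has non-finite coordinates")
  if (k >= n) stop("k must be smaller than the number of cells")
  nn <- FNN::get.knn(embedding, k = k)$nn.index
  i <- rep(seq_len(n), k)
  j <- as.vector(nn)
  adj <- Matrix::sparseMatrix(i = c(i, j, seq_len(n)),
                              j = c(j, i, seq_len(n)),
                              x = 1, dims = c(n, n), use.last.ij = FALSE)
  adj@x[] <- 1  # union symmetrization: collapse duplicate edges to weight 1
  adj <- methods::as(adj, "CsparseMatrix")
  trans <- adj / Matrix::rowSums(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  structure(list(cell_ids = ids, adjacency = adj, transition = trans,
                 n_components = comp$no, component = comp$membership),
            class = "ctap_graph")
}

#' Neighbourhood abundance matrix (NAM)
#'
#' Starts from the samples x cells membership matrix D (1/n_s for cells of
#' sample s) and diffuses it `steps` times through the graph's
#' row-stochastic transition matrix; each row stays a probability
#' distribution over cells. Columns are then standardized to mean 0, sd 1
#' across samples (zero-variance columns are set to 0).
#'
#' @param graph A [build_graph()] result.
#' @param sample_ids Per-cell sample ids aligned with `graph$cell_ids`.
#' @param steps Diffusion steps (>= 1), or `"auto"` to keep diffusing until
#'   the median column kurtosis of the raw NAM falls below `kurtosis_stop`
#'   (the usual smoothness heuristic for neighbourhood abundance scores),
#'   up to `max_steps`.
#' @param kurtosis_stop,max_steps Parameters of the `"auto"` rule.
#' @return List with `nam` (standardized samples x cells), `nam_raw`
#'   (pre-standardization), `samples`, `steps` (the number actually used).
#' @export
compute_nam <- function(graph, sample_ids, steps = "auto",
                        kurtosis_stop = 6, max_steps = 30L) {
  auto <- identical(steps, "auto")
  if (!auto && steps < 1L) stop("steps must be >= 1")
  n <- length(graph$cell_ids)
  if (length(sample_ids) != n)
    stop("sample_ids length does not match the graph")
  samples <- unique(sample_ids)
  n_per <- table(factor(sample_ids, samples))
  if (any(n_per == 0)) stop("sample with zero cells")
  D <- Matrix::sparseMatrix(i = match(sample_ids, samples),
                            j = seq_len(n),
                            x = 1 / as.numeric(n_per[match(sample_ids, samples)]),
                            dims = c(length(samples), n))
  M <- D
  col_kurt <- function(m) {
    probe <- if (ncol(m) > 500L) {
      round(seq(1L, ncol(m), length.out = 500L))
    } else seq_len(ncol(m))
    x <- as.matrix(m[, probe, drop = FALSE])
    x <- sweep(x, 2, colMeans(x))
    v <- colMeans(x^2)
    stats::median(ifelse(v > 0, colMeans(x^4) / v^2, 0))
  }
  used <- 0L
  repeat {
    M <- M %*% graph$transition
    used <- used + 1L
    if (auto) {
      if (used >= max_steps || col_kurt(M) < kurtosis_stop) break
    } else if (used >= steps) break
  }
  nam_raw <- as.matrix(M)
  dimnames(nam_raw) <- list(samples, graph$cell_ids)
  nam <- scale(nam_raw)
  nam[, attr(nam, "scaled:scale") == 0] <- 0
  attr(nam, "scaled:center") <- NULL
  attr(nam, "scaled:scale") <- NULL
  list(nam = nam, nam_raw = nam_raw, samples = samples, steps = used)
}

# residualize columns of v on covariate design X (with intercept)
residualize <- function(qr_x, v) {
  as.matrix(qr.resid(qr_x, as.matrix(v)))
}

# correlations of (column-centred) NAM columns with a centred vector;
# one cells x samples product per call — the dominant permutation cost
ncorr_against <- function(nam_res, col_norms, y) {
  yn <- sqrt(sum(y^2))
  if (yn == 0) return(rep(0, ncol(nam_res)))
  r <- as.vector(crossprod(nam_res, y)) / (col_norms * yn)
  r[col_norms == 0] <- 0
  pmin(pmax(r, -1), 1)
}

#' Covarying-neighbourhood association test
#'
#' Tests whether a per-sample phenotype is associated with the single-cell
#' neighbourhood abundance structure. Phenotype and NAM columns are
#' residualized on the covariates (linear projection with intercept). The
#' residualized NAM is decomposed into principal components; for each
#' m = 1..M (M = min(floor(n/2), `n_components`)) the R-squared of the
#' phenotype on the first m components is computed and the test statistic
#' is its maximum over m. The global p-value is a Westfall-Young permutation
#' p (phenotype permuted across samples, the max taken inside every
#' permutation). Per-cell neighbourhood correlations `ncorr` are Pearson
#' correlations of the residualized NAM columns with the residualized
#' phenotype; per-cell significance uses an empirical-null FDR over the
#' permutation |ncorr| distribution at level `q`.
#'
#' @param nam A [compute_nam()] result (or a samples x cells matrix).
#' @param phenotype Per-sample numeric (or 0/1 indicator), aligned with the
#'   NAM rows.
#' @param covariates Optional per-sample numeric matrix / data frame (e.g.
#'   age, sex indicator, log cell count); must be full rank.
#' @param n_components Maximum NAM components to consider (default 10).
#' @param n_perm Permutations (>= 20; default 1000).
#' @param q FDR level for the per-cell mask (default 0.05).
#' @param seed Permutation seed.
#' @return Object of class `ctap_assoc`: `ncorr`, `mask` (logical, FDR < q),
#'   `fdr_threshold`, `global_p`, `m_star`, `r2_profile`, `statistic`,
#'   `n_perm`, `q`, `covariates_used`.
#' @export
associate <- function(nam, phenotype, covariates = NULL, n_components = 10L,
                      n_perm = 1000L, q = 0.05, seed = 1L) {
  if (is.list(nam)) nam <- nam$nam
  n <- nrow(nam)
  if (n < 6L) stop("need at least 6 samples")
  if (n_perm < 20L) stop("n_perm must be >= 20")
  phenotype <- as.numeric(phenotype)
  if (length(phenotype) != n) stop("phenotype length must match NAM rows")
  if (stats::sd(phenotype) == 0) stop("phenotype has no variance")

  X <- cbind(intercept = rep(1, n))
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates))
    storage.mode(cv) <- "double"
    X <- cbind(X, cv)
    if (qr(X)$rank < ncol(X)) stop("covariates are not full rank")
  }
  qr_x <- qr(X)
  y <- drop(residualize(qr_x, phenotype))
  if (stats::sd(y) < 1e-12)
    stop("phenotype has no variance after covariate adjustment")
  nam_res <- residualize(qr_x, nam)

  # PCA of the residualized NAM via the small sample-space Gram matrix
  gram <- tcrossprod(nam_res)
  eig <- eigen(gram, symmetric = TRUE)
  pos <- eig$values > max(eig$values) * 1e-10
  U <- eig$vectors[, pos, drop = FALSE]
  M <- min(floor(n / 2), n_components, ncol(U))
  if (M < 1L) stop("no usable NAM components")
  U <- U[, seq_len(M), drop = FALSE]

  r2_profile <- function(yv) {
    ssy <- sum(yv^2)
    cumsum(as.vector(crossprod(U, yv))^2) / ssy
  }
  r2 <- r2_profile(y)
  statistic <- max(r2)
  m_star <- which.max(r2)

  col_norms <- sqrt(colSums(nam_res^2))
  ncorr <- ncorr_against(nam_res, col_norms, y)

  set.seed(seed)
  obs_abs_sorted <- sort(abs(ncorr))
  null_ge <- numeric(length(obs_abs_sorted))
  perm_stats <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    yp <- drop(residualize(qr_x, phenotype[sample.int(n)]))
    if (stats::sd(yp) < 1e-12) { perm_stats[b] <- 0; next }
    proj <- as.vector(crossprod(U, yp))
    r2p <- cumsum(proj^2) / sum(yp^2)
    perm_stats[b] <- max(r2p)
    ncp <- abs(ncorr_against(nam_res, col_norms, yp))
    # for each observed threshold t: how many permuted |ncorr| >= t
    sp <- sort(ncp)
    null_ge <- null_ge +
      (length(sp) - findInterval(obs_abs_sorted, sp, left.open = TRUE))
  }
  global_p <- (1 + sum(perm_stats >= statistic - 1e-12)) / (n_perm + 1)

  n_obs_ge <- length(obs_abs_sorted) - seq_along(obs_abs_sorted) + 1L
  fdr <- (null_ge / n_perm) / n_obs_ge
  pass <- which(fdr <= q)
  if (length(pass)) {
    thr <- obs_abs_sorted[min(pass)]
    mask <- abs(ncorr) >= thr
  } else {
    thr <- Inf
    mask <- rep(FALSE, length(ncorr))
  }
  names(ncorr) <- colnames(nam)
  names(mask) <- colnames(nam)
  structure(list(ncorr = ncorr, mask = mask, fdr_threshold = thr,
                 global_p = global_p, m_star = m_star, r2_profile = r2,
                 statistic = statistic, n_perm = n_perm, q = q,
                 covariates_used = colnames(X)[-1]),
            class = "ctap_assoc")
}

#' Summarize neighbourhood associations by cell state
#'
#' For every fine state, the fraction of its cells whose neighbourhood
#' correlation is FDR-significant in the positive and in the negative
#' direction, alongside the global permutation p of the run.
#'
#' @param result A [associate()] result.
#' @param state_labels Per-cell state labels aligned with `result$ncorr`;
#'   no missing values allowed.
#' @return Data frame: state, n_cells, frac_positive, frac_negative,
#'   global_p.
#' @export
summarize_by_state <- function(result, state_labels) {
  if (length(state_labels) != length(result$ncorr))
    stop("state_labels length does not match the association result")
  if (anyNA(state_labels)) stop("unknown (missing) state label")
  states <- unique(as.character(state_labels))
  rows <- lapply(states, function(s) {
    sel <- state_labels == s
    data.frame(state = s, n_cells = sum(sel),
               frac_positive = mean(result$mask[sel] & result$ncorr[sel] > 0),
               frac_negative = mean(result$mask[sel] & result$ncorr[sel] < 0),
               global_p = result$global_p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.ctap_assoc <- function(x, ...) {
  cat("ctap_assoc: global p =", format(x$global_p, digits = 3),
      "| components used =", x$m_star,
      "| significant cells =", sum(x$mask), "/", length(x$mask),
      "(FDR <", x$q, ")\n")
  invisible(x)
}
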