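#' Variance in an outcome explained by CTAP membership
#'
#' Incremental R-squared of adding the CTAP factor to a covariate-only
#' linear model, with the p-value from the nested F-test (ANOVA). Missing
#' values are dropped by complete-case analysis with a logged count.
#'
#' @param outcome Per-sample numeric outcome.
#' @param ctap_labels Per-sample CTAP labels (>= 2 CTAPs with >= 2 samples).
#' @param covariates Optional per-sample data frame / matrix.
#' @return List with `fraction` (incremental R-squared in \[0,1\]), `p`,
#'   `degenerate` (TRUE when the full model fits perfectly and the F test
#'   is undefined), `n_used`, `n_dropped`.
#' @export
variance_explained <- function(outcome, ctap_labels, covariates = NULL) {
  df <- data.frame(.y = as.numeric(outcome),
                   .ctap = factor(ctap_labels))
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  keep <- stats::complete.cases(df)
  n_dropped <- sum(!keep)
  if (n_dropped) message("variance_explained: dropping ", n_dropped,
                         " incomplete sample(s)")
  df <- df[keep, , drop = FALSE]
  tab <- table(droplevels(df$.ctap))
  if (length(tab) < 2L || sum(tab >= 2L) < 2L)
    stop("need at least 2 CTAPs with at least 2 samples each")
  covar_terms <- setdiff(names(df), c(".y", ".ctap"))
  f0 <- if (length(covar_terms)) {
    stats::as.formula(paste(".y ~", paste(covar_terms, collapse = " + ")))
  } else .y ~ 1
  f1 <- stats::update(f0, . ~ . + .ctap)
  m0 <- stats::lm(f0, df)
  m1 <- stats::lm(f1, df)
  if (anyNA(stats::coef(m1))) {
    aliased <- names(stats::coef(m1))[is.na(stats::coef(m1))]
    stop("rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "))
  }
  tss <- sum((df$.y - mean(df$.y))^2)
  fraction <- (stats::deviance(m0) - stats::deviance(m1)) / tss
  degenerate <- stats::deviance(m1) < 1e-10 * tss
  p <- if (degenerate) NA_real_ else stats::anova(m0, m1)[2, "Pr(>F)"]
  if (degenerate)
    warning("full model fits perfectly; nested F test is degenerate")
  list(fraction = fraction, p = p, degenerate = degenerate,
       n_used = nrow(df), n_dropped = n_dropped)
}

#' Pearson correlation between two per-sample proportions
#'
#' Standard Pearson r with a two-sided t-test on n - 2 degrees of freedom.
#'
#' @param prop_a,prop_b Numeric vectors of equal length (n >= 3, both with
#'   positive variance).
#' @return List with `r`, `p`, `n`.
#' @export
proportion_correlation <- function(prop_a, prop_b) {
  keep <- stats::complete.cases(prop_a, prop_b)
  a <- prop_a[keep]; b <- prop_b[keep]
  if (length(a) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("zero variance input")
  ct <- stats::cor.test(a, b, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}

#' Filter genes with low counts within a cell type
#'
#' A gene is analyzable in a cell type when the fraction of that type's
#' cells with more than one UMI of the gene is at least `min_frac`
#' (boundary included).
#'
#' @param counts Sparse or dense genes x cells counts.
#' @param cell_type_mask Logical or integer index of the cells of the type.
#' @param min_frac Minimum fraction (default 0.05).
#' @return Character vector of analyzable gene ids.
#' @export
filter_low_count_genes <- function(counts, cell_type_mask, min_frac = 0.05) {
  sub <- counts[, cell_type_mask, drop = FALSE]
  if (!ncol(sub)) stop("empty cell mask")
  frac <- Matrix::rowSums(sub > 1) / ncol(sub)
  rownames(counts)[frac >= min_frac]
}

# equal-occupancy mean-expression bins over genes
expression_bins <- function(mean_expr, n_bins) {
  br <- unique(stats::quantile(mean_expr, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2L) return(rep(1L, length(mean_expr)))
  findInterval(mean_expr, br, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Correlation of a gene's expression with neighbourhood scores, with an
#' expression-matched permutation null
#'
#' Computes the Pearson correlation of the gene's per-cell normalized
#' expression with the per-cell neighbourhood correlation, and compares it
#' with correlations of `n_perm` genes drawn from the same mean-expression
#' bin (bins of equal gene occupancy; a bin with too few candidates is
#' widened to its neighbours with a warning). The p-value is one-sided for
#' positive correlation.
#'
#' @param expr Genes x cells normalized expression matrix.
#' @param gene Gene id to test (must have passed
#'   [filter_low_count_genes()]).
#' @param ncorr Per-cell neighbourhood correlations aligned with `expr`
#'   columns.
#' @param n_bins Number of equal-occupancy expression bins (default 10).
#' @param n_perm Null draws (default 1000; drawn with replacement when the
#'   bin holds fewer candidate genes).
#' @param exclude Gene ids to keep out of the matched-null candidate pool
#'   (e.g. the full risk-gene set under study, so candidate risk genes do
#'   not contaminate each other's nulls).
#' @param seed Seed.
#' @return Object of class `ctap_risk_gene`: `gene`, `r`, `p`, `tier`
#'   (`"p<0.01"`, `"0.01-0.05"`, `"ns"`), `bin`, `bin_mean`, `n_candidates`,
#'   `n_perm`.
#' @export
gene_score_correlation <- function(expr, gene, ncorr, n_bins = 10L,
                                   n_perm = 1000L, exclude = NULL,
                                   seed = 1L) {
  if (!gene %in% rownames(expr)) stop("gene not found: ", gene)
  x <- as.numeric(expr[gene, ])
  if (stats::sd(x) == 0) stop("zero variance expression for ", gene)
  r <- stats::cor(x, ncorr)
  mean_expr <- Matrix::rowMeans(expr)
  bins <- expression_bins(mean_expr, n_bins)
  g_bin <- bins[match(gene, rownames(expr))]
  candidates <- setdiff(rownames(expr)[bins == g_bin], c(gene, exclude))
  width <- 0L
  while (length(candidates) < min(n_perm, 20L) && width < n_bins) {
    width <- width + 1L
    candidates <- setdiff(
      rownames(expr)[abs(bins - g_bin) <= width], c(gene, exclude))
  }
  if (width > 0L)
    warning("expression bin widened by ", width, " on each side for ", gene)
  if (!length(candidates)) stop("no candidate genes for the matched null")
  set.seed(seed)
  # correlations of all candidates computed in one pass, then sampled
  cand_x <- expr[candidates, , drop = FALSE]
  cand_r <- suppressWarnings(
    as.vector(stats::cor(t(as.matrix(cand_x)), ncorr)))
  cand_r[is.na(cand_r)] <- 0
  null_r <- sample(cand_r, n_perm, replace = TRUE)
  p <- (1 + sum(null_r >= r)) / (n_perm + 1)
  tier <- if (p < 0.01) "p<0.01" else if (p < 0.05) "0.01-0.05" else "ns"
  structure(list(gene = gene, r = r, p = p, tier = tier, bin = g_bin,
                 bin_mean = mean(mean_expr[bins == g_bin]),
                 n_candidates = length(candidates), n_perm = n_perm),
            class = "ctap_risk_gene")
}

#' Count risk genes enriched in CTAP-associated neighbourhoods, with a
#' phenotype-permutation null
#'
#' Runs [gene_score_correlation()] for every risk gene over a grid of cell
#' types and CTAPs (per-cell ncorr supplied per type x CTAP), counting the
#' tests significant at `alpha`. The null repeats the same pipeline with
#' sample phenotype labels permuted: `ncorr_fun(phenotypes)` must rebuild
#' the per-type-per-CTAP ncorr lists from a (permuted) per-sample label
#' vector.
#'
#' @param expr_list Named list (per cell type) of genes x cells normalized
#'   expression matrices.
#' @param risk_genes Character vector of risk gene ids.
#' @param phenotypes Named per-sample phenotype labels.
#' @param ncorr_fun Function(phenotypes) -> named list per type of named
#'   lists per CTAP of per-cell ncorr vectors aligned with `expr_list`.
#' @param alpha Per-test significance level (default 0.05).
#' @param n_perm Null pipeline iterations (warning below 100).
#' @param n_perm_gene Null draws inside each gene test.
#' @param seed Seed.
#' @return List with `observed`, `null_counts`, `null_median`, `p`
#'   (fraction of null counts >= observed), `n_tests`.
#' @export
risk_gene_enrichment_count <- function(expr_list, risk_genes, phenotypes,
                                       ncorr_fun, alpha = 0.05,
                                       n_perm = 100L, n_perm_gene = 200L,
                                       seed = 1L) {
  if (n_perm < 100L)
    warning("n_perm < 100 limits the resolution of the permutation p")
  count_significant <- function(ncorr_lists, seed_offset) {
    cnt <- 0L; n_tests <- 0L
    for (ty in names(ncorr_lists)) {
      expr <- expr_list[[ty]]
      if (is.null(expr)) next
      genes <- intersect(risk_genes, rownames(expr))
      for (ctap in names(ncorr_lists[[ty]])) {
        nc <- ncorr_lists[[ty]][[ctap]]
        for (g in genes) {
          n_tests <- n_tests + 1L
          res <- tryCatch(
            suppressWarnings(gene_score_correlation(
              expr, g, nc, n_perm = n_perm_gene, exclude = risk_genes,
              seed = substream_seed(seed + seed_offset, paste(ty, ctap, g)))),
            error = function(e) NULL)
          if (!is.null(res) && res$p < alpha) cnt <- cnt + 1L
        }
      }
    }
    list(count = cnt, n_tests = n_tests)
  }
  obs_lists <- ncorr_fun(phenotypes)
  if (!length(obs_lists) || !length(unlist(obs_lists, recursive = FALSE)))
    stop("empty results grid")
  obs <- count_significant(obs_lists, 0L)
  if (obs$n_tests == 0L) stop("empty results grid")
  set.seed(seed)
  perms <- lapply(seq_len(n_perm), function(b) sample(phenotypes))
  null_counts <- vapply(seq_len(n_perm), function(b) {
    ph <- perms[[b]]
    names(ph) <- names(phenotypes)
    count_significant(ncorr_fun(ph), b)$count
  }, integer(1))
  list(observed = obs$count, null_counts = null_counts,
       null_median = stats::median(null_counts),
       p = (1 + sum(null_counts >= obs$count)) / (n_perm + 1),
       n_tests = obs$n_tests)
}

#' Association between treatment response and CTAP membership
#'
#' Logistic regression of the responder flag on the CTAP factor plus
#' covariates. The overall p comes from the likelihood-ratio test of the
#' CTAP term; per-CTAP odds ratios are from one-vs-rest logistic models
#' with Wald confidence intervals. Quasi-separation is flagged and a
#' ridge-penalized fallback fit (glmnet) reported when detected.
#'
#' @param ctap_labels Per-sample CTAP labels.
#' @param responder_flags Per-sample 0/1 (or logical) response indicator.
#' @param covariates Optional per-sample data frame (sex, age, treatment,
#'   CCP status, ...).
#' @param conf_level Wald CI level (default 0.95).
#' @return List with `overall_p`, `per_ctap` (data frame: ctap, or, ci_lo,
#'   ci_hi, p, separation), `n_used`, `n_dropped`.
#' @export
response_association <- function(ctap_labels, responder_flags,
                                 covariates = NULL, conf_level = 0.95) {
  df <- data.frame(.y = as.integer(responder_flags),
                   .ctap = factor(ctap_labels))
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  keep <- stats::complete.cases(df)
  if (any(!keep)) message("response_association: dropping ", sum(!keep),
                          " incomplete sample(s)")
  df <- df[keep, , drop = FALSE]
  df$.ctap <- droplevels(df$.ctap)
  covar_terms <- setdiff(names(df), c(".y", ".ctap"))
  f0 <- if (length(covar_terms)) {
    stats::as.formula(paste(".y ~", paste(covar_terms, collapse = " + ")))
  } else .y ~ 1
  f1 <- stats::update(f0, . ~ . + .ctap)
  m0 <- stats::glm(f0, stats::binomial(), df)
  m1 <- stats::glm(f1, stats::binomial(), df)
  overall_p <- stats::anova(m0, m1, test = "Chisq")[2, "Pr(>Chi)"]
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  per <- lapply(levels(df$.ctap), function(g) {
    d2 <- df; d2$.ind <- as.integer(d2$.ctap == g)
    f <- if (length(covar_terms)) {
      stats::as.formula(paste(".y ~ .ind +",
                              paste(covar_terms, collapse = " + ")))
    } else .y ~ .ind
    fit <- suppressWarnings(stats::glm(f, stats::binomial(), d2))
    beta <- stats::coef(fit)[".ind"]
    se <- sqrt(stats::vcov(fit)[".ind", ".ind"])
    separated <- !fit$converged || abs(beta) > 8 || se > 10
    if (separated) {
      pen <- penalized_logit_or(d2, covar_terms)
      beta <- pen$beta; se <- pen$se
    }
    data.frame(ctap = g, or = exp(beta),
               ci_lo = exp(beta - zq * se), ci_hi = exp(beta + zq * se),
               p = 2 * stats::pnorm(-abs(beta / se)),
               separation = separated, stringsAsFactors = FALSE)
  })
  list(overall_p = overall_p, per_ctap = do.call(rbind, per),
       n_used = nrow(df), n_dropped = sum(!keep))
}

# ridge-penalized logistic fallback for (quasi-)separated indicators
penalized_logit_or <- function(d2, covar_terms) {
  if (!requireNamespace("glmnet", quietly = TRUE))
    stop("glmnet is required for the penalized separation fallback")
  x <- stats::model.matrix(
    stats::as.formula(paste("~ .ind", if (length(covar_terms))
      paste("+", paste(covar_terms, collapse = " + ")) else "")), d2)[, -1,
                                                                     drop = FALSE]
  if (ncol(x) < 2L) x <- cbind(x, .pad = 0)  # glmnet needs >= 2 columns
  fit <- glmnet::glmnet(x, d2$.y, family = "binomial", alpha = 0,
                        lambda = 0.05, standardize = FALSE)
  beta <- as.numeric(stats::coef(fit))[1 + match(".ind", colnames(x))]
  # approximate SE from the penalized working weights
  eta <- drop(cbind(1, x) %*% as.numeric(stats::coef(fit)))
  mu <- stats::plogis(eta)
  W <- mu * (1 - mu)
  XtWX <- crossprod(cbind(1, x) * sqrt(W)) + diag(0.05 * nrow(x),
                                                  ncol(x) + 1)
  se <- sqrt(solve(XtWX)[1 + match(".ind", colnames(x)),
                         1 + match(".ind", colnames(x))])
  list(beta = beta, se = se)
}

#' Permutation test for compositional stability of paired biopsies
#'
#' The statistic is the mean Euclidean distance between paired
#' compositions; the null re-pairs the follow-up samples at random. The
#' p-value is the fraction of null means at most the observed mean
#' (small distances = stable pairing).
#'
#' @param comp_t0,comp_t1 Paired composition matrices (same row order,
#'   >= 2 pairs).
#' @param n_perm Permutations (default 999).
#' @param seed Seed.
#' @return List with `observed`, `p`, `n_perm`, `n_pairs`.
#' @export
paired_stability_test <- function(comp_t0, comp_t1, n_perm = 999L, seed = 1L) {
  a <- unclass(comp_t0); b <- unclass(comp_t1)
  if (nrow(a) != nrow(b)) stop("paired matrices must have equal rows")
  if (nrow(a) < 2L) stop("need at least 2 pairs")
  pair_dist <- function(bb) mean(sqrt(rowSums((a - bb)^2)))
  obs <- pair_dist(b)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i)
    pair_dist(b[sample.int(nrow(b)), , drop = FALSE]), numeric(1))
  list(observed = obs, p = (1 + sum(null <= obs)) / (n_perm + 1),
       n_perm = n_perm, n_pairs = nrow(a))
}
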