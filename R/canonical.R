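#' Canonical synovial cell lineages
#'
#' The six major cell lineages every composition object in this package is
#' expressed over, in fixed order: T cells, B/plasma cells, NK cells,
#' myeloid cells, stromal cells (fibroblasts) and endothelial cells.
#'
#' @return Character vector of length 6.
#' @export
canonical_types <- function() {
  c("T", "B/plasma", "NK", "myeloid", "stromal", "endothelial")
}

# single-letter codes used in CTAP names; NK carries no letter by convention
type_letters <- function() {
  c("T" = "T", "B/plasma" = "B", "myeloid" = "M",
    "stromal" = "F", "endothelial" = "E")
}

# conventional display precedence of the letters within a CTAP name
letter_precedence <- function() c("T", "E", "F", "M", "B")

#' Validate and construct a composition matrix
#'
#' A composition matrix holds per-sample cell-type proportions: rows are
#' samples, columns the six canonical lineages, every row summing to one.
#'
#' @param x Numeric matrix (samples x cell types) with rownames (sample ids)
#'   and colnames (cell-type names).
#' @param tol Row-sum tolerance.
#' @return `x`, validated, with class `ctap_composition` prepended.
#' @export
as_composition <- function(x, tol = 1e-9) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) stop("composition matrix needs sample rownames")
  if (is.null(colnames(x))) stop("composition matrix needs cell-type colnames")
  if (ncol(x) < 1L) stop("composition matrix needs at least one cell type")
  if (any(x < 0)) stop("composition matrix has negative entries")
  bad <- which(abs(rowSums(x) - 1) > tol)
  if (length(bad)) {
    stop("composition rows do not sum to 1: ",
         paste(rownames(x)[bad], collapse = ", "))
  }
  class(x) <- c("ctap_composition", class(x))
  x
}

#' Close non-negative rows onto the unit simplex
#'
#' Divides each row by its sum (compositional closure).
#'
#' @param x Numeric matrix with positive row sums.
#' @return Matrix with rows summing to 1.
#' @export
close_rows <- function(x) {
  s <- rowSums(x)
  if (any(s <= 0)) stop("cannot close rows with non-positive sums")
  sweep(x, 1, s, "/")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items
#' (Hubert & Arabie). Equals 1 for identical partitions and is 0 in
#' expectation for independent ones.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  choose2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

# Dirichlet sampler (one row per draw)
rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}

# derive a deterministic per-stage seed below 2^31 from a master seed
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offset <- sum(utf8ToInt(stage)) * 10007L
  as.integer((as.numeric(seed) + offset) %% 2147483647)
}
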