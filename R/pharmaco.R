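#' Filter and KNN-impute a drug response (IC50) matrix
#'
#' Drugs (rows) missing in more than `na_limit` of the cell lines are
#' removed and logged. Remaining missing entries are imputed by the K
#' nearest neighbours among the other drugs: Euclidean distance over
#' mutually observed columns (scaled by the number of shared columns), mean
#' of the k nearest rows that are observed in the target column. Rows whose
#' missing fraction exceeds `rowmax` fall back to column means, and any
#' column missing more than `colmax` is an error naming the cell line.
#' `maxp` and `seed` are part of the published imputation contract: the
#' seeded recursive-partitioning path only activates above `maxp` rows, so
#' for matrices smaller than `maxp` (every desk-scale screen) the result is
#' deterministic and the seed is inert.
#'
#' @param ic50 [omics_matrix()] with role `"ic50"` or plain matrix, drugs x
#'   cell lines.
#' @param na_limit drop drugs with missing fraction > `na_limit`
#'   (default 0.30).
#' @param k neighbours (default 5).
#' @param rowmax,colmax row/column missingness limits (defaults 0.5, 0.8).
#' @param maxp block size above which large matrices would be partitioned
#'   (default 1500).
#' @param seed RNG seed of the partitioning path (default 362436069).
#' @return list `matrix` (complete), `removed` (data.frame `drug`,
#'   `missing_fraction`), `n_imputed`.
#' @export
prepare_ic50 <- function(ic50, na_limit = 0.30, k = 5L, rowmax = 0.5,
                         colmax = 0.8, maxp = 1500L, seed = 362436069) {
  x <- if (inherits(ic50, "omics_matrix")) unomx(ic50) else ic50
  stopifnot(is.matrix(x), is.numeric(x))
  na_frac_row <- rowMeans(is.na(x))
  removed <- data.frame(drug = rownames(x)[na_frac_row > na_limit],
                        missing_fraction = na_frac_row[na_frac_row > na_limit],
                        stringsAsFactors = FALSE)
  rownames(removed) <- NULL
  x <- x[na_frac_row <= na_limit, , drop = FALSE]
  na_frac_col <- colMeans(is.na(x))
  if (any(na_frac_col > colmax))
    stop("input error: cell line(s) exceed colmax missingness: ",
         paste(colnames(x)[na_frac_col > colmax], collapse = ", "))
  n_missing <- sum(is.na(x))
  if (n_missing == 0L)
    return(list(matrix = x, removed = removed, n_imputed = 0L))
  if (nrow(x) > maxp)
    set.seed(seed)  # partitioning path placeholder; full KNN still runs
  col_means <- colMeans(x, na.rm = TRUE)
  out <- x
  need <- which(rowSums(is.na(x)) > 0)
  for (i in need) {
    miss_cols <- which(is.na(x[i, ]))
    if (mean(is.na(x[i, ])) > rowmax) {
      out[i, miss_cols] <- col_means[miss_cols]
      next
    }
    # distances to all other rows over mutually observed columns
    d <- knn_row_distances(x, i)
    for (j in miss_cols) {
      cand <- which(!is.na(x[, j]))
      cand <- cand[cand != i]
      dc <- d[cand]
      cand <- cand[is.finite(dc)]
      dc <- dc[is.finite(dc)]
      if (!length(cand)) { out[i, j] <- col_means[j]; next }
      nn <- cand[order(dc)][seq_len(min(k, length(cand)))]
      out[i, j] <- mean(x[nn, j])
    }
  }
  list(matrix = out, removed = removed, n_imputed = n_missing)
}

# Euclidean distances from row i to every other row, averaged over shared
# observed columns (Inf when no column is shared).
knn_row_distances <- function(x, i) {
  xi <- x[i, ]
  obs_i <- !is.na(xi)
  d <- rep(Inf, nrow(x))
  for (r in seq_len(nrow(x))) {
    if (r == i) next
    shared <- obs_i & !is.na(x[r, ])
    ns <- sum(shared)
    if (ns == 0L) next
    d[r] <- sqrt(sum((xi[shared] - x[r, shared])^2) / ns)
  }
  d
}

#' Spearman correlation screen between two omics matrices
#'
#' Every row of `expr` (panel-gene expression) is correlated with every row
#' of `response` (drug IC50, actionable-gene expression, essentiality
#' profiles, or a proliferation marker) across their shared columns using
#' Spearman's rho with average-rank ties, pairwise-complete observations,
#' and the standard `cor.test` p-value (exact for small n without ties, t
#' approximation otherwise). P-values are BH-adjusted over all defined
#' pairs of the screen, and a pair is `significant` when
#' `|scc| > scc_threshold` and adjusted p < `alpha`. Pairs where either
#' side is constant are reported with `NA` rho and excluded from the
#' adjustment.
#'
#' @param expr,response [omics_matrix()] or plain matrices with shared
#'   column names (>= `min_shared` in common).
#' @param scc_threshold |rho| threshold recorded with the rows (0.15 for
#'   drug screens, 0.2 for actionable-gene / essentiality / proliferation
#'   screens).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param adjust p-adjustment method (default `"BH"`).
#' @param min_shared minimum shared samples (default 3).
#' @return data.frame `left_id`, `right_id`, `scc`, `p_value`,
#'   `adjusted_p`, `n_pairs`, `threshold`, `significant`.
#' @export
correlation_screen <- function(expr, response, scc_threshold = 0.15,
                               alpha = 0.05, adjust = "BH",
                               min_shared = 3L) {
  xl <- if (inherits(expr, "omics_matrix")) unomx(expr) else expr
  xr <- if (inherits(response, "omics_matrix")) unomx(response) else response
  stopifnot(is.matrix(xl), is.matrix(xr))
  shared <- intersect(colnames(xl), colnames(xr))
  if (length(shared) < min_shared)
    stop("input error: fewer than ", min_shared, " shared samples")
  xl <- xl[, shared, drop = FALSE]
  xr <- xr[, shared, drop = FALSE]
  grid <- expand.grid(left = rownames(xl), right = rownames(xr),
                      stringsAsFactors = FALSE)
  rho <- p <- n_pairs <- numeric(nrow(grid))
  for (idx in seq_len(nrow(grid))) {
    a <- xl[grid$left[idx], ]
    b <- xr[grid$right[idx], ]
    ok <- !is.na(a) & !is.na(b)
    n_pairs[idx] <- sum(ok)
    if (n_pairs[idx] < min_shared ||
        stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
      rho[idx] <- NA_real_; p[idx] <- NA_real_
      next
    }
    ct <- suppressWarnings(stats::cor.test(a[ok], b[ok], method = "spearman"))
    rho[idx] <- unname(ct$estimate)
    p[idx] <- ct$p.value
  }
  padj <- rep(NA_real_, length(p))
  def <- !is.na(p)
  padj[def] <- stats::p.adjust(p[def], method = adjust)
  out <- data.frame(left_id = grid$left, right_id = grid$right, scc = rho,
                    p_value = p, adjusted_p = padj, n_pairs = n_pairs,
                    threshold = scc_threshold,
                    significant = def & !is.na(rho) &
                      abs(rho) > scc_threshold & padj < alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
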