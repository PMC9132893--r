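#' Tumor-versus-normal differential expression
#'
#' Per cancer type with at least `min_normals` normal samples: two-sided
#' Wilcoxon rank-sum test per gene on log2(FPKM + offset) values, BH
#' adjustment across genes within the cancer type, and
#' `log2FC = log2(mean tumor FPKM + offset) - log2(mean normal FPKM + offset)`
#' (mode `"log-means"`, the default) or the difference of mean logs
#' (`"mean-logs"`). A gene is called `up` when `log2FC > lfc_threshold` and
#' adjusted p < `alpha`; `down` symmetrically; `ns` otherwise. Cancer types
#' with fewer normals are skipped with an explicit status, mirroring the
#' restriction of pan-cancer cohorts to those with enough normal tissue.
#'
#' @param expr [omics_matrix()] with role `"expression"` (FPKM, genes x
#'   samples); column metadata must contain `cancer_type` and logical
#'   `tumor`.
#' @param cancer_types subset of cancer types to analyze (default: all in
#'   the metadata).
#' @param min_normals minimum normal samples per cohort (default 5,
#'   interpreted as "more than five" being satisfied at > 5; cohorts with
#'   `<= min_normals` normals are skipped).
#' @param offset pseudocount inside the fold-change logs (default 1).
#' @param lfc_threshold,alpha thresholds of the direction call.
#' @param fc_mode `"log-means"` or `"mean-logs"`.
#' @return list with `results` (data.frame `gene`, `cancer_type`,
#'   `log2_fold_change`, `p_value`, `adjusted_p`, `direction`) and
#'   `skipped` (data.frame `cancer_type`, `n_normal`, `status`).
#' @export
differential_expression <- function(expr, cancer_types = NULL,
                                    min_normals = 5L, offset = 1,
                                    lfc_threshold = 1, alpha = 0.05,
                                    fc_mode = c("log-means", "mean-logs")) {
  fc_mode <- match.arg(fc_mode)
  meta <- omx_meta(expr)
  if (is.null(meta) || !all(c("cancer_type", "tumor") %in% names(meta)))
    stop("input error: expression matrix needs cancer_type and tumor metadata")
  x <- unomx(expr)
  if (any(x < 0)) stop("input error: FPKM values must be nonnegative")
  if (is.null(cancer_types)) cancer_types <- unique(meta$cancer_type)

  res <- list(); skipped <- list()
  for (ct in cancer_types) {
    tum <- meta$cancer_type == ct & meta$tumor
    nor <- meta$cancer_type == ct & !meta$tumor
    if (sum(nor) <= min_normals || sum(tum) < 1L) {
      skipped[[ct]] <- data.frame(cancer_type = ct, n_normal = sum(nor),
                                  status = "skipped: too few normal samples",
                                  stringsAsFactors = FALSE)
      next
    }
    lt <- log2(x[, tum, drop = FALSE] + offset)
    ln <- log2(x[, nor, drop = FALSE] + offset)
    p <- vapply(seq_len(nrow(x)), function(i)
      suppressWarnings(stats::wilcox.test(lt[i, ], ln[i, ], exact = FALSE,
                                          correct = TRUE)$p.value),
      numeric(1))
    p[is.nan(p)] <- 1  # constant gene in both groups
    lfc <- if (fc_mode == "log-means") {
      log2(rowMeans(x[, tum, drop = FALSE]) + offset) -
        log2(rowMeans(x[, nor, drop = FALSE]) + offset)
    } else {
      rowMeans(lt) - rowMeans(ln)
    }
    padj <- stats::p.adjust(p, method = "BH")
    dir <- ifelse(lfc > lfc_threshold & padj < alpha, "up",
           ifelse(lfc < -lfc_threshold & padj < alpha, "down", "ns"))
    res[[ct]] <- data.frame(gene = rownames(x), cancer_type = ct,
                            log2_fold_change = lfc, p_value = p,
                            adjusted_p = padj, direction = dir,
                            stringsAsFactors = FALSE)
  }
  results <- if (length(res)) do.call(rbind, res) else
    data.frame(gene = character(), cancer_type = character(),
               log2_fold_change = numeric(), p_value = numeric(),
               adjusted_p = numeric(), direction = character(),
               stringsAsFactors = FALSE)
  rownames(results) <- NULL
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(cancer_type = character(), n_normal = integer(),
               status = character(), stringsAsFactors = FALSE)
  rownames(skipped) <- NULL
  list(results = results, skipped = skipped)
}

#' Tissue-specificity classes from mean expression per tissue
#'
#' Human-protein-atlas style classification of each gene from its mean
#' expression across normal tissues, with threshold factor `fold`
#' (default 4):
#' \itemize{
#'   \item \strong{tissue enriched}: one tissue at least `fold` times every
#'     other tissue;
#'   \item \strong{group enriched}: a group of 2..`group_max` tissues, each
#'     member at least `fold` times the mean of all remaining tissues;
#'   \item \strong{tissue enhanced}: the top tissue at least `fold` times
#'     the mean across all tissues;
#'   \item \strong{low specificity} otherwise.
#' }
#' The group search examines descending-expression prefixes, which is
#' optimal: any other group of the same size has a smaller minimum and a
#' larger complement mean.
#'
#' @param expr_by_tissue numeric matrix genes x tissues (>= 3 tissues),
#'   nonnegative mean expression.
#' @param fold threshold factor (default 4).
#' @param group_max maximum group size (default 7).
#' @return data.frame `gene`, `class`, `tissues` (comma-separated members
#'   of the enriched tissue/group, `NA` for the other classes).
#' @export
tissue_specificity_classify <- function(expr_by_tissue, fold = 4,
                                        group_max = 7L) {
  stopifnot(is.matrix(expr_by_tissue))
  if (ncol(expr_by_tissue) < 3L) stop("input error: need at least 3 tissues")
  if (any(expr_by_tissue < 0))
    stop("input error: expression must be nonnegative")
  tis <- colnames(expr_by_tissue)
  out <- lapply(seq_len(nrow(expr_by_tissue)), function(i) {
    v <- expr_by_tissue[i, ]
    o <- order(v, decreasing = TRUE)
    vs <- v[o]
    nt <- length(vs)
    if (vs[1] >= fold * vs[2] && vs[1] > 0)
      return(c("tissue enriched", tis[o[1]]))
    for (g in 2:min(group_max, nt - 1L)) {
      rest <- vs[(g + 1L):nt]
      if (vs[g] >= fold * mean(rest) && vs[g] > 0)
        return(c("group enriched", paste(tis[o[1:g]], collapse = ",")))
    }
    if (vs[1] >= fold * mean(vs) && vs[1] > 0)
      return(c("tissue enhanced", tis[o[1]]))
    c("low specificity", NA_character_)
  })
  data.frame(gene = rownames(expr_by_tissue),
             class = vapply(out, `[`, character(1), 1),
             tissues = vapply(out, `[`, character(1), 2),
             stringsAsFactors = FALSE)
}

#' Rank all genes by Spearman correlation with an anchor gene
#'
#' Computes the Spearman correlation (average-rank tie handling) of every
#' other gene with the anchor across samples and returns them sorted in
#' descending order. Genes with zero variance have undefined correlation;
#' they are placed last and flagged `defined = FALSE`.
#'
#' @param expr [omics_matrix()] or plain numeric matrix (genes x samples).
#' @param anchor_gene row name of the anchor; must have nonzero variance.
#' @return data.frame `gene`, `rho`, `defined`, ordered by decreasing rho.
#' @export
rank_by_correlation <- function(expr, anchor_gene) {
  x <- if (inherits(expr, "omics_matrix")) unomx(expr) else expr
  stopifnot(is.matrix(x))
  if (!anchor_gene %in% rownames(x))
    stop("input error: anchor gene not in matrix")
  a <- x[anchor_gene, ]
  if (stats::sd(a) == 0)
    stop("input error: anchor gene is constant across samples")
  others <- setdiff(rownames(x), anchor_gene)
  ra <- rank(a)
  rk <- apply(x[others, , drop = FALSE], 1, rank)  # samples x genes
  rho <- suppressWarnings(as.numeric(stats::cor(ra, rk)))
  # rows with zero variance yield NA (constant ranks)
  sds <- apply(x[others, , drop = FALSE], 1, stats::sd)
  rho[sds == 0] <- NA_real_
  out <- data.frame(gene = others, rho = rho, defined = !is.na(rho),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$defined, -out$rho), , drop = FALSE]
  rownames(out) <- NULL
  out
}
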