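#' Mutation frequency of panel genes per cancer type
#'
#' Frequency is the proportion of samples of a cancer type carrying at least
#' one mutation in the gene, i.e. distinct mutated samples divided by the
#' cohort size.
#'
#' @param muts mutation table (data.frame with `sample`, `cancer_type`,
#'   `gene`).
#' @param cohort_sizes named integer vector: samples per cancer type. Every
#'   cancer type present in `muts` must be covered.
#' @param panel [gene_panel]; defines the row set (genes without mutations
#'   get frequency 0).
#' @return numeric matrix genes x cancer types, values in \[0, 1\].
#' @export
mutation_frequency_matrix <- function(muts, cohort_sizes, panel) {
  stopifnot(inherits(panel, "gene_panel"), is.numeric(cohort_sizes),
            !is.null(names(cohort_sizes)))
  if (any(cohort_sizes < 1)) stop("input error: cohort sizes must be >= 1")
  genes <- panel$genes$symbol
  types <- names(cohort_sizes)
  out <- matrix(0, length(genes), length(types),
                dimnames = list(genes, types))
  if (nrow(muts)) {
    missing_ct <- setdiff(unique(muts$cancer_type), types)
    if (length(missing_ct))
      stop("input error: cancer types absent from cohort_sizes: ",
           paste(missing_ct, collapse = ", "))
    m <- muts[muts$gene %in% genes, c("sample", "cancer_type", "gene")]
    if (nrow(m)) {
      m <- unique(m)
      tab <- table(factor(m$gene, levels = genes),
                   factor(m$cancer_type, levels = types))
      out <- sweep(unclass(tab), 2, cohort_sizes[types], "/")
      dimnames(out) <- list(genes, types)
    }
  }
  out
}

#' Tumor mutation burden per sample
#'
#' TMB is the count of nonsynonymous mutations per patient. Samples in the
#' supplied universe without any record get 0.
#'
#' @param muts mutation table with `sample` and `variant_class`.
#' @param samples character vector, the sample universe.
#' @return named integer vector over `samples`.
#' @export
compute_tmb <- function(muts, samples) {
  stopifnot(length(samples) > 0)
  out <- stats::setNames(integer(length(samples)), samples)
  if (nrow(muts)) {
    ns <- muts[muts$variant_class == "nonsynonymous" &
                 muts$sample %in% samples, "sample"]
    if (length(ns)) {
      tab <- table(ns)
      out[names(tab)] <- as.integer(tab)
    }
  }
  out
}

#' Binomial enrichment of mutations in transmembrane regions
#'
#' For each panel gene, tests whether the `k` mutations observed inside its
#' TM intervals out of `N` total positioned mutations exceed the uniform
#' expectation `p_ri = L_TR / L_g`. The p-value is the upper binomial tail
#' `P(X >= k)` at `(N, p_ri)`, evaluated with the survival-function form of
#' `pbinom` for numerical stability, and the enrichment ratio is
#' `E = k / (N * p_ri)`. A gene is flagged `enriched` when
#' `E > e_threshold` and its (by default BH-adjusted) p-value is below
#' `p_threshold`; set `p_adjust = "none"` to threshold the raw p-value
#' instead. Genes with no TM annotation (`L_TR = 0`) or no positioned
#' mutations are reported unscored. Mutations without a protein position
#' are excluded here (but still count for frequency and TMB).
#'
#' @param muts mutation table.
#' @param panel [gene_panel].
#' @param e_threshold enrichment-ratio threshold (default 1.3).
#' @param p_threshold significance threshold (default 0.05).
#' @param p_adjust `"BH"` (default) or `"none"`; which p-value column the
#'   threshold applies to. The BH family is the set of scored genes.
#' @return data.frame with one row per panel gene: `gene`, `n_mutations`
#'   (N), `k_tm` (k), `p_ri`, `enrichment` (E), `p_value`, `p_adjusted`,
#'   `enriched`, `scored`.
#' @export
tm_region_enrichment <- function(muts, panel, e_threshold = 1.3,
                                 p_threshold = 0.05,
                                 p_adjust = c("BH", "none")) {
  stopifnot(inherits(panel, "gene_panel"))
  p_adjust <- match.arg(p_adjust)
  g <- panel$genes
  pos <- muts[!is.na(muts$protein_pos) & muts$gene %in% g$symbol, ,
              drop = FALSE]
  if (nrow(pos)) {
    L <- stats::setNames(g$length, g$symbol)
    bad <- pos$protein_pos < 1 | pos$protein_pos > L[pos$gene]
    if (any(bad))
      stop("internal consistency error: protein position outside [1, L_g] for ",
           paste(unique(pos$gene[bad]), collapse = ", "))
    in_tm <- in_tm_region(panel, pos$gene, pos$protein_pos)
    N <- table(factor(pos$gene, levels = g$symbol))
    k <- table(factor(pos$gene[in_tm], levels = g$symbol))
  } else {
    N <- k <- stats::setNames(integer(nrow(g)), g$symbol)
  }
  N <- as.integer(N[g$symbol]); k <- as.integer(k[g$symbol])
  if (any(k > N)) stop("internal consistency error: k > N")
  p_ri <- g$tm_length / g$length
  scored <- N >= 1L & g$tm_length >= 1
  p <- E <- rep(NA_real_, nrow(g))
  p[scored] <- stats::pbinom(k[scored] - 1L, N[scored], p_ri[scored],
                             lower.tail = FALSE)
  E[scored] <- k[scored] / (N[scored] * p_ri[scored])
  padj <- rep(NA_real_, nrow(g))
  padj[scored] <- stats::p.adjust(p[scored], method = "BH")
  pcrit <- if (p_adjust == "BH") padj else p
  enriched <- scored & !is.na(E) & E > e_threshold & pcrit < p_threshold
  data.frame(gene = g$symbol, n_mutations = N, k_tm = k, p_ri = p_ri,
             enrichment = E, p_value = p, p_adjusted = padj,
             enriched = enriched, scored = scored,
             stringsAsFactors = FALSE)
}

#' Per-gene mutation densities by region
#'
#' Densities are mutations per residue: `k / L_TR` inside TM regions and
#' `(N - k) / (L_g - L_TR)` outside. With `per_gene = FALSE` the counts and
#' lengths are pooled across genes first.
#'
#' @inheritParams tm_region_enrichment
#' @param per_gene logical; per-gene densities (default) or pooled.
#' @return data.frame `gene`, `tm_density`, `other_density` (one row with
#'   gene `"pooled"` when `per_gene = FALSE`). Genes without TM annotation
#'   or without positioned mutations are dropped.
#' @export
mutation_density_by_region <- function(muts, panel, per_gene = TRUE) {
  enr <- tm_region_enrichment(muts, panel)
  g <- panel$genes
  keep <- enr$scored & g$tm_length < g$length
  if (per_gene) {
    d <- data.frame(gene = enr$gene[keep],
                    tm_density = enr$k_tm[keep] / g$tm_length[keep],
                    other_density = (enr$n_mutations[keep] - enr$k_tm[keep]) /
                      (g$length[keep] - g$tm_length[keep]),
                    stringsAsFactors = FALSE)
  } else {
    d <- data.frame(gene = "pooled",
                    tm_density = sum(enr$k_tm[keep]) / sum(g$tm_length[keep]),
                    other_density = sum(enr$n_mutations[keep] - enr$k_tm[keep]) /
                      sum(g$length[keep] - g$tm_length[keep]),
                    stringsAsFactors = FALSE)
  }
  rownames(d) <- NULL
  d
}

#' Rank-sum comparison of values between TM and other regions
#'
#' Two-sided Wilcoxon rank-sum comparison of two score vectors (per-gene
#' mutation densities, or per-mutation CADD scores, by region). For a
#' combined sample size of at most 20 the p-value is exact, computed by
#' complete enumeration over all group assignments of the average-rank
#' statistic (so ties are handled exactly); above that, the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param tm,other numeric vectors (both nonempty).
#' @param exact_limit combined size up to which the exact enumeration runs.
#' @return list with `p_value`, `statistic` (rank-sum W of the TM group on
#'   the Mann-Whitney scale), `shift` (Hodges-Lehmann location shift
#'   TM - other), `method`.
#' @export
region_value_compare <- function(tm, other, exact_limit = 20L) {
  tm <- tm[!is.na(tm)]; other <- other[!is.na(other)]
  if (!length(tm) || !length(other))
    stop("input error: both regions need at least one value")
  n1 <- length(tm); n <- n1 + length(other)
  r <- rank(c(tm, other))
  w_obs <- sum(r[seq_len(n1)])
  hl <- stats::median(outer(tm, other, "-"))
  if (n <= exact_limit) {
    idx <- utils::combn(n, n1)
    sums <- colSums(matrix(r[idx], nrow = n1))
    ew <- n1 * (n + 1) / 2
    p <- mean(abs(sums - ew) >= abs(w_obs - ew) - 1e-9)
    list(p_value = p, statistic = w_obs - n1 * (n1 + 1) / 2, shift = hl,
         method = "exact enumeration")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(tm, other, exact = FALSE,
                                              correct = TRUE))
    list(p_value = wt$p.value, statistic = unname(wt$statistic), shift = hl,
         method = "normal approximation")
  }
}

#' Association between region and deleterious/damaging status
#'
#' Builds the 2x2 table of positioned panel mutations, rows = region
#' (TM / other), columns = deleterious/damaging or not, where a mutation is
#' deleterious/damaging if SIFT labels it deleterious or PolyPhen labels it
#' damaging. Mutations with both labels missing are excluded. Tested with
#' the two-sided Fisher exact test; the conditional-MLE odds ratio is
#' reported.
#'
#' @inheritParams tm_region_enrichment
#' @return list with `table` (2x2), `p_value`, `odds_ratio`,
#'   `n_excluded_na`.
#' @export
deleterious_region_association <- function(muts, panel) {
  stopifnot(inherits(panel, "gene_panel"))
  m <- muts[!is.na(muts$protein_pos) & muts$gene %in% panel$genes$symbol, ,
            drop = FALSE]
  has_label <- !(is.na(m$sift) & is.na(m$polyphen))
  n_excl <- sum(!has_label)
  m <- m[has_label, , drop = FALSE]
  if (!nrow(m))
    stop("input error: no mutation carries a SIFT or PolyPhen label")
  region <- ifelse(in_tm_region(panel, m$gene, m$protein_pos), "TM", "other")
  del <- (!is.na(m$sift) & m$sift == "deleterious") |
    (!is.na(m$polyphen) & m$polyphen == "damaging")
  tab <- table(factor(region, levels = c("TM", "other")),
               factor(ifelse(del, "deleterious", "not"),
                      levels = c("deleterious", "not")))
  ft <- stats::fisher.test(tab)
  list(table = tab, p_value = ft$p.value,
       odds_ratio = unname(ft$estimate), n_excluded_na = n_excl)
}

#' CNV gain and loss frequencies per cancer type
#'
#' Gain frequency is the fraction of samples with a thresholded value of
#' +1 or +2 (or +2 only in `"high"` mode); loss frequency symmetric with
#' negative values. Gain + loss <= 1 per cell by construction.
#'
#' @param cnv [omics_matrix()] with role `"cnv"` (genes x samples) whose
#'   column metadata carries `cancer_type`.
#' @param panel [gene_panel]; restricts and orders the rows.
#' @param mode `"inclusive"` (default, |value| >= 1) or `"high"`
#'   (|value| = 2 only).
#' @return list of two matrices gene x cancer type: `gain`, `loss`.
#' @export
cnv_frequency_matrix <- function(cnv, panel, mode = c("inclusive", "high")) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "gene_panel"))
  meta <- omx_meta(cnv)
  if (is.null(meta) || !"cancer_type" %in% names(meta))
    stop("input error: cnv matrix needs cancer_type column metadata")
  x <- unomx(cnv)
  v <- x[!is.na(x)]
  if (any(v != round(v)) || any(abs(v) > 2))
    stop("input error: cnv values must be integers in -2..2")
  genes <- intersect(panel$genes$symbol, rownames(x))
  x <- x[genes, , drop = FALSE]
  types <- unique(meta$cancer_type)
  thr <- if (mode == "inclusive") 1 else 2
  gain <- loss <- matrix(NA_real_, length(genes), length(types),
                         dimnames = list(genes, types))
  for (ct in types) {
    cols <- meta$cancer_type == ct
    gain[, ct] <- rowMeans(x[, cols, drop = FALSE] >= thr)
    loss[, ct] <- rowMeans(x[, cols, drop = FALSE] <= -thr)
  }
  list(gain = gain, loss = loss)
}
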