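#' Read a GMT gene set collection
#'
#' Tab-separated, one set per line: name, description, then gene symbols.
#'
#' @param path file path.
#' @return named list of unique gene symbol vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT line (need name, description, >=1 gene): ",
           substr(l, 1, 60))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Write a GMT gene set collection
#' @param sets named list of character vectors.
#' @param path file path.
#' @param description description column (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

# Signed maximum deviation of the GSEA running sum, computed from the hit
# positions alone: between hits the walk decreases linearly, so extrema
# occur right after a hit (candidate maxima) or right before one (candidate
# minima).
es_from_positions <- function(pos, w, n_total) {
  m <- length(pos)
  o <- order(pos)
  pos <- pos[o]; w <- w[o]
  if (sum(w) == 0) w <- rep(1, m)
  nh <- cumsum(w) / sum(w)
  miss_step <- 1 / (n_total - m)
  dev_after <- nh - (pos - seq_len(m)) * miss_step
  dev_before <- c(0, nh[-m]) - (pos - seq_len(m)) * miss_step
  hi <- max(dev_after)
  lo <- min(dev_before, 0)
  if (hi >= -lo) hi else lo
}

#' Preranked GSEA enrichment score
#'
#' Weighted Kolmogorov-Smirnov running sum over a ranked gene list: at each
#' gene in the set the sum increases by `|score|^weight` (normalized so the
#' hit increments total 1), at each other gene it decreases by
#' `1/(N - N_hit)`. The enrichment score is the signed maximum deviation of
#' the running sum from zero. With `weight = 0` this reduces to the classic
#' unweighted KS statistic.
#'
#' @param ranked named numeric vector of scores (e.g. Spearman correlations
#'   with an anchor gene); sorted internally in decreasing score order with
#'   ties broken by name for determinism.
#' @param gene_set character vector. Its intersection with the ranked genes
#'   must be nonempty and a proper subset of the list.
#' @param weight exponent on |score| for hit increments (default 1).
#' @return list `es`, `running` (deviation after each list position),
#'   `hits` (logical vector along the ranked list), `ranked_genes`.
#' @export
preranked_es <- function(ranked, gene_set, weight = 1) {
  stopifnot(is.numeric(ranked), !is.null(names(ranked)))
  o <- order(-ranked, names(ranked))
  ranked <- ranked[o]
  genes <- names(ranked)
  hits <- genes %in% gene_set
  m <- sum(hits); n <- length(genes)
  if (m == 0L) stop("input error: gene set does not intersect the ranked list")
  if (m == n) stop("input error: gene set covers the entire ranked list")
  w <- abs(ranked)^weight
  wh <- w[hits]
  if (sum(wh) == 0) wh <- rep(1, m)  # all-zero scores: fall back to equal steps
  inc <- numeric(n)
  inc[hits] <- wh / sum(wh)
  inc[!hits] <- -1 / (n - m)
  running <- cumsum(inc)
  es <- running[which.max(abs(running))]
  list(es = es, running = running, hits = hits, ranked_genes = genes)
}

#' GSEA screen of gene sets against panel-gene co-expression rankings
#'
#' For each anchor gene: every other gene is ranked by Spearman correlation
#' with the anchor ([rank_by_correlation()]); each gene set's enrichment
#' score is computed on that ranking; the null distribution comes from
#' `n_perm` random draws of set membership over the list positions
#' (set-membership permutation, the preranked convention). The normalized
#' enrichment score divides the observed ES by the mean |null ES| of
#' matching sign, the permutation p-value is two-sided on |ES| with the +1
#' correction (so its floor is `1/(n_perm + 1)`), and BH adjustment runs
#' across sets within each anchor.
#'
#' @param expr [omics_matrix()] or matrix, genes x samples (>= 10 samples).
#' @param anchors character vector of anchor genes.
#' @param collection named list of gene sets.
#' @param n_perm permutations per set (default 1000).
#' @param seed integer; permutations are reproducible bit-for-bit.
#' @param min_overlap minimum set overlap with the ranked list (default 5).
#' @param weight ES weight (default 1).
#' @return data.frame `anchor`, `set`, `size`, `es`, `nes`, `p_value`,
#'   `adjusted_p`, `status` (`"ok"` or `"skipped: small overlap"`;
#'   skipped sets have NA scores and are outside the BH family).
#' @export
gsea_screen <- function(expr, anchors, collection, n_perm = 1000L,
                        seed = 1L, min_overlap = 5L, weight = 1) {
  x <- if (inherits(expr, "omics_matrix")) unomx(expr) else expr
  stopifnot(is.matrix(x))
  if (ncol(x) < 10L) stop("input error: need at least 10 samples")
  if (!length(collection)) stop("input error: empty collection")
  out <- list()
  for (anchor in anchors) {
    rk <- rank_by_correlation(x, anchor)
    rk <- rk[rk$defined, , drop = FALSE]
    ranked <- stats::setNames(rk$rho, rk$gene)
    o <- order(-ranked, names(ranked))
    ranked <- ranked[o]
    n <- length(ranked)
    w_all <- abs(ranked)^weight
    rows <- lapply(names(collection), function(set_name) {
      set <- collection[[set_name]]
      hit_pos <- which(names(ranked) %in% set)
      m <- length(hit_pos)
      if (m < min_overlap || m >= n)
        return(data.frame(anchor = anchor, set = set_name, size = m,
                          es = NA_real_, nes = NA_real_, p_value = NA_real_,
                          adjusted_p = NA_real_,
                          status = "skipped: small overlap",
                          stringsAsFactors = FALSE))
      es <- es_from_positions(hit_pos, w_all[hit_pos], n)
      null_es <- with_op_seed(seed, set_seed_offset(anchor, set_name), {
        vapply(seq_len(n_perm), function(i) {
          p <- sample.int(n, m)
          es_from_positions(p, w_all[p], n)
        }, numeric(1))
      })
      same_sign <- null_es[sign(null_es) == sign(es)]
      nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NA_real_
      p <- (1 + sum(abs(null_es) >= abs(es))) / (n_perm + 1)
      data.frame(anchor = anchor, set = set_name, size = m, es = es,
                 nes = nes, p_value = p, adjusted_p = NA_real_,
                 status = "ok", stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    ok <- res$status == "ok"
    res$adjusted_p[ok] <- stats::p.adjust(res$p_value[ok], "BH")
    out[[anchor]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Deterministic small offset from anchor/set names so every (anchor, set)
# cell has its own reproducible permutation stream.
set_seed_offset <- function(anchor, set_name) {
  s <- paste0(anchor, "\r", set_name)
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 100003L + 1000L
}
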