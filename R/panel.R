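#' Construct a gene panel
#'
#' A gene panel is the unit of analysis for every landscape statistic in this
#' package: a set of gene symbols with family labels, protein lengths, and
#' optional transmembrane (TM) interval annotations in protein coordinates.
#'
#' Intervals are 1-based and inclusive on both ends (the UniProt convention
#' for residue ranges). Overlapping or book-ended intervals of the same gene
#' are merged before the covered length `tm_length` is computed, so the
#' derived per-gene TM fraction `tm_length / length` is always in \[0, 1\].
#'
#' @param genes data.frame with columns `symbol`, `family`, `length`
#'   (protein length in residues, > 0).
#' @param tm_intervals data.frame with columns `gene`, `start`, `end`
#'   (residues, 1-based inclusive), or `NULL` for a panel without TM
#'   annotation. Every interval must lie within its gene's protein length.
#' @return An object of class `gene_panel`: a list with elements
#'   `genes` (data.frame `symbol`, `family`, `length`, `tm_length`) and
#'   `tm_intervals` (merged intervals, data.frame `gene`, `start`, `end`).
#' @examples
#' gene_panel(data.frame(symbol = "G1", family = "F", length = 500),
#'            data.frame(gene = "G1", start = 101, end = 121))
#' @export
gene_panel <- function(genes, tm_intervals = NULL) {
  stopifnot(is.data.frame(genes),
            all(c("symbol", "family", "length") %in% names(genes)))
  genes <- data.frame(symbol = as.character(genes$symbol),
                      family = as.character(genes$family),
                      length = as.numeric(genes$length),
                      stringsAsFactors = FALSE)
  if (nrow(genes) < 1L) stop("panel must contain at least one gene")
  if (anyDuplicated(genes$symbol)) stop("duplicate gene symbols in panel")
  if (any(!is.finite(genes$length) | genes$length <= 0))
    stop("protein lengths must be positive")

  if (is.null(tm_intervals) || nrow(tm_intervals) == 0L) {
    tm_intervals <- data.frame(gene = character(), start = integer(),
                               end = integer(), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("gene", "start", "end") %in% names(tm_intervals)))
    tm_intervals <- data.frame(gene = as.character(tm_intervals$gene),
                               start = as.integer(tm_intervals$start),
                               end = as.integer(tm_intervals$end),
                               stringsAsFactors = FALSE)
    unknown <- setdiff(tm_intervals$gene, genes$symbol)
    if (length(unknown))
      stop("TM intervals reference genes absent from panel: ",
           paste(unknown, collapse = ", "))
    if (any(tm_intervals$start < 1L) || any(tm_intervals$end < tm_intervals$start))
      stop("TM intervals must satisfy 1 <= start <= end")
    glen <- stats::setNames(genes$length, genes$symbol)
    if (any(tm_intervals$end > glen[tm_intervals$gene]))
      stop("TM interval extends beyond protein length")
    tm_intervals <- merge_intervals(tm_intervals)
  }

  tm_len <- stats::setNames(numeric(nrow(genes)), genes$symbol)
  if (nrow(tm_intervals)) {
    cov <- tapply(tm_intervals$end - tm_intervals$start + 1L,
                  tm_intervals$gene, sum)
    tm_len[names(cov)] <- cov
  }
  genes$tm_length <- as.numeric(tm_len[genes$symbol])

  structure(list(genes = genes, tm_intervals = tm_intervals),
            class = "gene_panel")
}

# Merge overlapping/adjacent 1-based inclusive intervals per gene.
merge_intervals <- function(iv) {
  out <- lapply(split(iv, iv$gene), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    s <- d$start; e <- d$end
    ms <- s[1]; me <- e[1]; rs <- integer(); re <- integer()
    for (i in seq_along(s)[-1]) {
      if (s[i] <= me + 1L) me <- max(me, e[i])
      else { rs <- c(rs, ms); re <- c(re, me); ms <- s[i]; me <- e[i] }
    }
    rs <- c(rs, ms); re <- c(re, me)
    data.frame(gene = d$gene[1], start = rs, end = re,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("Gene panel:", nrow(x$genes), "genes,",
      length(unique(x$genes$family)), "families;",
      nrow(x$tm_intervals), "TM intervals\n")
  fam <- table(x$genes$family)
  cat(paste0("  ", names(fam), ": ", as.integer(fam), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
as.data.frame.gene_panel <- function(x, ...) x$genes

#' Is a position inside a gene's TM region?
#'
#' @param panel `gene_panel`.
#' @param gene character vector of gene symbols.
#' @param pos integer vector of protein positions (1-based), same length.
#' @return logical vector; `NA` where `pos` is `NA` or the gene is not in
#'   the panel.
#' @export
in_tm_region <- function(panel, gene, pos) {
  stopifnot(inherits(panel, "gene_panel"), length(gene) == length(pos))
  out <- rep(NA, length(gene))
  known <- gene %in% panel$genes$symbol & !is.na(pos)
  if (!any(known)) return(out)
  iv <- panel$tm_intervals
  res <- logical(sum(known))
  g <- gene[known]; p <- pos[known]
  iv_by_gene <- split(iv, iv$gene)
  for (gg in unique(g)) {
    sel <- g == gg
    ivg <- iv_by_gene[[gg]]
    if (is.null(ivg) || nrow(ivg) == 0L) { res[sel] <- FALSE; next }
    # intervals are merged and sorted, so membership reduces to one lookup
    idx <- findInterval(p[sel], ivg$start)
    res[sel] <- idx >= 1L & p[sel] <= ivg$end[pmax(idx, 1L)]
  }
  out[known] <- res
  out
}

#' The curated TRP channel panel
#'
#' Returns the shipped 28-gene transient-receptor potential (TRP) channel
#' panel, grouped into the six classic families/sub-families: TRPA, TRPC,
#' TRPM, TRPV, TRPML (MCOLN) and TRPP (PKD). Symbols and family membership
#' follow the HGNC TRP group; TRPC2 is a pseudogene in human and its length
#' is taken from the reference rodent ortholog. Protein lengths are
#' approximate canonical-isoform lengths.
#'
#' The transmembrane interval table shipped with the package
#' (`trp_tm_intervals_synthetic.tsv`) is a deterministic synthetic placement
#' of six TM helices in the channel-domain region of each protein, provided
#' so that region-level statistics are runnable out of the box; it is not a
#' UniProt extract. For real analyses supply UniProt intervals via
#' [read_tm_intervals()].
#'
#' @param tm_intervals logical; attach the synthetic TM interval table
#'   (default `TRUE`).
#' @return A [gene_panel].
#' @examples
#' p <- trp_panel()
#' nrow(p$genes)                  # 28
#' length(unique(p$genes$family)) # 6
#' @export
trp_panel <- function(tm_intervals = TRUE) {
  genes <- utils::read.delim(
    system.file("extdata", "trp_panel.tsv", package = "panelscan"),
    stringsAsFactors = FALSE)
  iv <- NULL
  if (tm_intervals)
    iv <- utils::read.delim(
      system.file("extdata", "trp_tm_intervals_synthetic.tsv",
                  package = "panelscan"),
      stringsAsFactors = FALSE)
  gene_panel(genes, iv)
}
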