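# All on-disk tables are TSV: UTF-8, LF, '.' decimal, header row, no
# quoting, NA as "NA" -- chosen so outputs are bit-exact regression
# fixtures.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA", eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

write_matrix_tsv <- function(x, path, id_col = "id") {
  df <- data.frame(rownames(x), as.data.frame(unomx(x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(x))
  write_tsv(df, path)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Read a MAF-like mutation table
#'
#' Tab-separated with a header; the default column names are those written
#' by [write_mutations()] (`sample`, `cancer_type`, `gene`, `protein_pos`,
#' `variant_class`, `sift`, `polyphen`, `cadd`) and can be remapped for
#' foreign files via `col_map` (a named character vector
#' `internal_name = file_column`).
#'
#' @param path file path.
#' @param col_map optional column remapping.
#' @return mutation table data.frame.
#' @export
read_mutations <- function(path, col_map = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  want <- c("sample", "cancer_type", "gene", "protein_pos", "variant_class",
            "sift", "polyphen", "cadd")
  if (!is.null(col_map)) {
    for (nm in names(col_map)) {
      if (!col_map[[nm]] %in% names(df))
        stop("input error: column '", col_map[[nm]], "' not in ", path)
      names(df)[names(df) == col_map[[nm]]] <- nm
    }
  }
  missing_cols <- setdiff(want, names(df))
  if (length(missing_cols))
    stop("input error: ", path, " lacks columns: ",
         paste(missing_cols, collapse = ", "))
  df <- df[, want]
  df$protein_pos <- as.integer(df$protein_pos)
  df$cadd <- as.numeric(df$cadd)
  class(df) <- c("mutation_table", "data.frame")
  df
}

#' Write a MAF-like mutation table
#' @param muts mutation table.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_mutations <- function(muts, path) write_tsv(muts, path)

#' Read a gene panel from TSV files
#'
#' @param panel_path TSV with columns `symbol`, `family`, `length`.
#' @param tm_path optional TSV with columns `gene`, `start`, `end`
#'   (1-based inclusive residue intervals, the UniProt convention).
#' @return [gene_panel].
#' @export
read_panel <- function(panel_path, tm_path = NULL) {
  genes <- utils::read.delim(panel_path, stringsAsFactors = FALSE)
  iv <- if (!is.null(tm_path)) read_tm_intervals(tm_path) else NULL
  gene_panel(genes, iv)
}

#' Read a transmembrane interval table
#' @param path TSV with columns `gene`, `start`, `end`.
#' @return data.frame.
#' @export
read_tm_intervals <- function(path)
  utils::read.delim(path, stringsAsFactors = FALSE)

#' Read an expression/CNV/IC50 matrix with optional sample metadata
#'
#' @param path matrix TSV: first column feature ids, remaining columns one
#'   per sample.
#' @param role omics role tag.
#' @param meta_path optional sample metadata TSV with a `sample` column.
#' @return [omics_matrix()].
#' @export
read_omics <- function(path, role, meta_path = NULL) {
  m <- read_matrix_tsv(path)
  meta <- if (!is.null(meta_path))
    utils::read.delim(meta_path, stringsAsFactors = FALSE) else NULL
  omics_matrix(m, role = role, col_data = meta)
}

#' Read a clinical table
#' @param path TSV written by [write_clinical()] or of the same shape.
#' @return clinical table data.frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"patient_id" %in% names(df))
    stop("input error: clinical table lacks patient_id")
  if ("stage" %in% names(df)) df$stage <- factor(df$stage, ordered = TRUE)
  if ("grade" %in% names(df)) df$grade <- factor(df$grade, ordered = TRUE)
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Write a clinical table
#' @param clinical clinical table.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  df <- clinical
  class(df) <- "data.frame"
  write_tsv(df, path)
}

# key: value manifest, one entry per line; vectors are comma-joined.
write_manifest <- function(entries, path) {
  lines <- vapply(names(entries), function(k) {
    v <- entries[[k]]
    paste0(k, ": ", paste(format(v, trim = TRUE), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write all outputs of a simulated cohort to a directory
#'
#' Materializes [sim_cohort()] output as the TSV/GMT file set that
#' [run_pipeline()] (and the `panelscan` command line) consumes: panel and
#' TM-interval tables, MAF-like mutation table, CNV/expression/IC50
#' matrices with sample metadata, clinical table, gene sets, and a
#' `manifest.txt` recording every planted parameter.
#'
#' @param cohort list from [sim_cohort()].
#' @param outdir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  paths <- c(panel = p("panel.tsv"), tm = p("tm_intervals.tsv"),
             mutations = p("mutations.tsv"), cnv = p("cnv.tsv"),
             cnv_meta = p("cnv_samples.tsv"),
             expression = p("expression.tsv"),
             expression_meta = p("expression_samples.tsv"),
             clinical = p("clinical.tsv"), status = p("status.tsv"),
             gene_sets = p("gene_sets.gmt"),
             ic50 = p("ic50.tsv"),
             cell_expression = p("cell_line_expression.tsv"),
             manifest = p("manifest.txt"))
  write_tsv(cohort$panel$genes[, c("symbol", "family", "length")],
            paths["panel"])
  write_tsv(cohort$panel$tm_intervals, paths["tm"])
  write_mutations(cohort$mutations, paths["mutations"])
  write_matrix_tsv(cohort$cnv, paths["cnv"], id_col = "gene")
  write_tsv(omx_meta(cohort$cnv), paths["cnv_meta"])
  write_matrix_tsv(cohort$expression, paths["expression"], id_col = "gene")
  write_tsv(omx_meta(cohort$expression), paths["expression_meta"])
  write_clinical(cohort$clinical, paths["clinical"])
  write_tsv(data.frame(patient_id = names(cohort$status),
                       status = unname(cohort$status),
                       stringsAsFactors = FALSE), paths["status"])
  write_gmt(cohort$gene_sets, paths["gene_sets"])
  write_matrix_tsv(cohort$drug$ic50, paths["ic50"], id_col = "drug")
  write_matrix_tsv(cohort$drug$expression, paths["cell_expression"],
                   id_col = "gene")
  mf <- cohort$manifest
  mf$planted_drug_pairs <- paste(mf$planted_drug_pairs$gene,
                                 mf$planted_drug_pairs$drug,
                                 mf$planted_drug_pairs$rho, sep = "|")
  write_manifest(mf, paths["manifest"])
  invisible(paths)
}
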