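#' Construct an omics matrix
#'
#' A numeric matrix (features x samples) tagged with a role and per-column
#' metadata. Roles and their value domains: `"expression"` (nonnegative
#' FPKM), `"cnv"` (thresholded integers -2..2), `"ic50"` (log scale, may
#' contain NA), `"essentiality"` (unrestricted scores).
#'
#' @param x numeric matrix with row and column names.
#' @param role one of `"expression"`, `"cnv"`, `"ic50"`, `"essentiality"`.
#' @param col_data optional data.frame with one row per column of `x`;
#'   must contain a `sample` column matching `colnames(x)`. Typical columns:
#'   `cancer_type`, `tumor` (logical), `tissue`.
#' @return `x` with class `omics_matrix` and attributes `role`, `col_data`.
#' @export
omics_matrix <- function(x, role = c("expression", "cnv", "ic50",
                                     "essentiality"),
                         col_data = NULL) {
  role <- match.arg(role)
  stopifnot(is.matrix(x), is.numeric(x))
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("omics matrix needs row and column names")
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x)))
    stop("row and column ids must be unique")
  if (role == "cnv") {
    v <- x[!is.na(x)]
    if (any(v != round(v)) || any(v < -2 | v > 2))
      stop("input error: cnv values must be integers in -2..2")
  }
  if (role == "expression" && any(x < 0, na.rm = TRUE))
    stop("input error: expression values must be nonnegative")
  if (!is.null(col_data)) {
    stopifnot(is.data.frame(col_data), "sample" %in% names(col_data))
    if (!identical(as.character(col_data$sample), colnames(x)))
      col_data <- col_data[match(colnames(x), col_data$sample), , drop = FALSE]
    if (any(is.na(col_data$sample)))
      stop("col_data does not cover all matrix columns")
    rownames(col_data) <- NULL
  }
  structure(x, class = c("omics_matrix", class(x)),
            role = role, col_data = col_data)
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat("<omics_matrix role=", attr(x, "role"), "> ", nrow(x), " x ", ncol(x),
      "; ", sum(is.na(x)), " missing\n", sep = "")
  invisible(x)
}

#' Column metadata of an omics matrix
#' @param x `omics_matrix`.
#' @return data.frame or `NULL`.
#' @export
omx_meta <- function(x) attr(x, "col_data")

#' Role tag of an omics matrix
#' @param x `omics_matrix`.
#' @return character scalar.
#' @export
omx_role <- function(x) attr(x, "role")

# Drop class/attrs for plain matrix math.
unomx <- function(x) {
  out <- x
  attributes(out) <- attributes(x)[c("dim", "dimnames")]
  out
}
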