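#' Construct an expression matrix with a two-condition design
#'
#' Bundles a genes-by-replicates numeric matrix (intensities, assumed already
#' calibrated / log-transformed) with the mapping from each replicate array to
#' one of two biological condition labels. Genes are the observations
#' (individuals) of every downstream analysis; replicate arrays are the
#' variables.
#'
#' @param values Numeric matrix, rows = genes, columns = replicate arrays.
#'   Row names are gene identifiers, column names replicate identifiers; both
#'   must be unique and non-missing.
#' @param conditions Named character vector mapping every replicate identifier
#'   (names) to its condition label (values). Exactly two distinct labels are
#'   required.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (the matrix) and `conditions` (the replicate-to-condition map,
#'   ordered as the matrix columns).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("r", 1:4)))
#' em <- expression_matrix(m, c(r1 = "A", r2 = "A", r3 = "B", r4 = "B"))
#' condition_labels(em)
#' @export
expression_matrix <- function(values, conditions) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  gene_ids <- rownames(values)
  rep_ids <- colnames(values)
  if (is.null(gene_ids) || anyNA(gene_ids) || any(gene_ids == ""))
    stop("`values` must have non-empty row names (gene identifiers)")
  if (is.null(rep_ids) || anyNA(rep_ids) || any(rep_ids == ""))
    stop("`values` must have non-empty column names (replicate identifiers)")
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifier: ", gene_ids[duplicated(gene_ids)][1L])
  if (anyDuplicated(rep_ids))
    stop("duplicate replicate identifier: ", rep_ids[duplicated(rep_ids)][1L])
  if (!all(is.finite(values)))
    stop("`values` contains non-finite entries; impute or remove them first")
  if (is.null(names(conditions)))
    stop("`conditions` must be named by replicate identifier")
  missing_design <- setdiff(rep_ids, names(conditions))
  if (length(missing_design))
    stop("replicate missing from design: ", paste(missing_design, collapse = ", "))
  extra_design <- setdiff(names(conditions), rep_ids)
  if (length(extra_design))
    stop("design replicate absent from matrix: ",
         paste(extra_design, collapse = ", "))
  conditions <- as.character(conditions[rep_ids])
  names(conditions) <- rep_ids
  labs <- unique(conditions)
  if (length(labs) != 2L)
    stop("exactly 2 condition labels required, got ", length(labs), ": ",
         paste(labs, collapse = ", "))
  cnt <- table(conditions)
  if (any(cnt < 2L))
    warning("condition(s) with a single replicate: ",
            paste(names(cnt)[cnt < 2L], collapse = ", "))
  structure(list(values = values, conditions = conditions),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cnt <- table(x$conditions)
  cat("expression_matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " replicates (",
      paste(sprintf("%s: %d", names(cnt), as.integer(cnt)), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Condition labels of an expression matrix
#'
#' @param x An `expression_matrix`.
#' @return Character vector of the two condition labels, in order of first
#'   appearance along the replicate columns.
#' @export
condition_labels <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  unique(x$conditions)
}

#' Read an expression matrix and its design file
#'
#' The matrix file is a delimited text table whose first column holds gene
#' identifiers and whose header row holds replicate identifiers. The design
#' file has two columns, `replicate_id` and `condition`. Replicate order is
#' taken from the matrix file and is authoritative downstream.
#'
#' @param path Path to the expression-matrix file.
#' @param design_path Path to the design file.
#' @param sep Field delimiter, default tab; pass `","` for CSV input.
#' @param impute If `TRUE`, missing cells are imputed with the per-gene mean;
#'   by default any missing value is an error.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, design_path, sep = "\t", impute = FALSE) {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(raw) < 2L)
    stop("expression matrix needs a gene-id column and at least one replicate")
  gene_ids <- raw[[1L]]
  rep_ids <- colnames(raw)[-1L]
  vals <- matrix(NA_real_, nrow(raw), length(rep_ids),
                 dimnames = list(gene_ids, rep_ids))
  for (j in seq_along(rep_ids)) {
    col <- raw[[j + 1L]]
    blank <- is.na(col) | col == "" | col == "NA"
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !blank)
    if (length(bad))
      stop("non-numeric value '", col[bad[1L]], "' at gene '",
           gene_ids[bad[1L]], "', replicate '", rep_ids[j], "'")
    vals[, j] <- num
  }
  if (anyNA(vals)) {
    if (!impute) {
      miss <- which(is.na(vals), arr.ind = TRUE)[1L, ]
      stop("missing value at gene '", gene_ids[miss[1L]], "', replicate '",
           rep_ids[miss[2L]], "' (use impute = TRUE for per-gene mean imputation)")
    }
    for (i in which(rowSums(is.na(vals)) > 0L)) {
      mu <- mean(vals[i, ], na.rm = TRUE)
      if (!is.finite(mu))
        stop("gene '", gene_ids[i], "' has no observed values to impute from")
      vals[i, is.na(vals[i, ])] <- mu
    }
  }
  design <- utils::read.table(design_path, header = TRUE, sep = sep,
                              check.names = FALSE, colClasses = "character",
                              quote = "", comment.char = "")
  if (ncol(design) < 2L)
    stop("design file needs columns replicate_id and condition")
  conditions <- stats::setNames(design[[2L]], design[[1L]])
  expression_matrix(vals, conditions)
}

#' Write an expression matrix (and optionally its design) to delimited text
#'
#' @param x An `expression_matrix`.
#' @param path Output path for the matrix table.
#' @param design_path Optional output path for the two-column design table.
#' @param sep Field delimiter.
#' @return Invisibly, `x`.
#' @export
write_expression <- function(x, path, design_path = NULL, sep = "\t") {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(design_path)) {
    dd <- data.frame(replicate_id = names(x$conditions),
                     condition = unname(x$conditions),
                     stringsAsFactors = FALSE)
    utils::write.table(dd, design_path, sep = sep, quote = FALSE,
                       row.names = FALSE)
  }
  invisible(x)
}
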