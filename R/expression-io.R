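#' Validate a genes-by-samples expression matrix
#'
#' An expression matrix is a plain numeric matrix on the log2 scale with
#' unique gene identifiers as rownames and unique sample identifiers as
#' colnames. All values must be finite: missing values are never allowed to
#' propagate into downstream scoring.
#'
#' @param values numeric matrix, genes as rows.
#' @return the validated matrix (invisibly unchanged).
#' @export
validate_expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must carry gene rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  if (!all(is.finite(values)))
    stop("expression matrix contains non-finite values; reject or impute ",
         "them at load time", call. = FALSE)
  values
}

#' Construct an expression matrix from values and identifiers
#'
#' @param values numeric matrix or coercible grid, genes as rows.
#' @param gene_ids,sample_ids identifiers; default to the dimnames of `values`.
#' @return a validated numeric matrix (genes x samples).
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids
  colnames(values) <- sample_ids
  validate_expression_matrix(values)
}

#' Read a tab-delimited expression matrix
#'
#' Expects a TSV with gene identifiers in the first column and sample
#' identifiers in the first row (a leading label for the gene column is
#' tolerated, as is the bare R `write.table` convention with one fewer header
#' field). Duplicate gene rows are collapsed by their mean with a warning;
#' duplicate sample identifiers are an error. Every cell must parse as a
#' finite number; a missing or malformed cell raises an error naming its row
#' and column unless `na_action = "impute_mean"`, in which case missing cells
#' are replaced by the gene's mean over observed samples.
#'
#' @param path file path.
#' @param transpose set `TRUE` when the file stores samples as rows; the
#'   returned matrix is always genes x samples.
#' @param na_action `"error"` (default) or `"impute_mean"`.
#' @param autolog2 if `TRUE` and the parsed maximum exceeds 50 (a raw-intensity
#'   scale), apply `log2(x + 1)` and say so loudly. Input is otherwise assumed
#'   to be log2-normalized already, the usual convention for array series.
#' @return genes x samples numeric matrix.
#' @export
read_expression_matrix <- function(path, transpose = FALSE,
                                   na_action = c("error", "impute_mean"),
                                   autolog2 = FALSE) {
  na_action <- match.arg(na_action)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("'", path, "' is empty or has no data rows", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  body <- fields[-1L]
  width <- lengths(body)
  if (length(unique(width)) != 1L)
    stop("ragged table: rows have differing field counts", call. = FALSE)
  n_col <- width[1L] - 1L
  if (n_col < 1L)
    stop("no sample columns found", call. = FALSE)
  col_ids <- if (length(header) == n_col) header else header[-1L]
  if (length(col_ids) != n_col)
    stop("header has ", length(header), " fields but data rows have ",
         n_col, " value columns", call. = FALSE)
  row_ids <- vapply(body, `[[`, character(1L), 1L)
  cells <- matrix(unlist(lapply(body, `[`, -1L), use.names = FALSE),
                  nrow = length(body), ncol = n_col, byrow = TRUE)
  values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- !is.finite(values)
  if (any(bad) && na_action == "error") {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("cell at row '", row_ids[idx[1L]], "', column '", col_ids[idx[2L]],
         "' is not a finite number (got \"", cells[idx[1L], idx[2L]], "\")",
         call. = FALSE)
  }
  na_token <- bad & (toupper(trimws(cells)) %in% c("NA", "NAN", "") |
                       !nzchar(trimws(cells)))
  if (any(bad & !na_token)) {
    idx <- which(bad & !na_token, arr.ind = TRUE)[1L, ]
    stop("cell at row '", row_ids[idx[1L]], "', column '", col_ids[idx[2L]],
         "' is not numeric (got \"", cells[idx[1L], idx[2L]], "\")",
         call. = FALSE)
  }
  rownames(values) <- row_ids
  colnames(values) <- col_ids
  if (transpose) values <- t(values)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(rownames(values))) {
    dups <- unique(rownames(values)[duplicated(rownames(values))])
    warning("collapsing ", length(dups), " duplicated gene row(s) by mean: ",
            paste(utils::head(dups, 5L), collapse = ", "),
            if (length(dups) > 5L) ", ...", call. = FALSE)
    values <- rowsum(values, group = rownames(values), reorder = FALSE) /
      as.vector(table(rownames(values))[unique(rownames(values))])
  }
  if (any(!is.finite(values))) {
    gene_means <- rowMeans(values, na.rm = TRUE)
    if (any(!is.finite(gene_means)))
      stop("gene(s) with no observed values cannot be mean-imputed: ",
           paste(rownames(values)[!is.finite(gene_means)], collapse = ", "),
           call. = FALSE)
    miss <- which(!is.finite(values), arr.ind = TRUE)
    values[miss] <- gene_means[miss[, 1L]]
    message("imputed ", nrow(miss), " missing cell(s) by per-gene mean")
  }
  if (max(values) > 50) {
    if (autolog2) {
      message("matrix maximum ", format(max(values)),
              " exceeds 50: applying log2(x + 1) (raw-scale input assumed)")
      values <- log2(values + 1)
    } else {
      warning("matrix maximum ", format(max(values)), " exceeds 50; input ",
              "may not be log2-scale (set autolog2 = TRUE to transform)",
              call. = FALSE)
    }
  }
  validate_expression_matrix(values)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]: gene identifiers in the first
#' column (headed `gene_id`), sample identifiers in the first row. Values are
#' printed with enough significant digits for a lossless round trip at 1e-6
#' relative tolerance.
#'
#' @param x genes x samples numeric matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  x <- validate_expression_matrix(x)
  header <- paste(c("gene_id", colnames(x)), collapse = "\t")
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], sprintf("%.10g", x[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read sample metadata
#'
#' Tab-delimited with a header; required columns `sample_id` and `group`.
#' Group labels are normalized case-insensitively onto `control`/`case`
#' through the alias vectors; any other token is an error. Extra columns are
#' kept as covariates (numeric where they parse as such).
#'
#' @param path file path.
#' @param control_labels,case_labels tokens (case-insensitive) accepted for
#'   each group; e.g. `case_labels = c("case", "ssc")` treats SSc biopsies as
#'   cases.
#' @return data.frame with columns `sample_id`, `group` (factor
#'   control/case), `group_label` (the raw token), plus covariate columns.
#' @export
read_sample_metadata <- function(path, control_labels = "control",
                                 case_labels = "case") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("sample_id", "group"), names(df))
  if (length(missing_cols))
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  raw <- as.character(df$group)
  low <- tolower(trimws(raw))
  group <- ifelse(low %in% tolower(control_labels), "control",
                  ifelse(low %in% tolower(case_labels), "case", NA_character_))
  if (anyNA(group))
    stop("unknown group token(s): ",
         paste(unique(raw[is.na(group)]), collapse = ", "),
         "; accepted (case-insensitive): ",
         paste(c(control_labels, case_labels), collapse = ", "),
         call. = FALSE)
  out <- sample_metadata(as.character(df$sample_id), group, group_label = raw)
  extra <- setdiff(names(df), c("sample_id", "group"))
  for (col in extra) {
    v <- df[[col]]
    num <- suppressWarnings(as.numeric(v))
    out[[col]] <- if (all(is.finite(num) | is.na(v))) num else v
  }
  out
}

#' Construct sample metadata
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param group `"control"` or `"case"` per sample.
#' @param group_label optional free-text label (e.g. the disease subtype).
#' @param ... further per-sample covariate vectors, e.g. `pampk = ...`.
#' @return data.frame with one row per sample.
#' @export
sample_metadata <- function(sample_id, group, group_label = group, ...) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  if (!all(group %in% c("control", "case")))
    stop("group must be 'control' or 'case'", call. = FALSE)
  data.frame(sample_id = sample_id,
             group = factor(group, levels = c("control", "case")),
             group_label = as.character(group_label),
             ...,
             stringsAsFactors = FALSE, row.names = NULL,
             check.names = FALSE)
}

#' Write sample metadata as TSV
#' @param meta data.frame from [sample_metadata()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  out <- meta
  out$group <- as.character(out$group)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Check that every sample of a matrix has metadata
#' @keywords internal
match_metadata <- function(expr, meta) {
  missing <- setdiff(colnames(expr), meta$sample_id)
  if (length(missing))
    stop("sample(s) without metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  meta[match(colnames(expr), meta$sample_id), , drop = FALSE]
}
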