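# Readers/writers for the delimited matrix formats used throughout: expression
# (genes x samples), drug response AUC (drugs x samples), and the two-column
# drug -> mechanism-class annotation. All matrices are plain numeric matrices
# with row IDs in rownames and sample IDs in colnames.

MISSING_TOKENS <- c("", "NA", "NaN")

#' Read a delimited expression or drug-response matrix
#'
#' Reads a delimited text file with one header row of sample identifiers and a
#' leading ID column (gene symbols or drug names). The delimiter is
#' auto-detected between tab and comma from the header line. Missing cells
#' (empty, `NA`, `NaN`) are handled per row: rows with more than
#' `max_missing_frac` missing are dropped, the remainder are mean-imputed
#' (default) or dropped, depending on `impute`.
#'
#' @param path Path to a delimited text file.
#' @param orientation Either `"rows-are-genes"` or `"rows-are-drugs"`; only
#'   recorded as the `"kind"` attribute of the result.
#' @param max_missing_frac Rows with a larger fraction of missing values are
#'   dropped (with a message).
#' @param impute `"row-mean"` (default) to impute remaining missing cells with
#'   the row mean, `"drop"` to drop any row with a missing value.
#' @return A numeric matrix with IDs as `rownames` and sample IDs as
#'   `colnames`, in file order.
#' @export
read_matrix <- function(path,
                        orientation = c("rows-are-genes", "rows-are-drugs"),
                        max_missing_frac = 0.2,
                        impute = c("row-mean", "drop")) {
  orientation <- match.arg(orientation)
  impute <- match.arg(impute)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_delim(path)
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          na.strings = MISSING_TOKENS, colClasses = "character",
                          data.table = FALSE, showProgress = FALSE)
  if (ncol(dt) < 2L) stop("matrix file needs an ID column plus >=1 sample column")
  ids <- as.character(dt[[1L]])
  sample_ids <- colnames(dt)[-1L]
  if (anyDuplicated(ids)) {
    stop("duplicate row IDs: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  vals <- matrix(NA_real_, nrow = nrow(dt), ncol = length(sample_ids),
                 dimnames = list(ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- dt[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad)) {
      stop(sprintf("non-numeric cell '%s' at row %d (ID %s), column %s",
                   col[bad[1L]], bad[1L], ids[bad[1L]], sample_ids[j]))
    }
    vals[, j] <- num
  }
  vals <- handle_missing(vals, max_missing_frac, impute)
  attr(vals, "kind") <- orientation
  vals
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_com <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_tab >= n_com) "\t" else ","
}

handle_missing <- function(vals, max_missing_frac, impute) {
  miss_frac <- rowMeans(is.na(vals))
  drop <- miss_frac > max_missing_frac
  if (any(drop)) {
    message(sum(drop), " row(s) dropped with >",
            round(100 * max_missing_frac), "% missing: ",
            paste(utils::head(rownames(vals)[drop], 5L), collapse = ", "))
    vals <- vals[!drop, , drop = FALSE]
  }
  if (anyNA(vals)) {
    if (impute == "drop") {
      keep <- !apply(is.na(vals), 1L, any)
      message(sum(!keep), " row(s) with missing values dropped")
      vals <- vals[keep, , drop = FALSE]
    } else {
      na_rows <- which(apply(is.na(vals), 1L, any))
      message(length(na_rows), " row(s) mean-imputed")
      for (i in na_rows) {
        row <- vals[i, ]
        row[is.na(row)] <- mean(row, na.rm = TRUE)
        vals[i, ] <- row
      }
    }
  }
  if (nrow(vals) && !all(is.finite(vals))) {
    stop("non-finite values remain after missing-value handling")
  }
  vals
}

#' Write a matrix in the package's delimited format
#'
#' The inverse of [read_matrix()]: one header row of sample IDs, a leading ID
#' column, values rendered at full double precision so that
#' `read_matrix(write_matrix(x))` is a bitwise round trip.
#'
#' @param x Numeric matrix with dimnames.
#' @param path Output path.
#' @param sep Field delimiter (tab by default).
#' @param id_name Header for the leading ID column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, sep = "\t", id_name = "id") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  header <- paste(c(id_name, colnames(x)), collapse = sep)
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], sprintf("%.17g", x[i, ])), collapse = sep)
  }, character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Restrict two matrices to their shared samples
#'
#' Both matrices are restricted to the (sorted) intersection of their sample
#' IDs, in identical order, so the result is invariant to the column order of
#' the inputs. Dropped samples are reported via `message()`.
#'
#' @param X,Y Numeric matrices with sample IDs in `colnames` (e.g. expression
#'   genes x samples and drug response drugs x samples).
#' @return A list with elements `X` and `Y`, column-aligned.
#' @export
align_samples <- function(X, Y) {
  shared <- sort(intersect(colnames(X), colnames(Y)))
  if (length(shared) < 3L) {
    stop("fewer than 3 shared samples (", length(shared),
         "); correlation would be degenerate")
  }
  drop_x <- setdiff(colnames(X), shared)
  drop_y <- setdiff(colnames(Y), shared)
  if (length(drop_x)) message("dropped from X: ", paste(drop_x, collapse = ", "))
  if (length(drop_y)) message("dropped from Y: ", paste(drop_y, collapse = ", "))
  list(X = X[, shared, drop = FALSE], Y = Y[, shared, drop = FALSE])
}

# Internal guard used by every operation consuming an (X, Y) pair.
assert_aligned <- function(X, Y) {
  if (!identical(colnames(X), colnames(Y))) {
    stop("matrices are not sample-aligned; run align_samples() first")
  }
  invisible(TRUE)
}

#' Read a drug-to-mechanism-class annotation
#'
#' Two-column delimited file (`drug_id`, `class`); repeated `drug_id` rows
#' encode multi-class membership (screens typically assign at most two broad
#' mechanism classes per drug; more than two triggers a warning).
#'
#' @param path Path to a two-column delimited file.
#' @return A named list mapping each drug to a character vector of class
#'   labels, with class `"drug_class_annotation"`.
#' @export
read_drug_classes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (length(readLines(path, n = 1L)) == 0L) stop("empty drug-class file: ", path)
  sep <- detect_delim(path)
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          colClasses = "character", data.table = FALSE,
                          showProgress = FALSE)
  if (nrow(dt) == 0L) stop("drug-class file has no rows: ", path)
  if (ncol(dt) < 2L) stop("drug-class file needs two columns (drug_id, class)")
  drug <- as.character(dt[[1L]])
  label <- as.character(dt[[2L]])
  if (any(is.na(label) | !nzchar(label))) stop("empty class label in ", path)
  ann <- lapply(split(label, drug), unique)
  ann <- ann[unique(drug)]  # preserve first-occurrence order
  n_over <- sum(lengths(ann) > 2L)
  if (n_over) warning(n_over, " drug(s) carry >2 class labels")
  classes <- unique(unlist(ann))
  tab <- table(unlist(ann))
  message(sprintf(
    "%d drugs, %d classes (%d with >1 drug), %d multi-class drugs",
    length(ann), length(classes), sum(tab > 1L), sum(lengths(ann) > 1L)))
  structure(ann, class = "drug_class_annotation")
}

#' Drug-by-class membership indicator matrix
#'
#' Expands a [read_drug_classes()] annotation into a binary drugs x classes
#' matrix over a given drug universe; multi-class drugs get a 1 in each of
#' their classes.
#'
#' @param classes A `drug_class_annotation` (named list drug -> classes).
#' @param universe Character vector of drug IDs to use as rows (default: all
#'   annotated drugs).
#' @return Binary matrix, drugs x classes.
#' @export
class_membership_matrix <- function(classes, universe = names(classes)) {
  labs <- sort(unique(unlist(classes[intersect(universe, names(classes))])))
  M <- matrix(0L, nrow = length(universe), ncol = length(labs),
              dimnames = list(universe, labs))
  for (d in intersect(universe, names(classes))) M[d, classes[[d]]] <- 1L
  M
}
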