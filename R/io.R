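#' Read a cells x features count table
#'
#' CSV tables are cells-as-rows with a leading cell-id column and one
#' column per feature; MatrixMarket input is features x cells (the
#' single-cell sparse convention) with feature and cell labels in
#' `<path>.features` / `<path>.cells` sidecar files, and is transposed on
#' read.  Feature ids are validated: PLA products are `"i:j"`, and the
#' free-oligo forms `"<p>:free_oligo_B"` / `"free_oligo_A:<p>"` mark
#' non-proximal probe counts.
#'
#' @param path input file.
#' @param format `"csv"` or `"mtx"`.
#' @return numeric matrix with cell rownames and feature colnames; the
#'   feature classification is in `attr(, "feature_type")` (`"pla"`,
#'   `"nonproximal_a"` or `"nonproximal_b"`).
#' @export
read_count_table <- function(path, format = c("csv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("count table needs a cell-id column and at ",
                            "least one feature column")
    feat <- names(df)[-1L]
    if (anyDuplicated(feat))          # subsetting would silently rename
      stop("duplicate feature ids: ",
           paste(unique(feat[duplicated(feat)]), collapse = ", "))
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) {
      badc <- colnames(df)[-1L][!vapply(df[-1L], is.numeric, TRUE)]
      stop("non-numeric entries in column(s): ",
           paste(badc, collapse = ", "))
    }
    rownames(m) <- ids
  } else {
    sp <- Matrix::readMM(path)
    feat <- readLines(paste0(path, ".features"))
    cells <- readLines(paste0(path, ".cells"))
    if (nrow(sp) != length(feat) || ncol(sp) != length(cells))
      stop("MTX dimensions do not match sidecar label files")
    m <- t(as.matrix(sp))
    dimnames(m) <- list(cells, feat)
  }
  if (anyDuplicated(rownames(m)))
    stop("duplicate cell ids: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]),
               collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stop("duplicate feature ids: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]),
               collapse = ", "))
  if (anyNA(m)) stop("missing values in count table")
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop("negative count at cell '", rownames(m)[bad[1L]],
         "', feature '", colnames(m)[bad[2L]], "'")
  }
  attr(m, "feature_type") <- classify_features(colnames(m))
  m
}

# Classify feature ids into PLA products and free-oligo (non-proximal)
# counts; errors name the offending column.
classify_features <- function(ids) {
  ab <- parse_product_ids(ids)
  type <- rep("pla", length(ids))
  type[ab$b == "free_oligo_B"] <- "nonproximal_a"
  type[ab$a == "free_oligo_A"] <- "nonproximal_b"
  setNames(type, ids)
}

#' Write a cells x features count table
#'
#' Inverse of [read_count_table()]: CSV with a `cell_id` column, or
#' MatrixMarket (features x cells) with label sidecars.  A written table
#' reads back with identical values and labels.
#'
#' @param x numeric matrix with cell rownames and feature colnames.
#' @param path output file.
#' @param format `"csv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path, format = c("csv", "mtx")) {
  format <- match.arg(format)
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("count matrix must have cell and feature names")
  if (format == "csv") {
    df <- data.frame(cell_id = rownames(x), x, check.names = FALSE,
                     row.names = NULL)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(t(x), sparse = TRUE), path)
    writeLines(colnames(x), paste0(path, ".features"))
    writeLines(rownames(x), paste0(path, ".cells"))
  }
  invisible(path)
}
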