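# Shared helpers for cells x PLA-products matrices whose columns are named
# "<proteinA>:<proteinB>".

# Parse product ids into probe-A / probe-B protein labels.
parse_product_ids <- function(ids) {
  parts <- strsplit(ids, ":", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop("malformed PLA product id(s): ", paste(ids[bad], collapse = ", "),
         " (expected \"<proteinA>:<proteinB>\")")
  data.frame(a = vapply(parts, `[`, "", 1L),
             b = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

# Index structure of a square product panel: protein list in panel order and
# integer a/b indices per product, plus 0/1 membership matrices used for fast
# per-cell margin sums (X %*% memb_a gives the probe-A margins).
panel_index <- function(x) {
  ids <- colnames(x)
  if (is.null(ids)) stop("count matrix must have product column names")
  ab <- parse_product_ids(ids)
  prots <- unique(c(rbind(ab$a, ab$b)))
  ai <- match(ab$a, prots)
  bi <- match(ab$b, prots)
  n <- length(prots)
  memb_a <- matrix(0, length(ids), n, dimnames = list(ids, prots))
  memb_b <- memb_a
  memb_a[cbind(seq_along(ids), ai)] <- 1
  memb_b[cbind(seq_along(ids), bi)] <- 1
  list(proteins = prots, a = ai, b = bi, memb_a = memb_a, memb_b = memb_b)
}

#' Per-cell protein abundance from PLA counts
#'
#' The abundance of protein i in a cell is the total appearance of i across
#' its PLA products, `Protein_i = sum_l X[i,l] + sum_k X[k,i]`; the
#' homodimer product i:i is counted twice because a homodimer carries two
#' molecules of the protein.
#'
#' @param x cells x products count matrix with "i:j" column names.
#' @return cells x proteins matrix of estimated protein counts.
#' @examples
#' x <- matrix(c(10, 0, 0, 0), 1, dimnames = list("c1",
#'   c("P1:P1", "P1:P2", "P2:P1", "P2:P2")))
#' protein_abundance(x)   # P1 = 20
#' @export
protein_abundance <- function(x) {
  x <- as.matrix(x)
  pi <- panel_index(x)
  x %*% pi$memb_a + x %*% pi$memb_b
}

#' Expected PLA counts under the random-ligation (independence) model
#'
#' For each cell the expected count of product i:j is
#' `E[i,j] = (sum_l X[i,l]) * (sum_k X[k,j]) / sum(X)`: the joint
#' probability of drawing probe A = i and probe B = j from the cell's
#' margins times its total PLA count.  Row and column margins of `E` equal
#' those of `X` in every cell.  Cells with zero total count get `E = 0` and
#' are flagged in `attr(, "zero_cells")`.
#'
#' @param x cells x products count matrix with "i:j" column names.
#' @return cells x products matrix of expected counts.
#' @export
expected_pla_count <- function(x) {
  x <- as.matrix(x)
  pi <- panel_index(x)
  row_m <- x %*% pi$memb_a      # per-cell probe-A margins
  col_m <- x %*% pi$memb_b
  tot <- rowSums(x)
  zero <- tot <= 0
  tot[zero] <- 1
  e <- (row_m[, pi$a, drop = FALSE] * col_m[, pi$b, drop = FALSE]) / tot
  e[zero, ] <- 0
  dimnames(e) <- dimnames(x)
  attr(e, "zero_cells") <- unname(which(zero))
  e
}

# Split a non-proximal ("free oligo") count matrix into per-protein A' and
# B' matrices.  Columns "<p>:free_oligo_B" carry the unligated probe-A count
# of protein p; "free_oligo_A:<p>" the unligated probe-B count.
split_nonproximal <- function(np, proteins) {
  np <- as.matrix(np)
  ids <- colnames(np)
  if (is.null(ids)) stop("non-proximal matrix must have column names")
  a_cols <- paste0(proteins, ":free_oligo_B")
  b_cols <- paste0("free_oligo_A:", proteins)
  missing <- setdiff(c(a_cols, b_cols), ids)
  if (length(missing))
    stop("non-proximal counts missing for: ",
         paste(missing, collapse = ", "))
  a <- np[, a_cols, drop = FALSE]
  b <- np[, b_cols, drop = FALSE]
  colnames(a) <- colnames(b) <- proteins
  list(a = a, b = b)
}

# Constructor for prediction results shared by all methods.
new_complex_prediction <- function(y, detected, p_adj, method,
                                   iterations = NA_integer_,
                                   converged = NA, coefficients = NULL,
                                   flags = character(0)) {
  structure(list(y = y, detected = detected, p_adj = p_adj,
                 method = method, iterations = iterations,
                 converged = converged, coefficients = coefficients,
                 flags = flags),
            class = "complex_prediction")
}

#' @export
print.complex_prediction <- function(x, ...) {
  cat("Protein-complex prediction (", x$method, "): ",
      sum(x$detected), "/", length(x$detected),
      " products detected\n", sep = "")
  if (sum(x$detected))
    cat("  detected:", paste(names(which(x$detected)), collapse = ", "),
        "\n")
  if (!is.na(x$iterations)) cat("  iterations:", x$iterations,
                                " converged:", x$converged, "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "),
                           "\n")
  invisible(x)
}
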