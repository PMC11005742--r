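#' Phased haplotype window
#'
#' The atomic input to all summary statistics: a binary haplotype-by-site
#' matrix (0 = ancestral, 1 = derived) with strictly increasing physical
#' positions. Monomorphic columns are dropped at construction so that every
#' retained site is polymorphic within the parent fragment.
#'
#' @param matrix binary matrix, haplotypes in rows, segregating sites in
#'   columns; entries must be 0/1.
#' @param positions numeric vector of per-site physical coordinates (bp),
#'   strictly increasing, one per column.
#' @param span length-2 numeric `(start_bp, end_bp)` of the parent fragment;
#'   defaults to the position range.
#' @param drop_monomorphic drop columns that are all-0 or all-1 (default TRUE).
#' @return an object of class `hap_window` with elements `matrix`,
#'   `positions`, `n_hap`, `span`.
#' @export
hap_window <- function(matrix, positions, span = NULL, drop_monomorphic = TRUE) {
  matrix <- as.matrix(matrix)
  dimnames(matrix) <- NULL
  storage.mode(matrix) <- "integer"
  if (nrow(matrix) < 2L) stop("hap_window needs at least 2 haplotypes")
  if (length(positions) != ncol(matrix))
    stop("positions length must equal the number of sites")
  if (any(matrix != 0L & matrix != 1L)) stop("haplotype matrix must be 0/1")
  if (ncol(matrix) > 1L && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (drop_monomorphic && ncol(matrix) > 0L) {
    cs <- colSums(matrix)
    keep <- cs > 0L & cs < nrow(matrix)
    matrix <- matrix[, keep, drop = FALSE]
    positions <- positions[keep]
  }
  if (is.null(span)) {
    span <- if (length(positions)) range(positions) else c(0, 0)
  }
  structure(
    list(matrix = matrix, positions = as.numeric(positions),
         n_hap = nrow(matrix), span = as.numeric(span)),
    class = "hap_window")
}

#' @export
print.hap_window <- function(x, ...) {
  cat(sprintf("<hap_window> %d haplotypes x %d segregating sites, span [%.0f, %.0f] bp\n",
              x$n_hap, ncol(x$matrix), x$span[1], x$span[2]))
  invisible(x)
}

#' Extract a sub-window of consecutive sites
#'
#' @param win a `hap_window`.
#' @param cols integer indices of sites to keep (consecutive for EHH use).
#' @return a `hap_window` over the selected sites (monomorphic columns kept:
#'   sub-windows inherit polymorphy from the parent fragment).
#' @export
hap_subwindow <- function(win, cols) {
  hap_window(win$matrix[, cols, drop = FALSE], win$positions[cols],
             span = win$span, drop_monomorphic = FALSE)
}

#' Distinct-haplotype grouping of the rows of a haplotype matrix
#'
#' Rows are hashed chunk-wise (30 sites per chunk, base-2 weights) so that
#' identical rows receive identical integer codes.
#'
#' @param mat 0/1 matrix.
#' @return integer vector of group codes in `1..G`.
#' @keywords internal
hap_row_groups <- function(mat) {
  S <- ncol(mat)
  if (S == 0L) return(rep(1L, nrow(mat)))
  if (S <= 30L) {
    key <- as.vector(mat %*% 2^(seq_len(S) - 1))
    return(match(key, unique(key)))
  }
  chunks <- split(seq_len(S), ceiling(seq_len(S) / 30))
  g <- rep(1, nrow(mat))
  for (cc in chunks) {
    key <- (g - 1) * 2^31 + as.vector(mat[, cc, drop = FALSE] %*% 2^(seq_along(cc) - 1))
    g <- match(key, unique(key))
  }
  g
}
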