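#' Fragment / feature-engineering specification
#'
#' Controls how a genomic fragment is converted into a feature matrix:
#' `n` SNP-centered feature windows of `2k+1` SNPs each, positionally
#' encoded onto `m` equal bp intervals of the fragment length `L`; `w`/`s`
#' are the genome sliding-window size and step for real-data scans.
#'
#' @param n number of feature windows (default 200).
#' @param k flank SNPs on each side of a window's central SNP (default 25).
#' @param m positional-encoding intervals (default 200).
#' @param L fragment length in bp (default 1e6, matching `w`).
#' @param w genome sliding-window size in bp (default 1e6).
#' @param s genome step in bp (default 5e4).
#' @return a `fragment_spec` list.
#' @export
fragment_spec <- function(n = 200L, k = 25L, m = 200L, L = 1e6, w = 1e6, s = 5e4) {
  stopifnot(n >= 1, k >= 1, m >= 1, w >= s)
  structure(list(n = as.integer(n), k = as.integer(k), m = as.integer(m),
                 L = L, w = w, s = s), class = "fragment_spec")
}

#' Select n central SNPs with k-SNP flanks, evenly spaced
#'
#' A fragment with fewer than `2k + n` SNPs is excluded (returns `NULL`).
#' Otherwise `n` indices are spread as evenly as possible over the eligible
#' range `[k+1, total - k]` (1-based) via
#' `round(k + t (total - 2k - 1)/(n - 1))`, t = 0..n-1.
#'
#' @param total_sites number of SNPs in the fragment.
#' @param spec a [fragment_spec()].
#' @return integer vector of `n` central-SNP indices, or `NULL` if excluded.
#' @export
select_central_snps <- function(total_sites, spec) {
  n <- spec$n; k <- spec$k
  if (total_sites < 2L * k + n) return(NULL)
  if (n == 1L) return(as.integer(k + 1L + round((total_sites - 2L * k - 1L) / 2)))
  t <- 0:(n - 1L)
  idx <- k + 1L + as.integer(round(t * (total_sites - 2L * k - 1L) / (n - 1L)))
  pmin(pmax(idx, k + 1L), total_sites - k)
}

#' Raw 40 x n statistic matrix over SNP windows
#'
#' Column j holds the statistic vector of the `2k+1`-SNP window centered on
#' central SNP j; window positions are the mean physical position of each
#' window's SNPs.
#'
#' @param fragment a [hap_window()] covering the fragment.
#' @param spec a [fragment_spec()].
#' @param registry statistic registry.
#' @param ctx run-level statistic context (see [compute_stat_vector()]).
#' @return list `grid` (nstat x n), `positions` (length n), or `NULL` when
#'   the fragment is excluded by the `2k + n` rule.
#' @export
build_raw_matrix <- function(fragment, spec, registry = sweep_stat_registry(),
                             ctx = list(baseline = 0.5)) {
  S <- ncol(fragment$matrix)
  centers <- select_central_snps(S, spec)
  if (is.null(centers)) return(NULL)
  k <- spec$k
  cols <- lapply(centers, function(cc) (cc - k):(cc + k))
  grid <- vapply(cols, function(ccols) {
    compute_stat_vector(hap_subwindow(fragment, ccols), registry, ctx)
  }, numeric(length(registry)))
  positions <- vapply(cols, function(ccols) mean(fragment$positions[ccols]),
                      numeric(1))
  list(grid = grid, positions = positions, names = names(registry))
}

#' Positional encoding onto m equal intervals
#'
#' Each fragment is divided into `m` equal bp intervals (left-open,
#' right-closed; position 0 falls in interval 1). Cell (i, j) is the mean of
#' statistic i over the windows whose mean position falls in interval j;
#' empty intervals are zero-filled to indicate absence of variation.
#'
#' @param raw list from [build_raw_matrix()] (`grid`, `positions`).
#' @param spec a [fragment_spec()] supplying `m` and `L`.
#' @param origin bp coordinate of the fragment start (default 0).
#' @return a `feature_matrix` list: `grid` (nstat x m), `interval_edges`,
#'   `window_positions`, `names`.
#' @export
positional_encode <- function(raw, spec, origin = 0) {
  m <- spec$m; L <- spec$L
  rel <- raw$positions - origin
  bin <- ceiling(rel / (L / m))
  bin[rel <= 0] <- 1L
  bin <- pmin(pmax(bin, 1L), m)
  grid <- matrix(0, nrow(raw$grid), m)
  agg <- rowsum(t(raw$grid), bin)            # intervals x nstat
  grid[, as.integer(rownames(agg))] <- t(agg / as.vector(table(bin)[rownames(agg)]))
  structure(list(grid = grid, interval_edges = seq(0, L, length.out = m + 1),
                 window_positions = raw$positions, names = raw$names),
            class = "feature_matrix")
}

#' Featurize a set of haplotype fragments
#'
#' Runs the full pipeline (central-SNP selection, per-window statistics,
#' positional encoding) over a list of fragments, using a shared run-level
#' derived-allele-frequency baseline for the delta-AF statistic.
#'
#' @param fragments list of [hap_window()] objects.
#' @param spec a [fragment_spec()].
#' @param registry statistic registry.
#' @param origin per-fragment start coordinates (scalar or vector,
#'   default 0: simulated fragments on `[0, L)`).
#' @return list `x` (array nstat x m x N), `names`, `kept` (logical: fragments
#'   passing the exclusion rule), `baseline`.
#' @export
featurize_fragments <- function(fragments, spec,
                                registry = sweep_stat_registry(), origin = 0) {
  origin <- rep_len(origin, length(fragments))
  baseline <- mean(vapply(fragments, function(fr) {
    if (ncol(fr$matrix) == 0L) return(NA_real_)
    mean(colSums(fr$matrix) / fr$n_hap)
  }, numeric(1)), na.rm = TRUE)
  ctx <- list(baseline = baseline)
  mats <- vector("list", length(fragments))
  kept <- logical(length(fragments))
  for (i in seq_along(fragments)) {
    raw <- build_raw_matrix(fragments[[i]], spec, registry, ctx)
    if (is.null(raw)) next
    mats[[i]] <- positional_encode(raw, spec, origin[i])$grid
    kept[i] <- TRUE
  }
  mats <- mats[kept]
  x <- array(0, c(length(registry), spec$m, length(mats)))
  for (i in seq_along(mats)) x[, , i] <- mats[[i]]
  list(x = x, names = names(registry), kept = kept, baseline = baseline)
}

#' Max-min standardization of a feature dataset
#'
#' Scales each feature row to `[0, 1]` using per-row min/max pooled across
#' positions and cases. In fit mode the scale is computed from the data and
#' returned for reuse; in apply mode a stored scale is re-applied (values are
#' clipped to `[0, 1]`). Non-finite entries are clamped to the row's finite
#' extremes (`+Inf` to the max, `-Inf`/`NA` to the min) before scaling so a
#' single degenerate window cannot destroy the scaling. Constant rows map
#' to 0.
#'
#' @param x array (nstat x m x N).
#' @param scale optional list with `min`, `max` per feature row; when `NULL`
#'   (fit mode) it is computed from `x`.
#' @return list `x` (standardized array), `scale`.
#' @export
minmax_standardize <- function(x, scale = NULL) {
  nstat <- dim(x)[1]
  xm <- matrix(x, nstat)                     # nstat x (m*N)
  for (i in seq_len(nstat)) {
    row <- xm[i, ]
    bad <- !is.finite(row)
    if (any(bad)) {
      fin <- row[!bad]
      lo <- if (length(fin)) min(fin) else 0
      hi <- if (length(fin)) max(fin) else 0
      hi_mask <- bad & !is.na(row) & row > 0   # +Inf
      row[bad & !hi_mask] <- lo                # -Inf, NA, NaN
      row[hi_mask] <- hi
      xm[i, ] <- row
    }
  }
  if (is.null(scale)) {
    scale <- list(min = apply(xm, 1, min), max = apply(xm, 1, max))
  }
  rng <- scale$max - scale$min
  rng[rng == 0] <- 1
  out <- (xm - scale$min) / rng
  out[out < 0] <- 0
  out[out > 1] <- 1
  zero <- which(scale$max == scale$min)
  if (length(zero)) out[zero, ] <- 0
  array(out, dim(x)) -> xs
  list(x = xs, scale = scale)
}

#' Split a chromosome's variants into sliding-window fragments
#'
#' Half-open fragments `[a, a+w)` advancing by step `s`; a chromosome
#' shorter than `w` yields a single fragment covering it.
#'
#' @param positions sorted variant positions (bp).
#' @param chrom_length chromosome length in bp (default max position).
#' @param spec a [fragment_spec()] supplying `w` and `s`.
#' @return list of lists `start`, `end`, `site_idx` (indices into
#'   `positions`); fragments with zero variants are retained with empty
#'   `site_idx` (callers apply the `2k+n` exclusion rule downstream).
#' @export
genome_to_fragments <- function(positions, chrom_length = NULL, spec) {
  if (!length(positions)) return(list())
  if (is.null(chrom_length)) chrom_length <- max(positions)
  if (is.unsorted(positions)) stop("positions must be sorted")
  w <- spec$w; s <- spec$s
  starts <- if (chrom_length <= w) 0 else seq(0, chrom_length - w, by = s)
  lapply(starts, function(a) {
    b <- min(a + w, chrom_length)
    list(start = a, end = b,
         site_idx = which(positions >= a & positions < a + w))
  })
}
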