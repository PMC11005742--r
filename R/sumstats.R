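#' @title Summary statistics for selective-sweep feature engineering
#' @description Per-window population-genetic summary statistics organised as
#'   a fixed-order registry of 40 named features covering three groups:
#'   polymorphism / site-frequency-spectrum shape, favored-mutation
#'   localisation (HAF, phi, kappa, SAFE), and haplotype-structure statistics
#'   distinguishing hard from soft sweeps (H1, H12, H123, H2/H1, EHH family).
#' @name sumstats
NULL

#' Nucleotide diversity (pi)
#'
#' Mean pairwise difference per window:
#' `pi = sum_sites 2 c_i (n - c_i) / (n (n-1))` with `c_i` the derived count.
#'
#' @param win a [hap_window()].
#' @return non-negative scalar; 0 for a window with no segregating sites.
#' @export
nucleotide_diversity <- function(win) {
  n <- win$n_hap
  cs <- colSums(win$matrix)
  if (!length(cs)) return(0)
  sum(2 * cs * (n - cs)) / (n * (n - 1))
}

#' Watterson's theta
#'
#' `S / a_n`, `a_n = sum_{i=1}^{n-1} 1/i`.
#' @param win a [hap_window()].
#' @return non-negative scalar.
#' @export
watterson_theta <- function(win) {
  n <- win$n_hap
  S <- ncol(win$matrix)
  if (S == 0L) return(0)
  S / sum(1 / seq_len(n - 1))
}

#' Fay and Wu's theta_H and H
#'
#' `theta_H = sum_i 2 xi_i i^2 / (n (n-1))` over unfolded SFS classes;
#' `H = pi - theta_H`. Requires derived/ancestral polarization.
#'
#' @param win a [hap_window()].
#' @return list with `theta_h` and `h`.
#' @export
fay_wu_h <- function(win) {
  n <- win$n_hap
  cs <- colSums(win$matrix)
  if (!length(cs)) return(list(theta_h = 0, h = 0))
  th <- sum(2 * cs^2) / (n * (n - 1))
  list(theta_h = th, h = nucleotide_diversity(win) - th)
}

#' Tajima's D
#'
#' Standard normalization of `pi - theta_W` (returns 0 when undefined:
#' fewer than 3 haplotypes or no segregating sites).
#' @param win a [hap_window()].
#' @return scalar.
#' @export
tajimas_d <- function(win) {
  n <- win$n_hap
  S <- ncol(win$matrix)
  if (S == 0L || n < 3L) return(0)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  denom <- sqrt(e1 * S + e2 * S * (S - 1))
  if (denom == 0) return(0)
  (nucleotide_diversity(win) - watterson_theta(win)) / denom
}

#' Unfolded site frequency spectrum
#'
#' @param win a [hap_window()].
#' @return integer vector of length `n_hap - 1`; entry i is the number of
#'   sites with derived-allele count i.
#' @export
site_frequency_spectrum <- function(win) {
  tabulate(colSums(win$matrix), nbins = win$n_hap - 1L)
}

#' Moments and entropy of the site-frequency distribution
#'
#' Raw moments 1..5 of the per-site derived-allele frequency (each segregating
#' site is one observation) and the Shannon entropy (natural log) of the
#' occupied SFS classes.
#'
#' @param sfs integer SFS vector as from [site_frequency_spectrum()].
#' @param n_hap haplotype count the SFS refers to.
#' @return named numeric vector `m1..m5, entropy`; all zero for an empty SFS.
#' @export
sfs_moments <- function(sfs, n_hap) {
  out <- c(m1 = 0, m2 = 0, m3 = 0, m4 = 0, m5 = 0, entropy = 0)
  S <- sum(sfs)
  if (S == 0) return(out)
  f <- seq_along(sfs) / n_hap
  w <- sfs / S
  for (k in 1:5) out[k] <- sum(w * f^k)
  p <- w[w > 0]
  out["entropy"] <- -sum(p * log(p))
  out
}

#' Haplotype frequency spectrum
#'
#' Relative frequencies of the distinct haplotypes in a window, sorted
#' descending.
#' @param win a [hap_window()].
#' @return numeric vector summing to 1, length = number of distinct rows.
#' @export
hap_spectrum <- function(win) {
  g <- hap_row_groups(win$matrix)
  sort(tabulate(g) / win$n_hap, decreasing = TRUE)
}

#' Haplotype-homozygosity statistics (Garud family)
#'
#' `H1 = sum p_i^2`; `H12` pools the top two haplotypes; `H123` the top
#' three; `H2/H1 = (H1 - p1^2)/H1`; heterozygosity `= 1 - H1`.
#'
#' @param hfs descending haplotype frequency spectrum from [hap_spectrum()].
#' @return named list `h1, h12, h123, h2_h1, het`.
#' @export
garud_h_stats <- function(hfs) {
  p <- sort(hfs, decreasing = TRUE)
  h1 <- sum(p^2)
  top2 <- sum(p[seq_len(min(2, length(p)))])
  top3 <- sum(p[seq_len(min(3, length(p)))])
  h12 <- top2^2 + if (length(p) > 2) sum(p[-(1:2)]^2) else 0
  h123 <- top3^2 + if (length(p) > 3) sum(p[-(1:3)]^2) else 0
  list(h1 = h1, h12 = h12, h123 = h123,
       h2_h1 = (h1 - p[1]^2) / h1, het = 1 - h1)
}

#' Haplotype allele frequency (HAF) scores
#'
#' `HAF(h)` is the sum, over the derived alleles carried by haplotype `h`,
#' of each allele's derived count in the window.
#'
#' @param win a [hap_window()].
#' @return numeric vector of per-haplotype HAF scores.
#' @export
haf_scores <- function(win) {
  cs <- colSums(win$matrix)
  as.numeric(win$matrix %*% cs)
}

#' Per-site phi, kappa and SAFE scores
#'
#' For each variant v: `phi(v)` = HAF mass of v's carriers over total HAF
#' mass; `kappa(v)` = distinct haplotypes among carriers over distinct
#' haplotypes overall. The SAFE score is the phi-kappa contrast standardized
#' by the binomial-null standard deviation at the variant's frequency:
#' `SAFE = (phi - kappa) / sqrt(f (1 - f))`, `f` the derived frequency.
#'
#' @param win a [hap_window()].
#' @return list of per-site vectors `phi`, `kappa`, `safe`.
#' @export
safe_family <- function(win) {
  mat <- win$matrix
  S <- ncol(mat)
  if (S == 0L) return(list(phi = numeric(0), kappa = numeric(0), safe = numeric(0)))
  haf <- haf_scores(win)
  tot <- sum(haf)
  phi <- if (tot > 0) as.numeric(crossprod(mat, haf)) / tot else rep(0, S)
  g <- hap_row_groups(mat)
  G <- max(g)
  member <- matrix(0L, nrow(mat), G)
  member[cbind(seq_len(nrow(mat)), g)] <- 1L
  carriers_per_group <- crossprod(member, mat)        # G x S
  kappa <- colSums(carriers_per_group > 0L) / G
  f <- colSums(mat) / win$n_hap
  safe <- (phi - kappa) / sqrt(f * (1 - f))
  list(phi = phi, kappa = kappa, safe = safe)
}

#' Extended haplotype homozygosity decay and its integrals
#'
#' EHH at distance x from the core site, within a carrier set, is the
#' probability that two random haplotypes from the set are identical at all
#' sites between the core and x. iHH integrates the decay curve by the
#' trapezoid rule on both sides of the core until EHH drops below `cutoff`
#' or the window edge is reached (fixed-size windows: truncation, no
#' discard).
#'
#' @param win a [hap_window()].
#' @param core_index column index of the core site.
#' @param carriers integer row indices of the carrier set (>= 2).
#' @param scale "bp" integrates over physical distance, "snp" over SNP index
#'   (the nSL convention).
#' @param cutoff EHH decay cutoff (default 0.05).
#' @return scalar iHH value.
#' @export
ehh_integral <- function(win, core_index, carriers, scale = c("bp", "snp"),
                         cutoff = 0.05) {
  scale <- match.arg(scale)
  nc <- length(carriers)
  if (nc < 2L) return(0)
  mat <- win$matrix[carriers, , drop = FALSE]
  S <- ncol(mat)
  trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
  side <- function(idx) {
    eh <- ehh_decay_curve(mat, idx, cutoff)
    if (!length(eh)) return(0)
    idx <- idx[seq_along(eh)]
    xs <- if (scale == "bp") abs(win$positions[idx] - win$positions[core_index])
          else seq_along(idx)
    trapz(c(0, xs), c(1, eh))       # EHH = 1 at distance 0
  }
  left  <- rev(seq_len(core_index - 1L))
  right <- if (core_index < S) (core_index + 1L):S else integer(0)
  side(left) + side(right)
}

# EHH decay along an ordered walk of site columns, truncated at the first
# value below cutoff (which is retained). Integer-key prefix grouping.
ehh_decay_curve <- function(mat, idx, cutoff) {
  nc <- nrow(mat)
  if (!length(idx)) return(numeric(0))
  g <- rep(1L, nc)
  eh <- numeric(length(idx))
  for (j in seq_along(idx)) {
    key <- 2L * g + mat[, idx[j]]
    g <- match(key, unique(key))
    tab <- tabulate(g)
    eh[j] <- sum(tab * (tab - 1)) / (nc * (nc - 1))
    if (eh[j] < cutoff) return(eh[seq_len(j)])
  }
  eh
}

#' iHS, nSL and delta-iHH at a core site (unstandardized)
#'
#' Contrasts integrated EHH of the ancestral- and derived-allele carrier
#' sets at the core: `iHS_unstd = ln(iHH_A / iHH_D)`, `nSL` the analog on
#' the SNP-count scale, `delta_iHH = iHH_A - iHH_D`.
#'
#' @param win a [hap_window()].
#' @param core_index column index of a polymorphic core site whose carrier
#'   and non-carrier sets each hold >= 2 haplotypes.
#' @return named list `ihs, nsl, delta_ihh, ihh_a, ihh_d` (ratios of zero
#'   integrals yield non-finite values, clamped downstream).
#' @export
ehh_family <- function(win, core_index) {
  der <- which(win$matrix[, core_index] == 1L)
  anc <- which(win$matrix[, core_index] == 0L)
  if (length(der) < 2L || length(anc) < 2L)
    return(list(ihs = 0, nsl = 0, delta_ihh = 0, ihh_a = 0, ihh_d = 0))
  S <- ncol(win$matrix)
  left  <- rev(seq_len(core_index - 1L))
  right <- if (core_index < S) (core_index + 1L):S else integer(0)
  trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
  both <- function(carriers) {      # one decay curve per side, two integrals
    mat <- win$matrix[carriers, , drop = FALSE]
    bp <- 0; snp <- 0
    for (idx in list(left, right)) {
      eh <- ehh_decay_curve(mat, idx, 0.05)
      if (!length(eh)) next
      ii <- idx[seq_along(eh)]
      bp <- bp + trapz(c(0, abs(win$positions[ii] - win$positions[core_index])),
                       c(1, eh))
      snp <- snp + trapz(c(0, seq_along(ii)), c(1, eh))
    }
    c(bp = bp, snp = snp)
  }
  d <- both(der); a <- both(anc)
  ihh_d <- d[["bp"]]; ihh_a <- a[["bp"]]
  nsl_d <- d[["snp"]]; nsl_a <- a[["snp"]]
  list(ihs = log(ihh_a / ihh_d), nsl = log(nsl_a / nsl_d),
       delta_ihh = ihh_a - ihh_d, ihh_a = ihh_a, ihh_d = ihh_d)
}

#' Within-run iHS standardization in derived-frequency bins
#'
#' Conventional z-scoring of unstandardized iHS within bins of the core
#' site's derived-allele frequency.
#'
#' @param values unstandardized iHS values.
#' @param freqs derived-allele frequency of each core site.
#' @param bins number of equal-width frequency bins (default 20).
#' @return z-scored values (bins with < 2 finite values pass through as 0).
#' @export
ihs_standardize <- function(values, freqs, bins = 20) {
  b <- pmin(pmax(ceiling(freqs * bins), 1L), bins)
  out <- numeric(length(values))
  for (bb in unique(b)) {
    i <- which(b == bb & is.finite(values))
    if (length(i) >= 2L && stats::sd(values[i]) > 0) {
      out[i] <- (values[i] - mean(values[i])) / stats::sd(values[i])
    }
  }
  out
}

#' Deviation of window derived-allele frequency from a run baseline
#'
#' @param win a [hap_window()].
#' @param baseline run-level mean derived-allele frequency.
#' @return `mean(column frequencies) - baseline` (0 for an empty window).
#' @export
delta_af <- function(win, baseline) {
  if (ncol(win$matrix) == 0L) return(0)
  mean(colSums(win$matrix) / win$n_hap) - baseline
}

#' The default 40-statistic registry
#'
#' An ordered, named list of statistic extractors. Each entry is a function
#' of a context list prepared once per window by [compute_stat_vector()]
#' (shared intermediates: derived counts, SFS, haplotype spectrum, HAF,
#' phi/kappa/SAFE vectors, EHH family at the central SNP). The roster is
#' configurable: pass any subset/reordering to [compute_stat_vector()] to
#' reproduce an alternative published roster.
#'
#' @return named list of 40 functions.
#' @export
sweep_stat_registry <- function() {
  list(
    pi            = function(cx) cx$pi,
    theta_w       = function(cx) cx$theta_w,
    theta_h       = function(cx) cx$theta_h,
    faywu_h       = function(cx) cx$faywu_h,
    tajimas_d     = function(cx) cx$tajd,
    n_seg_sites   = function(cx) cx$S,
    sfs_m1        = function(cx) cx$sfsm["m1"],
    sfs_m2        = function(cx) cx$sfsm["m2"],
    sfs_m3        = function(cx) cx$sfsm["m3"],
    sfs_m4        = function(cx) cx$sfsm["m4"],
    sfs_m5        = function(cx) cx$sfsm["m5"],
    sfs_entropy   = function(cx) cx$sfsm["entropy"],
    delta_af      = function(cx) cx$delta_af,
    singleton_prop = function(cx) if (cx$S > 0) mean(cx$counts == 1L) else 0,
    highfreq_prop = function(cx) if (cx$S > 0) mean(cx$counts / cx$n >= 0.8) else 0,
    window_span_kb = function(cx) cx$span_kb,
    n_hap_classes = function(cx) length(cx$hfs),
    hap_het       = function(cx) cx$garud$het,
    hap_entropy   = function(cx) -sum(cx$hfs * log(cx$hfs)),
    h1            = function(cx) cx$garud$h1,
    h12           = function(cx) cx$garud$h12,
    h123          = function(cx) cx$garud$h123,
    h2_h1         = function(cx) cx$garud$h2_h1,
    hap_top1      = function(cx) cx$hfs[1],
    hap_top2      = function(cx) if (length(cx$hfs) > 1) cx$hfs[2] else 0,
    ihs_unstd     = function(cx) cx$ehh$ihs,
    nsl_unstd     = function(cx) cx$ehh$nsl,
    delta_ihh     = function(cx) cx$ehh$delta_ihh,
    ihh_derived   = function(cx) cx$ehh$ihh_d,
    ihh_ancestral = function(cx) cx$ehh$ihh_a,
    haf_mean      = function(cx) mean(cx$haf),
    haf_max       = function(cx) max(cx$haf),
    haf_var       = function(cx) stats::var(cx$haf),
    phi_mean      = function(cx) if (cx$S > 0) mean(cx$safe$phi) else 0,
    phi_max       = function(cx) if (cx$S > 0) max(cx$safe$phi) else 0,
    kappa_mean    = function(cx) if (cx$S > 0) mean(cx$safe$kappa) else 0,
    kappa_min     = function(cx) if (cx$S > 0) min(cx$safe$kappa) else 0,
    safe_mean     = function(cx) if (cx$S > 0) mean(cx$safe$safe) else 0,
    safe_max      = function(cx) if (cx$S > 0) max(cx$safe$safe) else 0,
    safe_center   = function(cx) if (cx$S > 0) cx$safe$safe[cx$core] else 0
  )
}

#' Pick an EHH core site near the window center
#'
#' The central column, or the nearest column whose carrier and non-carrier
#' sets both hold >= 2 haplotypes; NA when no such site exists.
#' @keywords internal
pick_core_site <- function(counts, n) {
  S <- length(counts)
  if (S == 0L) return(NA_integer_)
  ok <- which(counts >= 2L & counts <= n - 2L)
  if (!length(ok)) return(NA_integer_)
  center <- (S + 1L) / 2
  ok[which.min(abs(ok - center))]
}

#' Compute the full statistic vector for one window
#'
#' Evaluates every registry entry on shared per-window intermediates.
#' Degenerate windows (no segregating sites) give a zero vector with a
#' warning. Non-finite entries (e.g. log-ratios of empty EHH integrals)
#' are left in place and clamped at run level by [minmax_standardize()].
#'
#' @param win a [hap_window()].
#' @param registry ordered statistic registry (default
#'   [sweep_stat_registry()]).
#' @param ctx run-level context; `ctx$baseline` is the run mean
#'   derived-allele frequency used by `delta_af` (default 0.5).
#' @return named numeric vector, one entry per registry slot.
#' @export
compute_stat_vector <- function(win, registry = sweep_stat_registry(),
                                ctx = list(baseline = 0.5)) {
  nstat <- length(registry)
  if (ncol(win$matrix) == 0L) {
    warning("degenerate window with no segregating sites: zero statistic vector")
    return(stats::setNames(numeric(nstat), names(registry)))
  }
  n <- win$n_hap
  counts <- colSums(win$matrix)
  sfs <- tabulate(counts, nbins = n - 1L)
  hfs <- hap_spectrum(win)
  fw <- fay_wu_h(win)
  core <- pick_core_site(counts, n)
  ehh <- if (is.na(core)) list(ihs = 0, nsl = 0, delta_ihh = 0, ihh_a = 0, ihh_d = 0)
         else ehh_family(win, core)
  cx <- list(
    n = n, S = ncol(win$matrix), counts = counts,
    pi = nucleotide_diversity(win), theta_w = watterson_theta(win),
    theta_h = fw$theta_h, faywu_h = fw$h, tajd = tajimas_d(win),
    sfsm = sfs_moments(sfs, n),
    delta_af = delta_af(win, if (is.null(ctx$baseline)) 0.5 else ctx$baseline),
    span_kb = (max(win$positions) - min(win$positions)) / 1000,
    hfs = hfs, garud = garud_h_stats(hfs),
    haf = haf_scores(win), safe = safe_family(win),
    core = if (is.na(core)) 1L else core, ehh = ehh)
  vapply(registry, function(f) as.numeric(f(cx))[1], numeric(1))
}

#' Approximate hard-sweep footprint length scale
#'
#' `s / (4 Ne r ln(Ne s))` with natural log: the helper used to reason about
#' how recombination-rate and selection-coefficient mismatches trade off.
#'
#' @param s selection coefficient.
#' @param Ne effective population size.
#' @param r per-bp recombination rate.
#' @return scalar length scale; errors when `Ne * s <= 1` (log non-positive).
#' @export
sweep_footprint <- function(s, Ne, r) {
  if (Ne * s <= 1) stop("sweep_footprint requires Ne * s > 1")
  s / (4 * Ne * r * log(Ne * s))
}
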