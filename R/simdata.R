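#' Scenario parameters for sweep simulation
#'
#' @param Ne effective population size (default 1e4).
#' @param r per-bp recombination rate. The default 1e-7 gives the 100 kb
#'   default fragments the same per-fragment recombination budget (and so
#'   the same sweep-footprint-to-fragment-length geometry) as megabase scan
#'   windows at the human-like 1e-8; set `r = 1e-8` together with `L = 1e6`
#'   for full-scale geometry.
#' @param mu per-bp mutation rate (default 1.25e-8).
#' @param s selection coefficient (default 0.05).
#' @param initial_freq starting frequency of the beneficial allele (0 for a
#'   de novo hard sweep; soft sweeps draw from `[0.01, 0.2]` when left at 0).
#' @param L fragment length in bp (default 1e5).
#' @param n_hap sampled haplotype count (default 50).
#' @param demographic_model `"constant"` or `"CEU"` (three-epoch style;
#'   affects the external-simulator command only).
#' @return a `scenario_params` list.
#' @export
scenario_params <- function(Ne = 1e4, r = 1e-7, mu = 1.25e-8, s = 0.05,
                            s_range = c(0.005, 0.1), initial_freq = 0,
                            L = 1e5, n_hap = 50L,
                            demographic_model = "constant") {
  stopifnot(Ne > 0, r > 0, mu > 0, s > 0, initial_freq >= 0, initial_freq < 1)
  structure(list(Ne = Ne, r = r, mu = mu, s = s, s_range = s_range,
                 initial_freq = initial_freq,
                 L = L, n_hap = as.integer(n_hap),
                 demographic_model = demographic_model),
            class = "scenario_params")
}

#' The five sweep classes, in canonical order
#' @return character vector `hard, linked_hard, soft, linked_soft, neutral`.
#' @export
sweep_classes <- function() c("hard", "linked_hard", "soft", "linked_soft", "neutral")

#' Draw a selected-site position consistent with a class label
#'
#' Sweep classes place the selected site within `(0.475 L, 0.525 L)`; linked
#' classes outside that central segment (within `[0.10, 0.425] U [0.575,
#' 0.90] L` so the sweep still lies inside the fragment); neutral cases have
#' none.
#' @keywords internal
draw_selected_pos <- function(label, L) {
  switch(label,
    hard = , soft = stats::runif(1, 0.475, 0.525) * L,
    linked_hard = , linked_soft = {
      u <- stats::runif(1, 0, 0.65)
      (if (u < 0.325) 0.10 + u else 0.575 + (u - 0.325)) * L
    },
    neutral = NA_real_)
}

#' Parametric fixture generator for labeled sweep cases
#'
#' A coalescent-free stand-in for a sweep simulator, used for self-contained
#' training and testing. Neutral background: segregating sites are placed
#' uniformly with derived-allele counts drawn from the neutral frequency
#' spectrum (`p(c) ~ 1/c`) and carriers assigned exchangeably. Sweep classes
#' copy a swept subset of haplotypes (final beneficial-allele frequency
#' drawn on `[0.7, 0.98]`) from one (hard) or 2-3 (soft) founder haplotypes
#' over a contiguous segment around the selected site; the per-side segment
#' extents are exponential with mean equal to the classical hard-sweep
#' footprint width `s / (2 r ln(4 Ne s))`, standing in for the nearest
#' recombination breakpoints, so the marginal collapse probability at
#' distance `d` is `exp(-d / scale)`. The selection
#' coefficient is drawn log-uniformly from `s_range` when set. The selected
#' site itself is inserted with the swept subset as carriers.
#' Linked classes apply the same construction with the selected site outside
#' the central segment.
#'
#' @param params a [scenario_params()].
#' @param label one of [sweep_classes()].
#' @param seed integer seed (reproducible: same seed, same case).
#' @return a `labeled_case` list: `haplotypes` ([hap_window()]), `label`,
#'   `params`, `selected_pos`.
#' @export
fixture_sweep_generator <- function(params, label, seed) {
  label <- match.arg(label, sweep_classes())
  set.seed(as.integer(seed %% .Machine$integer.max))
  n <- params$n_hap
  theta <- 4 * params$Ne * params$mu * params$L
  a_n <- sum(1 / seq_len(n - 1))
  S <- max(4L, stats::rpois(1, theta * a_n))
  pos <- sort(stats::runif(S)) * params$L
  cnt <- sample(seq_len(n - 1), S, replace = TRUE,
                prob = 1 / seq_len(n - 1))
  mat <- matrix(0L, n, S)
  for (j in seq_len(S)) mat[sample.int(n, cnt[j]), j] <- 1L
  sel <- draw_selected_pos(label, params$L)

  if (label != "neutral") {
    n_founders <- if (label %in% c("hard", "linked_hard")) 1L else sample(2:3, 1)
    beta <- stats::runif(1, 0.7, 0.98)       # final beneficial-allele frequency
    s_case <- if (!is.null(params$s_range))
      exp(stats::runif(1, log(params$s_range[1]), log(params$s_range[2])))
    else params$s
    swept <- sample.int(n, max(n_founders + 1L, round(beta * n)))
    founder_of <- sort(rep_len(seq_len(n_founders), length(swept)))
    founders <- mat[sample.int(n, n_founders), , drop = FALSE]
    scale <- s_case / (2 * params$r * log(4 * params$Ne * s_case))
    # each swept haplotype copies its founder over a contiguous segment
    # around the selected site; exponential extents on both sides emulate
    # the nearest recombination breakpoints, so the collapse probability at
    # distance d decays as exp(-d / scale)
    eL <- stats::rexp(length(swept), rate = 1 / scale)
    eR <- stats::rexp(length(swept), rate = 1 / scale)
    posm <- matrix(pos, length(swept), S, byrow = TRUE)
    collapse <- posm >= (sel - eL) & posm <= (sel + eR)
    target <- founders[founder_of, , drop = FALSE]
    sub <- mat[swept, , drop = FALSE]
    sub[collapse] <- target[collapse]
    mat[swept, ] <- sub
    params$s_drawn <- s_case
    # insert the selected site: derived allele carried by the swept subset
    ins <- findInterval(sel, pos)
    selcol <- integer(n); selcol[swept] <- 1L
    mat <- cbind(mat[, seq_len(ins), drop = FALSE], selcol,
                 if (ins < S) mat[, (ins + 1L):S, drop = FALSE])
    pos <- c(pos[seq_len(ins)], sel, if (ins < S) pos[(ins + 1L):S])
  }
  pos <- pos + cumsum(c(0, diff(pos) == 0)) * 1e-9   # enforce strict increase
  win <- hap_window(mat, pos, span = c(0, params$L))
  structure(list(haplotypes = win, label = label, params = params,
                 selected_pos = sel), class = "labeled_case")
}

#' Build a discoal-style simulator command line
#'
#' For users with an external coalescent sweep simulator on PATH. Not used
#' by the built-in fixture backend.
#'
#' @param params a [scenario_params()].
#' @param label one of [sweep_classes()].
#' @param n_reps replicates.
#' @param seed integer seed.
#' @return character vector of command arguments.
#' @export
discoal_command <- function(params, label, n_reps = 1L, seed = 1L) {
  nsites <- as.integer(params$L)
  theta <- 4 * params$Ne * params$mu * params$L
  rho <- 4 * params$Ne * params$r * params$L
  args <- c(params$n_hap, n_reps, nsites,
            "-t", format(theta), "-r", format(rho), "-d", seed, seed + 1L)
  if (label != "neutral") {
    alpha <- 2 * params$Ne * params$s
    x <- draw_selected_pos(label, 1)
    args <- c(args, "-a", format(alpha), "-x", format(x))
    if (label %in% c("soft", "linked_soft")) {
      f0 <- if (params$initial_freq > 0) params$initial_freq else stats::runif(1, 0.01, 0.2)
      args <- c(args, "-f", format(f0))
    }
  }
  as.character(args)
}

#' Simulate one labeled case through a pluggable backend
#'
#' @param params a [scenario_params()].
#' @param label one of [sweep_classes()].
#' @param seed integer seed.
#' @param backend `"fixture"` (built-in parametric generator), or the path
#'   to an external discoal-compatible simulator binary whose ms-format
#'   output is parsed with [read_ms_format()].
#' @return a `labeled_case`.
#' @export
simulate_case <- function(params, label, seed, backend = "fixture") {
  if (identical(backend, "fixture"))
    return(fixture_sweep_generator(params, label, seed))
  cmd <- discoal_command(params, label, 1L, seed)
  out <- tryCatch(system2(backend, cmd, stdout = TRUE),
                  error = function(e) stop("simulator backend failed: ",
                                           backend, " ", paste(cmd, collapse = " ")))
  cases <- read_ms_format(out, L = params$L)
  structure(list(haplotypes = cases[[1]], label = label, params = params,
                 selected_pos = draw_selected_pos(label, params$L)),
            class = "labeled_case")
}

#' 4 x 4 grid of mismatched target-domain scenarios
#'
#' The Cartesian product of recombination rates and selection coefficients,
#' spanning the published corner values (high r = 3.75e-8, low r = 3.125e-9,
#' high s = 0.2, low s = 0.0075, plus r = 2.75e-8).
#'
#' @param base a [scenario_params()] for the source domain (not mutated).
#' @param r_values 4 recombination rates.
#' @param s_values 4 selection coefficients.
#' @return list of 16 `scenario_params`, named `r<i>_s<j>`.
#' @export
mismatch_grid <- function(base,
                          r_values = c(3.125e-9, 1.25e-8, 2.75e-8, 3.75e-8),
                          s_values = c(0.0075, 0.025, 0.075, 0.2)) {
  stopifnot(length(r_values) == 4, length(s_values) == 4)
  out <- list()
  for (i in seq_along(r_values)) for (j in seq_along(s_values)) {
    p <- base
    p$r <- r_values[i]; p$s <- s_values[j]
    p$s_range <- NULL                        # mismatch scenarios fix s
    out[[sprintf("r%d_s%d", i, j)]] <- p
  }
  out
}

#' Generate a labeled case collection
#'
#' @param params a [scenario_params()].
#' @param per_class cases per class.
#' @param seed master seed; case i of class c uses `seed + hash(c, i)`.
#' @param classes class labels to generate (default all five).
#' @param backend simulation backend (see [simulate_case()]).
#' @return list of `labeled_case`.
#' @export
generate_cases <- function(params, per_class, seed,
                           classes = sweep_classes(), backend = "fixture") {
  out <- vector("list", per_class * length(classes))
  idx <- 0L
  for (ci in seq_along(classes)) for (i in seq_len(per_class)) {
    idx <- idx + 1L
    out[[idx]] <- simulate_case(params, classes[ci],
                                seed = (seed * 131L + ci * 7919L + i) %% 2147483629L,
                                backend = backend)
  }
  out
}

#' Stratified train/validation/test splits
#'
#' @param cases list of `labeled_case`.
#' @param per_class named or unnamed counts `c(train, validation, test)` per
#'   class (defaults 2400/300/300).
#' @param seed shuffle seed.
#' @return list `train`, `validation`, `test` of disjoint case lists.
#' @export
make_splits <- function(cases, per_class = c(train = 2400, validation = 300, test = 300),
                        seed = 1L) {
  set.seed(as.integer(seed))
  labels <- vapply(cases, `[[`, character(1), "label")
  need <- sum(per_class)
  splits <- list(train = list(), validation = list(), test = list())
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < need)
      stop(sprintf("class '%s' has %d cases; %d required", cl, length(idx), need))
    idx <- sample(idx)
    splits$train <- c(splits$train, cases[idx[seq_len(per_class[1])]])
    splits$validation <- c(splits$validation,
                           cases[idx[per_class[1] + seq_len(per_class[2])]])
    splits$test <- c(splits$test,
                     cases[idx[per_class[1] + per_class[2] + seq_len(per_class[3])]])
  }
  splits
}

#' Robustness stress transforms
#'
#' Applies one of the robustness scenarios to a case collection:
#' \describe{
#'   \item{missing_regions}{drops all SNPs inside contiguous masked regions
#'     covering `fraction` (default 0.20) of each fragment's length.}
#'   \item{recomb_hetero}{for `fraction` (default 0.5) of the cases, rescales
#'     the bp coordinate axis by a 5-segment piecewise-constant
#'     recombination-rate multiplier map (log-normal multipliers), emulating
#'     rate heterogeneity along the fragment; the map is recorded in
#'     `params$rate_map`.}
#'   \item{low_recomb_factor}{divides `params$r` by `factor` (one of
#'     5/10/50/100 in the published scenarios) and regenerates each case
#'     under its original seed-independent construction when `regenerate`.}
#'   \item{imbalance}{resamples cases to the class proportions in `weights`.}
#' }
#'
#' @param cases list of `labeled_case`.
#' @param kind one of `missing_regions`, `recomb_hetero`,
#'   `low_recomb_factor`, `imbalance`.
#' @param fraction masked-bp or heterogeneous-case fraction.
#' @param factor recombination reduction factor.
#' @param weights named per-class sampling proportions.
#' @param regenerate regenerate cases after a parameter change.
#' @param seed transform seed.
#' @return transformed list of `labeled_case` (provenance in `params`).
#' @export
robustness_transform <- function(cases, kind = c("missing_regions", "recomb_hetero",
                                                 "low_recomb_factor", "imbalance"),
                                 fraction = 0.20, factor = 10, weights = NULL,
                                 regenerate = TRUE, seed = 1L) {
  kind <- match.arg(kind)
  set.seed(as.integer(seed))
  if (kind == "missing_regions") {
    if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
    if (fraction == 0) return(cases)
    return(lapply(cases, function(cs) {
      L <- cs$params$L
      a <- stats::runif(1, 0, 1 - fraction) * L
      keep <- cs$haplotypes$positions < a | cs$haplotypes$positions >= a + fraction * L
      cs$haplotypes <- hap_window(cs$haplotypes$matrix[, keep, drop = FALSE],
                                  cs$haplotypes$positions[keep], span = c(0, L))
      cs$params$masked <- c(a, a + fraction * L)
      cs
    }))
  }
  if (kind == "recomb_hetero") {
    if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
    hetero <- stats::runif(length(cases)) < fraction
    return(mapply(function(cs, h) {
      if (!h) return(cs)
      L <- cs$params$L
      mult <- exp(stats::rnorm(5, 0, 0.7))
      edges <- seq(0, L, length.out = 6)
      # warp bp axis by the cumulative (normalized) rate map
      cum <- c(0, cumsum(mult * diff(edges)))
      cum <- cum / cum[6] * L
      seg <- findInterval(cs$haplotypes$positions, edges, rightmost.closed = TRUE)
      newpos <- cum[seg] + (cs$haplotypes$positions - edges[seg]) /
        diff(edges)[seg] * (cum[seg + 1] - cum[seg])
      cs$haplotypes <- hap_window(cs$haplotypes$matrix, newpos, span = c(0, L))
      cs$params$rate_map <- list(edges = edges, mult = mult)
      cs
    }, cases, hetero, SIMPLIFY = FALSE))
  }
  if (kind == "low_recomb_factor") {
    return(lapply(seq_along(cases), function(i) {
      cs <- cases[[i]]
      cs$params$r <- cs$params$r / factor
      if (regenerate)
        cs <- simulate_case(cs$params, cs$label, seed = seed * 977L + i)
      cs$params$low_recomb_factor <- factor
      cs
    }))
  }
  # imbalance
  labels <- vapply(cases, `[[`, character(1), "label")
  if (is.null(weights)) stop("imbalance requires named class weights")
  n_total <- length(cases)
  out <- list()
  for (cl in names(weights)) {
    idx <- which(labels == cl)
    take <- sample(idx, round(weights[[cl]] * n_total), replace = TRUE)
    out <- c(out, cases[take])
  }
  out
}

#' Featurize labeled cases into a standardized dataset
#'
#' @param cases list of `labeled_case`.
#' @param spec a [fragment_spec()].
#' @param registry statistic registry.
#' @param scale optional stored min-max scale (apply mode).
#' @return list `x` (nstat x m x N standardized array), `y` (factor of
#'   labels for kept cases, or NULL when unlabeled), `scale`, `names`,
#'   `kept`.
#' @export
featurize_cases <- function(cases, spec, registry = sweep_stat_registry(),
                            scale = NULL) {
  frags <- lapply(cases, `[[`, "haplotypes")
  fe <- featurize_fragments(frags, spec, registry)
  std <- minmax_standardize(fe$x, scale)
  labels <- vapply(cases, function(cs) {
    if (is.null(cs$label)) NA_character_ else cs$label
  }, character(1))[fe$kept]
  y <- if (all(is.na(labels))) NULL else factor(labels, levels = sweep_classes())
  list(x = std$x, y = y, scale = std$scale, names = fe$names, kept = fe$kept)
}
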