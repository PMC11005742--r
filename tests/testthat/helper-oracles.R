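# Brute-force oracles, independent of the package implementations, plus
# small fixture builders shared across test files.

rand_hap_window <- function(n_hap = 8, S = 12, seed = 1, L = 1e4) {
  set.seed(seed)
  repeat {
    mat <- matrix(rbinom(n_hap * S, 1, runif(1, 0.2, 0.6)), n_hap, S)
    cs <- colSums(mat)
    if (any(cs > 0 & cs < n_hap)) break
  }
  hap_window(mat, sort(runif(S, 0, L)) + seq_len(S) * 1e-6, span = c(0, L))
}

# mean pairwise Hamming distance over all haplotype pairs
pi_oracle <- function(win) {
  mat <- win$matrix
  n <- nrow(mat)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(mat[i, ] != mat[j, ])
  tot / choose(n, 2)
}

theta_w_oracle <- function(win) {
  ncol(win$matrix) / sum(1 / seq_len(nrow(win$matrix) - 1))
}

theta_h_oracle <- function(win) {
  n <- nrow(win$matrix)
  xi <- tabulate(colSums(win$matrix), n - 1)
  sum(2 * xi * seq_len(n - 1)^2) / (n * (n - 1))
}

garud_oracle <- function(win) {
  key <- apply(win$matrix, 1, paste, collapse = "")
  p <- sort(as.vector(table(key)) / nrow(win$matrix), decreasing = TRUE)
  h1 <- sum(p^2)
  h12 <- (sum(p[1:min(2, length(p))]))^2 + sum(p[-seq_len(min(2, length(p)))]^2)
  h123 <- (sum(p[1:min(3, length(p))]))^2 + sum(p[-seq_len(min(3, length(p)))]^2)
  list(h1 = h1, h12 = h12, h123 = h123, h2_h1 = (h1 - p[1]^2) / h1, het = 1 - h1)
}

haf_oracle <- function(win) {
  mat <- win$matrix
  cs <- colSums(mat)
  out <- numeric(nrow(mat))
  for (i in seq_len(nrow(mat))) for (j in seq_len(ncol(mat)))
    if (mat[i, j] == 1) out[i] <- out[i] + cs[j]
  out
}

phi_kappa_oracle <- function(win) {
  mat <- win$matrix
  haf <- haf_oracle(win)
  key <- apply(mat, 1, paste, collapse = "")
  G <- length(unique(key))
  phi <- kappa <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    carriers <- which(mat[, j] == 1)
    phi[j] <- sum(haf[carriers]) / sum(haf)
    kappa[j] <- length(unique(key[carriers])) / G
  }
  list(phi = phi, kappa = kappa)
}

# EHH from explicit pairwise sharing; trapezoid integration with the same
# 0.05 decay cutoff and window-edge truncation convention
ehh_integral_oracle <- function(win, core, carriers, scale = "bp", cutoff = 0.05) {
  mat <- win$matrix
  one_side <- function(idx) {
    if (!length(idx)) return(0)
    pairs <- utils::combn(carriers, 2)
    eh <- numeric(length(idx))
    for (j in seq_along(idx)) {
      cols <- idx[seq_len(j)]
      same <- apply(pairs, 2, function(pr)
        all(mat[pr[1], cols] == mat[pr[2], cols]))
      eh[j] <- mean(same)
      if (eh[j] < cutoff) { eh <- eh[seq_len(j)]; idx <- idx[seq_len(j)]; break }
    }
    xs <- if (scale == "bp") abs(win$positions[idx] - win$positions[core])
          else seq_along(idx)
    x <- c(0, xs); y <- c(1, eh)
    sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  }
  S <- ncol(mat)
  one_side(rev(seq_len(core - 1))) +
    one_side(if (core < S) (core + 1):S else integer(0))
}

ks_d_oracle <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(ecdf(a)(pts) - ecdf(b)(pts)))
}

# toy feature arrays with class signal planted on one statistic row
make_planted_features <- function(n_per_class, nstat = 10, m = 16, row = 7,
                                  seed = 1, shift = 0) {
  set.seed(seed)
  N <- n_per_class * 5
  x <- array(runif(nstat * m * N, 0, 0.3), c(nstat, m, N)) + shift
  y <- rep(1:5, each = n_per_class)
  centers <- round(seq(2, m - 2, length.out = 5))
  for (i in seq_len(N)) {
    j <- centers[y[i]]
    x[row, (j - 1):(j + 1), i] <- x[row, (j - 1):(j + 1), i] + 0.6
  }
  list(x = pmin(x, 1), y = y)
}

# shift every parameter away from 0 so that no pre-activation sits exactly
# on the ReLU kink (zero-initialized biases + dead upstream units otherwise
# make finite differences one-sided there)
jitter_params <- function(model, sd = 0.05, seed = 99) {
  set.seed(seed)
  for (net in c("extractor", "classifier", "discriminator")) {
    for (i in seq_along(model[[net]]$layers)) {
      ps <- model[[net]]$layers[[i]]$params
      if (!length(ps)) next
      for (nm in names(ps))
        model[[net]]$layers[[i]]$params[[nm]] <-
          ps[[nm]] + rnorm(length(ps[[nm]]), 0, sd)
    }
  }
  model
}

abind_cases <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1:3], d[4] + dim(b)[4]))
  out[, , , seq_len(d[4])] <- a
  out[, , , d[4] + seq_len(dim(b)[4])] <- b
  out
}

tiny_dann_config <- function(...) {
  dann_config(conv_channels = c(4L, 8L), fc_classifier = c(32L, 16L, 8L),
              fc_discriminator = c(16L, 8L), dropout = 0, batch_size = 32L, ...)
}
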