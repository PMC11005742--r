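test_that("diversity estimators match closed forms on known windows", {
  # n=4, one site at derived count 2: enumerating the 6 pairs gives 2/3
  w1 <- hap_window(matrix(c(1, 1, 0, 0), 4, 1), 10)
  expect_equal(nucleotide_diversity(w1), 2 * 2 * 2 / (4 * 3))
  # additivity over sites
  w2 <- hap_window(cbind(c(1, 1, 0, 0), c(1, 1, 0, 0)), c(10, 20))
  expect_equal(nucleotide_diversity(w2), 2 * nucleotide_diversity(w1))
  # Watterson: S = 3, n = 4 -> 3 / (1 + 1/2 + 1/3)
  w3 <- hap_window(cbind(c(1, 0, 0, 0), c(0, 1, 1, 0), c(1, 1, 1, 0)), 1:3)
  expect_equal(watterson_theta(w3), 3 / (1 + 1 / 2 + 1 / 3))
  # n = 2: a_1 = 1 so theta_W = S
  w4 <- hap_window(cbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1), c(1, 0)), 1:5)
  expect_equal(watterson_theta(w4), 5)
  # theta_H: one site at derived count 3, n = 4 -> 2 * 1 * 9 / 12
  w5 <- hap_window(matrix(c(1, 1, 1, 0), 4, 1), 5)
  expect_equal(fay_wu_h(w5)$theta_h, 1.5)
  # all-singleton window: theta_H = 2S/(n(n-1)), H = pi - theta_H
  w6 <- hap_window(diag(4), 1:4)
  expect_equal(fay_wu_h(w6)$theta_h, 2 * 4 / 12)
  expect_equal(fay_wu_h(w6)$h, nucleotide_diversity(w6) - 2 * 4 / 12)
})

test_that("degenerate monomorphic windows give zero statistics", {
  w <- hap_window(matrix(0L, 4, 3), 1:3)   # columns dropped at parse time
  expect_equal(ncol(w$matrix), 0)
  expect_equal(nucleotide_diversity(w), 0)
  expect_equal(watterson_theta(w), 0)
  expect_equal(fay_wu_h(w), list(theta_h = 0, h = 0))
  expect_warning(v <- compute_stat_vector(w), "degenerate")
  expect_equal(unname(v), numeric(40))
})

test_that("SFS moments and entropy match the weighted-mean oracle", {
  # two sites at freq 1/4 and two at 2/4: first moment 0.375, entropy log 2
  w <- hap_window(cbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(1, 1, 0, 0), c(0, 1, 1, 0)), 1:4)
  mo <- sfs_moments(site_frequency_spectrum(w), 4)
  expect_equal(unname(mo["m1"]), 0.375)
  expect_equal(unname(mo["entropy"]), log(2))
  for (k in 1:5)
    expect_equal(unname(mo[k]), mean(c(0.25, 0.25, 0.5, 0.5)^k))
  # all sites at one frequency class: entropy 0
  w1 <- hap_window(cbind(c(1, 1, 0, 0), c(0, 1, 1, 0)), 1:2)
  expect_equal(unname(sfs_moments(site_frequency_spectrum(w1), 4)["entropy"]), 0)
  expect_equal(sfs_moments(integer(3), 4), c(m1 = 0, m2 = 0, m3 = 0, m4 = 0,
                                             m5 = 0, entropy = 0))
})

test_that("haplotype spectrum counts distinct rows, sorted descending", {
  w <- hap_window(rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)), 1:2)
  expect_equal(hap_spectrum(w), c(0.5, 0.5))
  w2 <- hap_window(rbind(c(1, 0), c(1, 0), c(0, 1), c(1, 1)), 1:2)
  expect_equal(hap_spectrum(w2), c(0.5, 0.25, 0.25))
  w3 <- hap_window(rbind(c(1, 0), c(1, 0), c(1, 0), c(0, 1)), 1:2)
  expect_equal(hap_spectrum(w3)[1], 0.75)
})

test_that("Garud H statistics match direct enumeration", {
  expect_equal(garud_h_stats(c(1)), list(h1 = 1, h12 = 1, h123 = 1, h2_h1 = 0, het = 0))
  g <- garud_h_stats(c(0.5, 0.25, 0.25))
  expect_equal(g$h1, 0.375)
  expect_equal(g$h12, 0.625)
  expect_equal(g$h123, 1.0)
  expect_equal(g$h2_h1, 1 / 3)
  expect_equal(g$het, 0.625)
  # k equifrequent haplotypes: H1 = 1/k, het = 1 - 1/k
  for (k in c(2, 5, 10)) {
    gk <- garud_h_stats(rep(1 / k, k))
    expect_equal(gk$h1, 1 / k)
    expect_equal(gk$het, 1 - 1 / k)
  }
})

test_that("HAF and SAFE scores match the counting oracles on hand cases", {
  w <- hap_window(rbind(c(1, 1), c(1, 0), c(0, 0)), 1:2, drop_monomorphic = FALSE)
  expect_equal(haf_scores(w), c(3, 2, 0))
  sf <- safe_family(w)
  expect_equal(sf$phi[2], 3 / 5)     # site 2 carried by row 1 only
  expect_equal(sf$phi[1], 1)         # site 1 carried by every HAF-bearing row
  expect_equal(sf$kappa[2], 1 / 3)   # 1 of 3 distinct haplotypes
  # variant carried by every haplotype: phi = kappa = 1
  wf <- hap_window(rbind(c(1, 1), c(1, 0), c(1, 0)), 1:2, drop_monomorphic = FALSE)
  sff <- safe_family(wf)
  expect_equal(sff$phi[1], 1)
  expect_equal(sff$kappa[1], 1)
})

test_that("every statistic equals its brute-force oracle on random windows", {
  for (rep in 1:100) {
    w <- rand_hap_window(n_hap = sample(4:10, 1), S = sample(5:15, 1), seed = rep)
    expect_equal(nucleotide_diversity(w), pi_oracle(w), tolerance = 1e-10)
    expect_equal(watterson_theta(w), theta_w_oracle(w), tolerance = 1e-10)
    expect_equal(fay_wu_h(w)$theta_h, theta_h_oracle(w), tolerance = 1e-10)
    g <- garud_h_stats(hap_spectrum(w)); go <- garud_oracle(w)
    expect_equal(g, go, tolerance = 1e-10)
    expect_equal(haf_scores(w), haf_oracle(w), tolerance = 1e-10)
    pk <- safe_family(w); pko <- phi_kappa_oracle(w)
    expect_equal(pk$phi, pko$phi, tolerance = 1e-10)
    expect_equal(pk$kappa, pko$kappa, tolerance = 1e-10)
  }
})

test_that("EHH integrals match the explicit pairwise-sharing trapezoid oracle", {
  for (rep in 1:40) {
    w <- rand_hap_window(n_hap = sample(6:10, 1), S = sample(7:12, 1), seed = 1000 + rep)
    counts <- colSums(w$matrix)
    core <- which(counts >= 2 & counts <= w$n_hap - 2)[1]
    if (is.na(core)) next
    for (allele in 0:1) {
      carriers <- which(w$matrix[, core] == allele)
      for (sc in c("bp", "snp")) {
        expect_equal(ehh_integral(w, core, carriers, sc),
                     ehh_integral_oracle(w, core, carriers, sc),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("iHS is antisymmetric under derived/ancestral relabeling", {
  for (rep in 1:20) {
    w <- rand_hap_window(n_hap = 8, S = 11, seed = 2000 + rep)
    counts <- colSums(w$matrix)
    core <- pmatch(TRUE, counts >= 2 & counts <= 6)
    if (is.na(core)) next
    e1 <- ehh_family(w, core)
    wf <- hap_window(1L - w$matrix, w$positions, span = w$span,
                     drop_monomorphic = FALSE)
    e2 <- ehh_family(wf, core)
    expect_equal(e1$ihs, -e2$ihs, tolerance = 1e-10)
    expect_equal(e1$delta_ihh, -e2$delta_ihh, tolerance = 1e-10)
  }
  # symmetric sharing structure: iHS = 0, delta-iHH = 0
  mat <- rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1), c(0, 0, 1))
  w <- hap_window(mat, c(10, 20, 30), drop_monomorphic = FALSE)
  e <- ehh_family(w, 2)
  expect_equal(e$ihs, 0)
  expect_equal(e$delta_ihh, 0)
})

test_that("statistic vector respects registry order and per-stat equality", {
  reg <- sweep_stat_registry()
  expect_length(reg, 40)
  w <- rand_hap_window(n_hap = 10, S = 20, seed = 7)
  v <- compute_stat_vector(w, ctx = list(baseline = 0.3))
  expect_equal(names(v), names(reg))
  expect_equal(unname(v["pi"]), nucleotide_diversity(w))
  expect_equal(unname(v["theta_w"]), watterson_theta(w))
  expect_equal(unname(v["h12"]), garud_h_stats(hap_spectrum(w))$h12)
  expect_equal(unname(v["haf_mean"]), mean(haf_scores(w)))
  expect_equal(unname(v["delta_af"]), delta_af(w, 0.3))
  # invariance to haplotype row permutation
  set.seed(1)
  wp <- hap_window(w$matrix[sample(w$n_hap), ], w$positions, span = w$span,
                   drop_monomorphic = FALSE)
  expect_equal(compute_stat_vector(wp, ctx = list(baseline = 0.3)), v)
})

test_that("H-statistic and moment invariants hold on random windows", {
  for (rep in 1:50) {
    w <- rand_hap_window(n_hap = sample(4:12, 1), S = sample(4:20, 1),
                         seed = 3000 + rep)
    g <- garud_h_stats(hap_spectrum(w))
    expect_true(g$h123 >= g$h12 - 1e-12 && g$h12 >= g$h1 - 1e-12)
    expect_true(g$h1 > 0 && g$h1 <= 1)
    expect_equal(g$h1 + g$het, 1)
    fw <- fay_wu_h(w)
    expect_equal(fw$h, nucleotide_diversity(w) - fw$theta_h)
    expect_true(nucleotide_diversity(w) >= 0 && fw$theta_h >= 0)
    pk <- safe_family(w)
    expect_true(all(pk$phi > 0 & pk$phi <= 1))
    expect_true(all(pk$kappa > 0 & pk$kappa <= 1))
  }
})

test_that("iHS standardization centers each frequency bin", {
  set.seed(5)
  vals <- rnorm(500, 1, 2)
  freqs <- runif(500, 0.05, 0.95)
  z <- ihs_standardize(vals, freqs, bins = 10)
  b <- pmin(pmax(ceiling(freqs * 10), 1), 10)
  for (bb in unique(b)) {
    expect_equal(mean(z[b == bb]), 0, tolerance = 1e-10)
    expect_equal(sd(z[b == bb]), 1, tolerance = 1e-10)
  }
})

test_that("sweep footprint follows the stated formula and monotonicities", {
  expect_equal(sweep_footprint(0.2, 1e4, 3.75e-8),
               0.2 / (4 * 1e4 * 3.75e-8 * log(2000)))
  expect_equal(sweep_footprint(0.2, 1e4, 3.75e-8), 17.54, tolerance = 1e-3)
  # doubling r halves the footprint
  expect_equal(sweep_footprint(0.1, 1e4, 2e-8),
               sweep_footprint(0.1, 1e4, 1e-8) / 2)
  # increasing in s for Ne*s > e
  ss <- seq(0.001, 0.2, length.out = 50)
  ss <- ss[1e4 * ss > exp(1)]
  fp <- vapply(ss, sweep_footprint, numeric(1), Ne = 1e4, r = 1e-8)
  expect_true(all(diff(fp) > 0))
  expect_error(sweep_footprint(1e-5, 1e4, 1e-8), "Ne \\* s")
})
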