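test_that("pattern distribution counts and normalises correctly", {
  d <- op_distribution(c(1L, 1L, 2L, 2L), D = 2)
  expect_equal(d$p, c(0.5, 0.5))
  expect_equal(d$counts, c(2L, 2L))
  expect_equal(d$m, 4L)

  dp <- op_distribution(rep(3L, 10), D = 3)
  expect_equal(dp$p[3], 1)
  expect_equal(sum(dp$p), 1, tolerance = 1e-12)

  expect_error(op_distribution(integer(0), D = 2), "empty")
  expect_error(op_distribution(c(1L, 7L), D = 2), "1\\.\\.2")
  expect_error(op_distribution(c(1L, 2L)), "`D` is required")
})

test_that("iid signals give equiprobable patterns", {
  set.seed(1)
  x <- runif(1e6)
  d <- op_distribution(op_encode(x, D = 3))
  se <- sqrt((1 / 6) * (5 / 6) / d$m)
  expect_true(all(abs(d$p - 1 / 6) < 3 * se))
})

test_that("permutation entropy evaluates the Shannon formula in bits", {
  expect_equal(permutation_entropy(rep(1 / 6, 6)), log2(6))
  expect_equal(permutation_entropy(c(1, 0, 0, 0, 0, 0)), 0)
  expect_equal(permutation_entropy(c(0.5, 0.25, 0.25, 0, 0, 0)), 1.5)
})

test_that("Renyi entropies behave across orders", {
  p <- c(0.5, 0.25, 0.25, 0, 0, 0)
  expect_equal(min_entropy(p), 1)
  expect_equal(renyi_entropy(c(0.5, 0.5), q = 2), 1)
  # uniform distribution: all orders coincide
  u <- rep(1 / 24, 24)
  expect_equal(min_entropy(u), log2(24))
  expect_equal(renyi_entropy(u, q = 2), log2(24))
  expect_equal(renyi_entropy(u, q = Inf), min_entropy(u))
  # q -> 1 approaches the Shannon value; large q approaches the min-entropy
  expect_equal(renyi_entropy(p, q = 1 + 1e-9), permutation_entropy(p),
               tolerance = 1e-6)
  expect_equal(renyi_entropy(p, q = 200), min_entropy(p), tolerance = 0.01)

  expect_error(renyi_entropy(p, q = 1), "Shannon")
  expect_error(renyi_entropy(p, q = 0), "positive")
  expect_error(renyi_entropy(p, q = -2), "positive")
  expect_error(permutation_entropy(c(0.5, 0.4)), "sum to 1")
})

test_that("entropy sandwich holds on random distributions", {
  set.seed(2)
  for (rep in 1:1000) {
    k <- sample(c(2, 6, 24), 1)
    w <- rexp(k)
    p <- w / sum(w)
    H <- permutation_entropy(p)
    Hinf <- min_entropy(p)
    Hmax <- log2(k)
    expect_lte(Hinf, H + 1e-12)
    expect_lte(H, Hmax + 1e-12)
    q <- runif(1, 1.1, 30)
    Hq <- renyi_entropy(p, q)
    expect_lte(Hinf, Hq + 1e-12)
    expect_lte(Hq, H + 1e-12)
  }
})

test_that("variability of translated windows equals the translation spread", {
  # strictly increasing signal with unit steps: every window has pattern 1
  # and the j-th components across windows are translates spaced by the
  # stride, so sigma_j(1) is the same for every j and avg = log2 of it
  D <- 3
  x <- as.numeric(1:41)
  enc <- op_encode(x, D)
  v <- magnitude_variability(enc)
  spread <- sd(seq(0, by = D - 1, length.out = enc$m))
  expect_equal(unname(v$mean_log_sigma), rep(log2(spread), D))
  expect_equal(v$avg, log2(spread))
  expect_equal(unname(v$dispersion), rep(0, D))
  expect_equal(v$excluded_mass, 0)
})

test_that("variability panel matches the brute-force grouping oracle", {
  set.seed(3)
  # D = 4 only at tau = 1: T = 50 gives too few windows per pattern at
  # larger strides for any dispersion to be defined
  cases <- expand.grid(D = 2:4, tau = 1:2, estimator = c("sd", "iqr"),
                       stringsAsFactors = FALSE)
  cases <- cases[!(cases$D == 4 & cases$tau == 2), ]
  for (i in seq_len(nrow(cases))) {
    D <- cases$D[i]; tau <- cases$tau[i]; est <- cases$estimator[i]
    x <- rnorm(50)
    enc <- suppressMessages(op_encode(x, D, tau))
    got <- magnitude_variability(enc, est)
    want <- brute_variability(x, D, tau, est)
    expect_equal(got$sigma, want$sigma, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(unname(got$mean_log_sigma), want$mean_log_sigma,
                 tolerance = 1e-12)
    expect_equal(got$avg, want$avg, tolerance = 1e-12)
    expect_equal(got$excluded_mass, want$excluded_mass, tolerance = 1e-12)
  }
})

test_that("doubling magnitudes shifts avg by +1 and leaves entropies fixed", {
  set.seed(4)
  x <- rnorm(400)
  s1 <- op_summary(x, D = 3)
  s2 <- op_summary(2 * x, D = 3)
  expect_equal(s2$variability$avg, s1$variability$avg + 1, tolerance = 1e-12)
  expect_identical(s2$H, s1$H)
  expect_identical(s2$H_inf, s1$H_inf)
})

test_that("entropies and avg are invariant under symbol relabelling", {
  set.seed(5)
  x <- rnorm(300)
  enc <- op_encode(x, D = 3)
  perm <- sample(6)
  enc2 <- enc
  enc2$symbols <- perm[enc$symbols]
  d1 <- op_distribution(enc); d2 <- op_distribution(enc2)
  expect_equal(permutation_entropy(d1), permutation_entropy(d2))
  expect_equal(min_entropy(d1), min_entropy(d2))
  expect_equal(magnitude_variability(enc)$avg,
               magnitude_variability(enc2)$avg, tolerance = 1e-12)
})

test_that("degenerate inputs are refused with the documented errors", {
  # every pattern occurs once: dispersion undefined everywhere
  enc1 <- op_encode(c(1, 2, 3), D = 3)
  expect_error(magnitude_variability(enc1), "insufficient data")
  # constant signal: zero spread everywhere (log2 0 undefined)
  encc <- suppressWarnings(op_encode(rep(1, 21), D = 3))
  expect_error(magnitude_variability(encc), "insufficient data")
  expect_error(magnitude_variability(1:10), "op_encode")
})

test_that("patterns with undefined dispersion are excluded and reported", {
  # two ascending windows with spread plus a single descending stray:
  # the stray pattern occurs once, so its dispersion is undefined
  x <- c(1, 2, 3, 4, 5, 4, 0)
  enc <- op_encode(x, D = 3)
  v <- magnitude_variability(enc)
  expect_true(v$excluded_mass > 0)
  expect_false(all(v$included))
  w <- sum(op_distribution(enc)$p[v$included])
  expect_equal(v$excluded_mass, 1 - w, tolerance = 1e-12)
})

test_that("summary composes the pipeline deterministically with provenance", {
  set.seed(6)
  x <- cumsum(abs(rnorm(100)) + 0.1) # strictly increasing, varying steps
  s <- op_summary(x, D = 3)
  expect_equal(s$H, 0)
  expect_equal(s$H_inf, 0)
  expect_equal(s$H_max, log2(6))
  expect_equal(s$provenance$m, (100 - 1) %/% 2)
  expect_equal(s$provenance$tie_fraction, 0)

  y <- rnorm(500)
  expect_identical(op_summary(y, D = 4), op_summary(y, D = 4))
  sd_ <- op_summary(y, D = 4, dither = "auto", seed = 9)
  expect_equal(sd_$provenance$seed, 9)
  expect_equal(sd_$provenance$dither_amplitude, diff(range(y)) * 2^-16)
})

test_that("per-component variability is homogeneous in band-chaotic regimes", {
  # at r = 3.6, eps = 0.01 the per-component <log2 sigma_j> values are
  # nearly identical; documented tolerance: their range stays below a
  # quarter of the panel's mean dispersion (error-bar scale)
  x <- simulate_coupled_logistic(3.6, 0.01)$x
  v <- op_summary(x, D = 4)$variability
  expect_lt(diff(range(v$mean_log_sigma)), 0.25 * mean(v$dispersion))
})
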