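test_that("embedding produces quasi-non-overlapping windows", {
  # T = 5, D = 3, tau = 1: two windows sharing the third sample
  e <- op_embed(c(10, 20, 30, 40, 50), D = 3)
  expect_equal(e$m, 2L)
  expect_equal(e$start_indices, c(1L, 3L))
  expect_equal(e$vectors, rbind(c(10, 20, 30), c(30, 40, 50)))

  # T = D: exactly one window, the whole signal
  e1 <- op_embed(c(3, 1, 2), D = 3)
  expect_equal(e1$m, 1L)
  expect_equal(e1$vectors[1, ], c(3, 1, 2))

  # T = 10, D = 3, tau = 2: windows at t = 1 and 5; the one at t = 9 is
  # incomplete and dropped
  x <- 101:110
  expect_message(e2 <- op_embed(x, D = 3, tau = 2), "trailing")
  expect_equal(e2$m, 2L)
  expect_equal(e2$start_indices, c(1L, 5L))
  expect_equal(e2$vectors, rbind(x[c(1, 3, 5)], x[c(5, 7, 9)]))

  # window count formula and the one-shared-sample property at tau = 1
  set.seed(11)
  for (D in 2:5) {
    x <- rnorm(57)
    e <- suppressMessages(op_embed(x, D))
    expect_equal(e$m, (length(x) - 1L) %/% (D - 1L))
    if (e$m > 1L)
      for (i in seq_len(e$m - 1L))
        expect_identical(e$vectors[i, D], e$vectors[i + 1L, 1L])
  }
})

test_that("embedding rejects too-short signals with the required minimum", {
  expect_error(op_embed(c(1, 2), D = 3), "at least 3")
  expect_error(op_embed(1:4, D = 3, tau = 2), "at least 5")
  expect_error(op_embed(numeric(0), D = 2), "at least one sample")
  expect_error(op_embed(c(1, NA, 2), D = 2), "non-finite")
})

test_that("ordinal ranking follows the ascending-lexicographic convention", {
  # D = 2: ascending -> 1, descending -> 2
  expect_identical(ordinal_pattern(c(0.1, 0.5)), 1L)
  expect_identical(ordinal_pattern(c(0.5, 0.1)), 2L)

  # strictly increasing vectors map to 1 for any D; decreasing to D!
  for (D in 2:6) {
    expect_identical(ordinal_pattern(sort(rnorm(D))), 1L)
    expect_identical(ordinal_pattern(sort(rnorm(D), decreasing = TRUE)),
                     as.integer(factorial(D)))
  }

  # D = 3: the 6 orderings give 6 distinct labels covering 1..6
  labs <- apply(all_perms(3L), 1L, function(p) ordinal_pattern(as.numeric(p)))
  expect_setequal(labs, 1:6)

  expect_error(ordinal_pattern(c(1, NaN, 2)), "non-finite")
  expect_error(ordinal_pattern(3), "at least 2")
})

test_that("ranking is a bijection onto 1..D! for D up to 6", {
  for (D in 2:6) {
    perms <- all_perms(D)
    labs <- apply(perms, 1L, function(p) ordinal_pattern(as.numeric(p)))
    expect_identical(sort(labs), seq_len(factorial(D)))
  }
})

test_that("ranking agrees with the enumeration oracle on random vectors", {
  set.seed(21)
  for (rep in 1:50) {
    D <- sample(2:5, 1)
    v <- rnorm(D)
    expect_identical(ordinal_pattern(v), brute_label(v))
  }
})

test_that("encoding assigns equal symbols iff orderings agree", {
  enc <- op_encode(c(1, 3, 2, 5, 4), D = 3)
  # both windows are low-high-mid
  expect_equal(enc$m, 2L)
  expect_identical(enc$symbols[1], enc$symbols[2])

  # constant signal: the tie rule forces the ascending label 1 everywhere
  expect_warning(encc <- op_encode(rep(2.5, 9), D = 3), "tied")
  expect_true(all(encc$symbols == 1L))
  expect_equal(encc$tie_fraction, 1)

  # monotone decreasing: always the descending label D!
  for (D in 2:4) {
    encd <- op_encode(seq(50, 1), D = D)
    expect_true(all(encd$symbols == factorial(D)))
  }
})

test_that("symbols are invariant under strictly increasing transforms", {
  set.seed(31)
  x <- rnorm(200)
  for (D in c(3, 4)) {
    base <- op_encode(x, D)$symbols
    for (f in increasing_transforms)
      expect_identical(op_encode(f(x), D)$symbols, base)
  }
})

test_that("dithering breaks ties, is seeded, and vanishes at amplitude 0", {
  x <- round(sin(1:200), 1) # quantised: many exact ties
  expect_identical(dither_signal(x, amplitude = 0), x)

  d1 <- dither_signal(x, seed = 7)
  d2 <- dither_signal(x, seed = 7)
  expect_identical(d1, d2)
  expect_false(any(duplicated(d1)))
  # default amplitude is one 16-bit quantisation step of the signal range
  expect_lt(max(abs(d1 - x)), diff(range(x)) * 2^-16 * 6)

  u <- dither_signal(x, dist = "uniform", seed = 7)
  expect_false(any(duplicated(u)))
  expect_lte(max(abs(u - x)), diff(range(x)) * 2^-16)

  # encode(dither(s, 0)) == encode(s) exactly
  y <- rnorm(100)
  expect_identical(op_encode(dither_signal(y, amplitude = 0), 3)$symbols,
                   op_encode(y, 3)$symbols)
})

test_that("delay resampling keeps every tau-th sample", {
  expect_identical(resample_signal(1:10, 1), as.numeric(1:10))
  expect_identical(resample_signal(1:10, 3), c(1, 4, 7, 10))
  expect_identical(resample_signal(1:10, 4), c(1, 5, 9))
  # length formula n + 1 with n = floor((T - 1)/tau)
  set.seed(41)
  for (rep in 1:20) {
    T_ <- sample(2:60, 1); tau <- sample(1:7, 1)
    expect_length(resample_signal(rnorm(T_), tau), (T_ - 1) %/% tau + 1)
  }
})
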