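# Independent oracles used to cross-check the package implementation.
# These deliberately avoid the package's own code paths: patterns are
# labelled by table lookup over explicitly enumerated permutations, and the
# variability panel is computed by explicit grouping and term-by-term sums.

# all permutations of 1:n in lexicographic order (rows)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- NULL
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    out <- rbind(out, cbind(first, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# label = position of the ascending-sorting permutation (ties: earlier
# index smaller) in the lexicographic list
brute_label <- function(v) {
  D <- length(v)
  perms <- all_perms(D)
  srt <- order(v) # stable: ties broken by index
  which(apply(perms, 1L, function(p) all(p == srt)))
}

# explicit quasi-non-overlapping embedding
brute_embed <- function(x, D, tau = 1L) {
  stride <- (D - 1L) * tau
  starts <- c()
  s <- 1L
  while (s + (D - 1L) * tau <= length(x)) {
    starts <- c(starts, s)
    s <- s + stride
  }
  t(vapply(starts, function(s0) x[s0 + (0:(D - 1L)) * tau], numeric(D)))
}

# term-by-term evaluation of the variability panel
brute_variability <- function(x, D, tau = 1L, estimator = "sd") {
  V <- brute_embed(x, D, tau)
  labs <- apply(V, 1L, brute_label)
  m <- length(labs)
  nsym <- factorial(D)
  p <- tabulate(labs, nsym) / m
  est <- function(col) {
    if (estimator == "sd") sd(col)
    else diff(quantile(col, c(0.25, 0.75), names = FALSE))
  }
  sigma <- matrix(NA_real_, nsym, D)
  for (a in seq_len(nsym)) {
    rows <- which(labs == a)
    if (length(rows) >= 2L)
      for (j in seq_len(D)) sigma[a, j] <- est(V[rows, j])
  }
  included <- rep(FALSE, nsym)
  for (a in seq_len(nsym))
    included[a] <- !anyNA(sigma[a, ]) && all(sigma[a, ] > 0)
  if (!any(included)) stop("brute oracle: nothing included")
  w <- p[included] / sum(p[included])
  mls <- numeric(D)
  for (j in seq_len(D))
    mls[j] <- sum(w * log2(sigma[included, j]))
  list(sigma = sigma, mean_log_sigma = mls, avg = mean(mls),
       excluded_mass = 1 - sum(p[included]))
}

# isolated logistic-map MLE from the analytic derivative, in plain R
brute_logistic_mle <- function(r, x0 = 0.65, n = 2e5, transient = 1e3) {
  x <- x0
  s <- 0
  for (t in seq_len(transient + n)) {
    if (t > transient) s <- s + log(abs(r * (1 - 2 * x)))
    x <- r * x * (1 - x)
  }
  s / n
}

# a random strictly-increasing transform (for order-isomorphism checks)
increasing_transforms <- list(
  function(z) exp(z),
  function(z) 2 * z + 1,
  function(z) atan(z),
  function(z) z^3 + z
)
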