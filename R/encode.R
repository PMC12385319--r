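#' Embed a signal into quasi-non-overlapping vectors
#'
#' Splits a signal into windows of `D` samples spaced `tau` apart, with
#' window `i` starting at time index `(i - 1)(D - 1)tau + 1`. Consecutive
#' windows therefore share exactly one sample when `tau = 1` (window `i`
#' ends where window `i + 1` starts): the encoding uses every sample once
#' as an interior point while keeping consecutive ordinal patterns free of
#' the artificial correlations that denser overlap would create. Only
#' complete windows are produced, `m = floor((T - 1) / ((D - 1) tau))`;
#' a trailing partial window is dropped with a message.
#'
#' @param x numeric signal of length `T >= (D - 1) * tau + 1`.
#' @param D integer embedding dimension, `>= 2`.
#' @param tau integer spacing between the `D` samples of a window, `>= 1`.
#' @return an object of class `"op_embedding"`: a list with `vectors`
#'   (`m x D` matrix), `start_indices`, `D`, `tau`, `m`, and `n_dropped`
#'   (tail samples not covered by a complete window).
#' @examples
#' e <- op_embed(c(1, 3, 2, 5, 4), D = 3)
#' e$vectors # rows {1,3,2} and {2,5,4}, sharing the third sample
#' @export
op_embed <- function(x, D, tau = 1L) {
  x <- check_signal(x)
  D <- as.integer(D); tau <- as.integer(tau)
  if (is.na(D) || D < 2L) stop("`D` must be an integer >= 2")
  if (is.na(tau) || tau < 1L) stop("`tau` must be a positive integer")
  n <- length(x)
  need <- (D - 1L) * tau + 1L
  if (n < need)
    stop(sprintf(
      "signal too short: %d samples, but one window with D = %d, tau = %d needs at least %d",
      n, D, tau, need))
  stride <- (D - 1L) * tau
  m <- (n - 1L) %/% stride
  starts <- 1L + (seq_len(m) - 1L) * stride
  idx <- outer(starts, (0:(D - 1L)) * tau, `+`)
  vectors <- matrix(x[idx], nrow = m, ncol = D)
  n_dropped <- n - (starts[m] + (D - 1L) * tau)
  if (n_dropped > 0L)
    message(sprintf("op_embed: %d trailing sample(s) not covered by a complete window",
                    n_dropped))
  structure(list(vectors = vectors, start_indices = starts,
                 D = D, tau = tau, m = m, n_dropped = n_dropped),
            class = "op_embedding")
}

#' @export
print.op_embedding <- function(x, ...) {
  cat(sprintf("ordinal embedding: m = %d windows, D = %d, tau = %d (%d tail sample(s) dropped)\n",
              x$m, x$D, x$tau, x$n_dropped))
  invisible(x)
}

# Vectorised ordinal-pattern labels for an m x D matrix of window
# magnitudes. The label is 1 + the lexicographic (Lehmer-code) rank of the
# permutation that sorts each row ascending, so an increasing row maps to 1
# and a decreasing row to D!; for D = 2 this is the classic
# ascending -> 1, descending -> 2 convention. Ties are broken by temporal
# order: the earlier sample counts as the smaller one.
#' @keywords internal
rank_patterns <- function(V) {
  m <- nrow(V); D <- ncol(V)
  if (anyNA(V)) stop("NaN/NA in embedded vectors; ordinal ranks are undefined")
  r <- matrix(1L, m, D)
  n_tied <- logical(m)
  for (j in seq_len(D)) {
    for (k in seq_len(D)) {
      if (k == j) next
      if (k < j) {
        eq <- V[, k] == V[, j]
        n_tied <- n_tied | eq
        r[, j] <- r[, j] + (V[, k] < V[, j]) + eq
      } else {
        r[, j] <- r[, j] + (V[, k] < V[, j])
      }
    }
  }
  # sorting permutation = inverse of the rank vector
  p <- matrix(0L, m, D)
  p[cbind(rep.int(seq_len(m), D), as.vector(r))] <- rep(seq_len(D), each = m)
  labels <- rep.int(1, m)
  for (j in seq_len(D - 1L)) {
    cj <- integer(m)
    for (k in seq.int(j + 1L, D)) cj <- cj + (p[, k] < p[, j])
    labels <- labels + cj * factorial(D - j)
  }
  list(labels = as.integer(labels), tie_fraction = mean(n_tied))
}

#' Ordinal pattern of a single vector
#'
#' Maps `D` magnitudes to an integer in `1..D!` identifying their ordinal
#' arrangement: two vectors get the same label exactly when their
#' componentwise order relations agree. The label is 1 plus the
#' lexicographic rank of the permutation that sorts the vector ascending,
#' so a strictly increasing vector maps to 1, a strictly decreasing one to
#' `D!`, and for `D = 2` the mapping is ascending -> 1, descending -> 2.
#' Ties are resolved by treating the earlier sample as smaller.
#'
#' @param v numeric vector of length `D >= 2`.
#' @return integer in `1..factorial(length(v))`.
#' @examples
#' ordinal_pattern(c(0.1, 0.5)) # 1
#' ordinal_pattern(c(0.5, 0.1)) # 2
#' ordinal_pattern(c(2, 5, 4))  # same label as c(1, 3, 2)
#' @export
ordinal_pattern <- function(v) {
  v <- check_signal(v, "v")
  if (length(v) < 2L) stop("an ordinal pattern needs at least 2 components")
  rank_patterns(matrix(v, nrow = 1L))$labels
}

#' Encode a signal into an ordinal-pattern sequence
#'
#' Runs [op_embed()] and ranks every window with the convention of
#' [ordinal_pattern()]. The embedded magnitudes are returned alongside the
#' symbols because the magnitude-variability statistic
#' ([magnitude_variability()]) needs them; the symbol sequence alone would
#' discard exactly the information that statistic recovers.
#'
#' A warning reports the fraction of windows containing tied magnitudes
#' (ties are broken by temporal order): quantised signals should normally
#' be passed through [dither_signal()] first.
#'
#' @inheritParams op_embed
#' @param warn_ties warn when tied magnitudes occur inside windows.
#' @return an object of class `"op_encoding"`: a list with `symbols`
#'   (integers in `1..D!`), `vectors`, `start_indices`, `D`, `tau`, `m`,
#'   `tie_fraction`, `n_dropped`.
#' @examples
#' enc <- op_encode(c(1, 3, 2, 5, 4), D = 3)
#' enc$symbols # both windows have the same low-high-mid arrangement
#' @export
op_encode <- function(x, D, tau = 1L, warn_ties = TRUE) {
  emb <- op_embed(x, D, tau)
  rp <- rank_patterns(emb$vectors)
  if (warn_ties && rp$tie_fraction > 0)
    warning(sprintf(
      "tied magnitudes in %.3g%% of windows (broken by temporal order); consider dither_signal()",
      100 * rp$tie_fraction))
  structure(list(symbols = rp$labels, vectors = emb$vectors,
                 start_indices = emb$start_indices, D = emb$D,
                 tau = emb$tau, m = emb$m,
                 tie_fraction = rp$tie_fraction,
                 n_dropped = emb$n_dropped),
            class = "op_encoding")
}

#' @export
print.op_encoding <- function(x, ...) {
  cat(sprintf("ordinal-pattern encoding: m = %d symbols in 1..%d (D = %d, tau = %d)\n",
              x$m, factorial(x$D), x$D, x$tau))
  if (x$tie_fraction > 0)
    cat(sprintf("  tie fraction: %.3g\n", x$tie_fraction))
  invisible(x)
}
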