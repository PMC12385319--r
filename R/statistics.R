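#' Ordinal-pattern probability distribution
#'
#' Counts the occurrences of each of the `D!` ordinal patterns in a symbol
#' sequence and normalises by the number of windows `m`.
#'
#' @param symbols an `"op_encoding"` from [op_encode()], or an integer
#'   vector of symbols in `1..factorial(D)`.
#' @param D embedding dimension; taken from the encoding when one is given.
#' @return an object of class `"op_distribution"`: list with `counts` and
#'   `p` (length-`D!` vectors), `D`, and `m`.
#' @examples
#' op_distribution(c(1L, 1L, 2L, 2L), D = 2)$p # 0.5 0.5
#' @export
op_distribution <- function(symbols, D = NULL) {
  if (inherits(symbols, "op_encoding")) {
    D <- symbols$D
    symbols <- symbols$symbols
  }
  if (is.null(D)) stop("`D` is required when `symbols` is a plain vector")
  D <- as.integer(D)
  nsym <- factorial(D)
  if (!length(symbols)) stop("empty symbol sequence")
  symbols <- as.integer(symbols)
  if (anyNA(symbols) || any(symbols < 1L) || any(symbols > nsym))
    stop(sprintf("symbols must be integers in 1..%d", nsym))
  counts <- tabulate(symbols, nbins = nsym)
  structure(list(counts = counts, p = counts / length(symbols),
                 D = D, m = length(symbols)),
            class = "op_distribution")
}

#' @export
print.op_distribution <- function(x, ...) {
  cat(sprintf("ordinal-pattern distribution: D = %d (%d patterns), m = %d windows, %d observed\n",
              x$D, length(x$p), x$m, sum(x$counts > 0)))
  invisible(x)
}

#' @keywords internal
as_probabilities <- function(dist) {
  p <- if (inherits(dist, "op_distribution")) dist$p else as.numeric(dist)
  if (anyNA(p) || any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-8) stop("probabilities must sum to 1")
  p
}

#' Permutation entropy (Shannon entropy of the ordinal patterns, in bits)
#'
#' `H = -sum_a P(a) log2 P(a)`, with `0 log2 0 = 0`. `H` ranges from 0
#' (a single pattern) to `log2(D!)` (uniform patterns).
#'
#' @param dist an `"op_distribution"` or a probability vector.
#' @return entropy in bits.
#' @examples
#' permutation_entropy(c(0.5, 0.25, 0.25, 0, 0, 0)) # 1.5
#' @export
permutation_entropy <- function(dist) {
  p <- as_probabilities(dist)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Renyi min-entropy (bits)
#'
#' `H_inf = -log2 max_a P(a)`, the q -> Inf limit of the Renyi family and
#' the lower bound of every Renyi entropy of the distribution. It resolves
#' differences between near-uniform distributions better than the Shannon
#' entropy because it depends only on the most probable pattern.
#'
#' @inheritParams permutation_entropy
#' @return min-entropy in bits.
#' @examples
#' min_entropy(c(0.5, 0.25, 0.25, 0, 0, 0)) # 1
#' @export
min_entropy <- function(dist) {
  p <- as_probabilities(dist)
  -log2(max(p))
}

#' Renyi entropy of order q (bits)
#'
#' `H_q = log2(sum_a P(a)^q) / (1 - q)` for `q > 0`, `q != 1`. The family
#' decreases in `q`, interpolating between the Shannon entropy (`q -> 1`,
#' use [permutation_entropy()]) and the min-entropy (`q -> Inf`, use
#' [min_entropy()], which is computed directly rather than by large-q
#' extrapolation).
#'
#' @inheritParams permutation_entropy
#' @param q Renyi order, positive and not 1; `q = Inf` dispatches to
#'   [min_entropy()].
#' @return entropy in bits.
#' @examples
#' renyi_entropy(c(0.5, 0.5), q = 2) # collision entropy, 1 bit
#' @export
renyi_entropy <- function(dist, q) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0)
    stop("`q` must be a single positive number")
  if (is.infinite(q)) return(min_entropy(dist))
  if (q == 1) stop("q = 1 is the Shannon limit; use permutation_entropy()")
  p <- as_probabilities(dist)
  p <- p[p > 0]
  log2(sum(p^q)) / (1 - q)
}

#' Magnitude variability of the embedded vectors, per ordinal pattern
#'
#' For every ordinal pattern `a` and window component `j`, `sigma_j(a)` is
#' the dispersion (sample standard deviation by default, or inter-quartile
#' range) of the signal magnitudes at component `j` over all embedded
#' vectors carrying symbol `a`. These are combined into the
#' pattern-averaged logarithms
#' `<log2 sigma_j> = sum_a P(a) log2 sigma_j(a)` and their component
#' average `avg = (1/D) sum_j <log2 sigma_j>` -- the scalar that
#' complements the entropies: it measures, on a log2 scale, the typical
#' amplitude spread the ordinal encoding throws away. Doubling a signal
#' shifts `avg` by exactly +1 and leaves every entropy unchanged.
#'
#' Patterns with fewer than two occurrences (dispersion undefined) or zero
#' dispersion (`log2 0 = -Inf`) are excluded and the weights renormalised
#' over the included patterns; the excluded probability mass is reported
#' and is negligible for long signals at the usual `D <= 5`.
#'
#' @param encoding an `"op_encoding"` from [op_encode()] (symbols and
#'   magnitudes must come from the same call).
#' @param estimator dispersion estimator: `"sd"` (sample standard
#'   deviation, the default) or `"iqr"` (inter-quartile range, robust to
#'   outliers and preferable for short signals). `"std"` is accepted as an
#'   alias of `"sd"`.
#' @return an object of class `"op_variability"`: list with `sigma`
#'   (`D! x D` matrix, `NA` where undefined), `mean_log_sigma` (length
#'   `D`), `avg` (scalar), `dispersion` (length `D`, the weighted standard
#'   deviation `sqrt(<log2^2 sigma_j> - <log2 sigma_j>^2)` used as error
#'   bars), `included` (logical, length `D!`), `excluded_mass`,
#'   `estimator`, `D`, `m`.
#' @examples
#' enc <- op_encode(simulate_coupled_logistic(3.8, 0.01, n = 2000)$x, D = 3)
#' magnitude_variability(enc)$avg
#' @export
magnitude_variability <- function(encoding, estimator = c("sd", "iqr", "std")) {
  if (!inherits(encoding, "op_encoding"))
    stop("`encoding` must be an \"op_encoding\" from op_encode()")
  estimator <- match.arg(estimator)
  if (estimator == "std") estimator <- "sd"
  V <- encoding$vectors
  sym <- encoding$symbols
  D <- encoding$D
  m <- encoding$m
  nsym <- factorial(D)
  counts <- tabulate(sym, nbins = nsym)
  p <- counts / m

  sigma <- matrix(NA_real_, nrow = nsym, ncol = D,
                  dimnames = list(alpha = NULL,
                                  paste0("j", seq_len(D))))
  present <- which(counts >= 2L)
  if (estimator == "sd") {
    s1 <- rowsum(V, sym, reorder = TRUE)
    s2 <- rowsum(V * V, sym, reorder = TRUE)
    grp <- as.integer(rownames(s1))
    ng <- counts[grp]
    keep <- ng >= 2L
    var_ <- (s2[keep, , drop = FALSE] -
             s1[keep, , drop = FALSE]^2 / ng[keep]) / (ng[keep] - 1)
    sigma[grp[keep], ] <- sqrt(pmax(var_, 0))
  } else {
    rows <- split(seq_len(m), sym)
    for (a in present) {
      sub <- V[rows[[as.character(a)]], , drop = FALSE]
      sigma[a, ] <- apply(sub, 2L, function(col)
        diff(quantile(col, c(0.25, 0.75), names = FALSE, type = 7)))
    }
  }

  included <- counts >= 2L & !is.na(sigma[, 1L]) &
    apply(sigma > 0, 1L, function(z) all(z) && !anyNA(z))
  if (!any(included))
    stop("insufficient data for variability: every ordinal pattern has fewer than 2 occurrences or zero spread")
  w <- p[included] / sum(p[included])
  ls <- log2(sigma[included, , drop = FALSE])
  mean_log_sigma <- colSums(w * ls)
  disp2 <- colSums(w * ls^2) - mean_log_sigma^2
  structure(list(sigma = sigma,
                 mean_log_sigma = mean_log_sigma,
                 avg = mean(mean_log_sigma),
                 dispersion = sqrt(pmax(disp2, 0)),
                 included = included,
                 excluded_mass = 1 - sum(p[included]),
                 estimator = estimator, D = D, m = m),
            class = "op_variability")
}

#' @export
print.op_variability <- function(x, ...) {
  cat(sprintf("magnitude variability (%s): avg_j{<log2 sigma_j>} = %.4f\n",
              x$estimator, x$avg))
  cat("  <log2 sigma_j> per component:",
      paste(sprintf("%.4f", x$mean_log_sigma), collapse = " "), "\n")
  if (x$excluded_mass > 0)
    cat(sprintf("  excluded pattern mass: %.3g\n", x$excluded_mass))
  invisible(x)
}

#' One-call ordinal-pattern summary of a signal
#'
#' Encodes the signal, computes the pattern distribution, the permutation
#' and Renyi min-entropies, and the magnitude-variability panel, returning
#' everything with a provenance block (encoding geometry, tie fraction,
#' excluded pattern mass) sufficient to re-run the analysis.
#'
#' @inheritParams op_embed
#' @inheritParams magnitude_variability
#' @param dither optional dither amplitude applied before encoding
#'   (`"auto"` for range * 2^-16, a number for an explicit amplitude,
#'   `NULL` for none).
#' @param seed seed for the dither noise, if any.
#' @return an object of class `"op_summary"`: list with `H`, `H_inf`,
#'   `H_max` (bits), `variability` (see [magnitude_variability()]),
#'   `distribution`, and `provenance`.
#' @examples
#' x <- simulate_coupled_logistic(3.8, 0.01, n = 5000)$x
#' op_summary(x, D = 4)
#' @export
op_summary <- function(x, D, tau = 1L, estimator = c("sd", "iqr", "std"),
                       dither = NULL, seed = NULL) {
  x <- check_signal(x)
  amplitude <- NULL
  if (!is.null(dither)) {
    amplitude <- if (identical(dither, "auto")) diff(range(x)) * 2^-16
                 else as.numeric(dither)
    x <- dither_signal(x, amplitude, seed = seed)
  }
  enc <- op_encode(x, D, tau)
  dist <- op_distribution(enc)
  vab <- magnitude_variability(enc, estimator)
  structure(list(
    H = permutation_entropy(dist),
    H_inf = min_entropy(dist),
    H_max = log2(factorial(enc$D)),
    variability = vab,
    distribution = dist,
    provenance = list(
      T = length(x), D = enc$D, tau = enc$tau, m = enc$m,
      tie_fraction = enc$tie_fraction,
      excluded_mass = vab$excluded_mass,
      estimator = vab$estimator,
      dither_amplitude = amplitude, seed = seed,
      opvar_version = as.character(packageVersion("opvar")))),
    class = "op_summary")
}

#' @export
print.op_summary <- function(x, ...) {
  pv <- x$provenance
  cat(sprintf("ordinal-pattern summary (T = %d, D = %d, tau = %d, m = %d)\n",
              pv$T, pv$D, pv$tau, pv$m))
  cat(sprintf("  H      = %.4f bits (max %.4f)\n", x$H, x$H_max))
  cat(sprintf("  H_inf  = %.4f bits\n", x$H_inf))
  cat(sprintf("  avg_j{<log2 sigma_j>} = %.4f (%s estimator)\n",
              x$variability$avg, pv$estimator))
  if (pv$tie_fraction > 0)
    cat(sprintf("  tie fraction %.3g; excluded pattern mass %.3g\n",
                pv$tie_fraction, pv$excluded_mass))
  invisible(x)
}
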