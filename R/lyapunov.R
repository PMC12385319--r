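#' Maximum Lyapunov exponent from the analytic Jacobian (Benettin)
#'
#' Propagates a unit tangent vector through the exact 2x2 Jacobian of the
#' map along a trajectory, renormalising at every step; the maximum
#' Lyapunov exponent is the average natural-log growth rate. This is the
#' reference method when the equations of motion are known: it involves
#' no embedding, neighbour search, or tracking heuristics.
#'
#' @param map `"logistic"` (coupled identical logistic maps, parameters
#'   `r`, `eps`) or `"henon"` (parameters `a`, `b`).
#' @param r,eps coupled-logistic parameters (used when
#'   `map = "logistic"`).
#' @param a,b Henon parameters (used when `map = "henon"`).
#' @param n_steps iterations averaged over.
#' @param transient iterations discarded first.
#' @param x0,y0 initial state.
#' @return an object of class `"lyapunov_result"`: list with `lambda`
#'   (nats per iteration), `method = "jacobian"`, `n_steps`, and a
#'   `params` echo.
#' @examples
#' # fully chaotic isolated logistic map: lambda = ln 2
#' mle_jacobian("logistic", r = 4, eps = 0, n_steps = 1e5)$lambda
#' @export
mle_jacobian <- function(map = c("logistic", "henon"), r = NULL, eps = NULL,
                         a = NULL, b = NULL, n_steps = 1e6,
                         transient = 1e3, x0 = 0.65, y0 = 0.44) {
  map <- match.arg(map)
  n_steps <- as.integer(n_steps); transient <- as.integer(transient)
  if (n_steps < 1L) stop("`n_steps` must be >= 1")
  if (map == "logistic") {
    if (is.null(r) || is.null(eps))
      stop("logistic map needs `r` and `eps`")
    lambda <- cpp_benettin_logistic(r, eps, x0, y0, n_steps, transient)
    params <- list(map = map, r = r, eps = eps, x0 = x0, y0 = y0,
                   transient = transient)
  } else {
    if (is.null(a) || is.null(b)) stop("Henon map needs `a` and `b`")
    lambda <- cpp_benettin_henon(a, b, x0, y0, n_steps, transient)
    params <- list(map = map, a = a, b = b, x0 = x0, y0 = y0,
                   transient = transient)
  }
  structure(list(lambda = lambda, method = "jacobian",
                 n_steps = n_steps, params = params),
            class = "lyapunov_result")
}

#' Maximum Lyapunov exponent from a trajectory (Wolf's method)
#'
#' Reconstructs the state sequence (a delay embedding when `x` is a scalar
#' signal; the measured states themselves when `x` is a matrix or a
#' [simulate_coupled_logistic()]/[simulate_henon()] trajectory), finds the
#' nearest neighbour of the fiducial point that is at least
#' `min_sep_frac * T` samples away in time (to exclude temporal
#' neighbours on the same trajectory segment), tracks the pair for
#' `max_track` iterations, accumulates the log distance growth, and then
#' replaces the neighbour by a nearby point chosen to minimise the change
#' of orientation relative to the fiducial point. The defaults --
#' dimension 2, delay 1, tracking horizon 10, 10% minimum temporal
#' separation -- are the standard configuration for two-dimensional maps;
#' the short horizon avoids saturation of the divergence at attractor
#' size.
#'
#' For maps with a weakly coupled hidden coordinate, pass the full
#' two-dimensional trajectory: a scalar delay embedding localises the
#' hidden coordinate only up to a factor of the coupling strength, so
#' nearest "neighbours" can hide state separations orders of magnitude
#' larger than their embedded distance, which inflates short-horizon
#' divergence estimates.
#'
#' Exactly coincident neighbour pairs (as arise on periodic orbits stored
#' in finite precision) contribute zero growth, so periodic signals yield
#' a non-positive estimate rather than an error.
#'
#' @param x numeric signal (one observed coordinate, to be
#'   delay-embedded), a numeric matrix with one state per row, or a
#'   `"map_trajectory"` (its `(x, y)` states are used directly).
#' @param embed_dim embedding dimension (2 for the maps handled here).
#' @param delay embedding delay in samples.
#' @param max_track iterations a neighbour pair is tracked before
#'   renormalisation (the divergence horizon).
#' @param min_sep_frac minimum temporal separation between fiducial and
#'   neighbour, as a fraction of the signal length.
#' @param angle_max maximum orientation change (radians) accepted when
#'   choosing a replacement neighbour before falling back to the smallest
#'   available orientation change.
#' @return an object of class `"lyapunov_result"`: list with `lambda`
#'   (nats per iteration), `method = "wolf"`, `n_steps` (iterations
#'   tracked), `n_segments`, and a `params` echo.
#' @examples
#' x <- simulate_henon(1.4, 0.3, n = 2e4)$x
#' mle_wolf(x)$lambda # about 0.42
#' @export
mle_wolf <- function(x, embed_dim = 2L, delay = 1L, max_track = 10L,
                     min_sep_frac = 0.1, angle_max = 0.3) {
  embed_dim <- as.integer(embed_dim); delay <- as.integer(delay)
  max_track <- as.integer(max_track)
  if (embed_dim < 2L) stop("`embed_dim` must be >= 2")
  if (delay < 1L) stop("`delay` must be >= 1")
  if (max_track < 1L) stop("`max_track` must be >= 1")
  if (min_sep_frac < 0 || min_sep_frac >= 1)
    stop("`min_sep_frac` must be in [0, 1)")
  if (inherits(x, "map_trajectory")) x <- cbind(x$x, x$y)
  if (is.matrix(x)) {
    if (anyNA(x) || any(!is.finite(x)))
      stop("`x` contains non-finite values (NA/NaN/Inf)")
    pts <- x
    n_signal <- nrow(x)
    embed_dim <- ncol(x)
  } else {
    x <- check_signal(x)
    n_signal <- length(x)
    np <- n_signal - (embed_dim - 1L) * delay
    if (np < 2L)
      stop(sprintf("signal too short for a dimension-%d, delay-%d embedding",
                   embed_dim, delay))
    pts <- vapply(seq_len(embed_dim) - 1L,
                  function(d) x[seq_len(np) + d * delay], numeric(np))
  }
  out <- cpp_wolf(pts, n_signal, max_track, min_sep_frac, angle_max)
  structure(list(lambda = out$lambda, method = "wolf",
                 n_steps = out$n_steps, n_segments = out$n_segments,
                 params = list(embed_dim = embed_dim, delay = delay,
                               max_track = max_track,
                               min_sep_frac = min_sep_frac,
                               angle_max = angle_max, T = n_signal)),
            class = "lyapunov_result")
}

#' @export
print.lyapunov_result <- function(x, ...) {
  cat(sprintf("maximum Lyapunov exponent: %.4f nats/iteration (%s method, %d steps)\n",
              x$lambda, x$method, as.integer(x$n_steps)))
  invisible(x)
}
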