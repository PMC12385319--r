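#' Simulate two coupled identical logistic maps
#'
#' Iterates
#' `x[t+1] = (1 - eps) f(x[t]) + eps f(y[t])`,
#' `y[t+1] = (1 - eps) f(y[t]) + eps f(x[t])`,
#' with `f(z) = r z (1 - z)`, discarding a transient and returning the
#' last `n` iterates of both coordinates in double precision. With
#' `eps = 0` the two maps are isolated logistic maps; the equations are
#' symmetric under swapping the coordinates together with their initial
#' conditions. Defaults are the benchmark configuration used throughout
#' the package: `x0 = 0.65`, `y0 = 0.44`, `transient = 1e3`, `n = 1e6`.
#'
#' @param r logistic control parameter, in `(3, 4]`.
#' @param eps coupling strength, in `[0, 1]`.
#' @param n retained trajectory length.
#' @param transient iterations discarded before retaining.
#' @param x0,y0 initial states, in `(0, 1)`.
#' @return an object of class `"map_trajectory"`: list with numeric
#'   vectors `x` and `y` (length `n`) and a `params` list.
#' @examples
#' tr <- simulate_coupled_logistic(3.8, 0.01, n = 1000)
#' range(tr$x) # stays inside [0, 1]
#' @export
simulate_coupled_logistic <- function(r, eps, n = 1e6, transient = 1e3,
                                      x0 = 0.65, y0 = 0.44) {
  if (!is.numeric(r) || length(r) != 1L || r <= 3 || r > 4)
    stop("`r` must be in (3, 4]")
  if (!is.numeric(eps) || length(eps) != 1L || eps < 0 || eps > 1)
    stop("`eps` must be in [0, 1]")
  if (x0 <= 0 || x0 >= 1 || y0 <= 0 || y0 >= 1)
    stop("initial states must lie in (0, 1)")
  n <- as.integer(n); transient <- as.integer(transient)
  if (n < 1L) stop("`n` must be >= 1")
  if (transient < 0L) stop("`transient` must be >= 0")
  out <- cpp_logistic_pair(r, eps, x0, y0, n, transient)
  structure(list(x = out$x, y = out$y,
                 params = list(map = "logistic", r = r, eps = eps,
                               x0 = x0, y0 = y0, n = n,
                               transient = transient)),
            class = "map_trajectory")
}

#' Simulate the Henon map
#'
#' Iterates `x[t+1] = 1 - a x[t]^2 + y[t]`, `y[t+1] = b x[t]`, discarding
#' a transient and returning the last `n` iterates. The classic chaotic
#' regime is `a = 1.4, b = 0.3`; `a = 1.0, b = 0.3` is periodic.
#' Divergence (`|x| > 1e6`) aborts with an error naming the iteration.
#'
#' @param a,b Henon control parameters.
#' @inheritParams simulate_coupled_logistic
#' @return an object of class `"map_trajectory"` (see
#'   [simulate_coupled_logistic()]). Note `y[t+1] = b x[t]`: the y signal
#'   is the x signal scaled by `b` and shifted one step.
#' @examples
#' tr <- simulate_henon(1.4, 0.3, n = 1000)
#' head(tr$y[-1] / tr$x[-1000]) # all equal to b
#' @export
simulate_henon <- function(a, b, n = 1e6, transient = 1e3,
                           x0 = 0.65, y0 = 0.44) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a))
    stop("`a` must be a finite number")
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b))
    stop("`b` must be a finite number")
  n <- as.integer(n); transient <- as.integer(transient)
  if (n < 1L) stop("`n` must be >= 1")
  if (transient < 0L) stop("`transient` must be >= 0")
  out <- cpp_henon_pair(a, b, x0, y0, n, transient)
  structure(list(x = out$x, y = out$y,
                 params = list(map = "henon", a = a, b = b,
                               x0 = x0, y0 = y0, n = n,
                               transient = transient)),
            class = "map_trajectory")
}

#' @export
print.map_trajectory <- function(x, ...) {
  p <- x$params
  spec <- if (p$map == "logistic")
    sprintf("coupled logistic maps (r = %g, eps = %g)", p$r, p$eps)
  else sprintf("Henon map (a = %g, b = %g)", p$a, p$b)
  cat(sprintf("%s: %d iterates after a transient of %d, from (%g, %g)\n",
              spec, p$n, p$transient, p$x0, p$y0))
  invisible(x)
}

#' Add observational noise to a signal
#'
#' Adds i.i.d. zero-mean Gaussian samples of standard deviation `sd` to a
#' measured signal. This is observational (measurement) noise: it
#' corrupts what is recorded without feeding back into the dynamics that
#' generated the signal.
#'
#' @param x numeric signal.
#' @param sd noise standard deviation, in signal units; 0 returns `x`
#'   unchanged.
#' @param seed optional integer seed; when given, the caller's RNG state
#'   is left untouched and the output is reproducible.
#' @return noisy signal, same length as `x`.
#' @examples
#' x <- simulate_henon(1.4, 0.3, n = 1000)$x
#' noisy <- add_observational_noise(x, sd = 0.1, seed = 42)
#' @export
add_observational_noise <- function(x, sd, seed = NULL) {
  x <- check_signal(x)
  if (!is.numeric(sd) || length(sd) != 1L || is.na(sd) || sd < 0)
    stop("`sd` must be a single non-negative number")
  if (sd == 0) return(x)
  x + with_local_seed(seed, rnorm(length(x), 0, sd))
}
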