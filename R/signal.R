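#' @keywords internal
check_signal <- function(x, arg = "x") {
  if (!is.numeric(x))
    stop(sprintf("`%s` must be a numeric vector", arg), call. = FALSE)
  if (length(x) < 1L)
    stop(sprintf("`%s` must contain at least one sample", arg), call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop(sprintf("`%s` contains non-finite values (NA/NaN/Inf)", arg),
         call. = FALSE)
  invisible(as.numeric(x))
}

# Run `expr` with a locally seeded RNG, restoring the caller's RNG state.
# seed = NULL leaves the global stream untouched (and advances it).
#' @keywords internal
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Resample a signal with an embedding delay
#'
#' Keeps every `tau`-th sample starting from the first:
#' `x[1], x[1 + tau], ..., x[1 + n*tau]` with `n = floor((T - 1) / tau)`,
#' so the output has `n + 1` samples. With `tau = 1` this is the identity.
#' Resampling acts as a crude low-pass filter; the ordinal encoding itself
#' takes `tau` as a within-window spacing instead (see [op_encode()]), which
#' uses the whole signal.
#'
#' @param x numeric signal.
#' @param tau positive integer delay.
#' @return numeric vector of length `floor((length(x) - 1) / tau) + 1`.
#' @examples
#' resample_signal(1:10, 3) # 1 4 7 10
#' @export
resample_signal <- function(x, tau = 1L) {
  x <- check_signal(x)
  tau <- as.integer(tau)
  if (is.na(tau) || tau < 1L) stop("`tau` must be a positive integer")
  x[seq.int(1L, length(x), by = tau)]
}

#' Dither a quantised signal
#'
#' Adds tiny white noise to break the magnitude degeneracies (exact ties)
#' that analogue-to-digital conversion introduces, so that ordinal ranking
#' is almost surely unambiguous. The default amplitude is the convention
#' used for 16-bit recordings: the signal range times `2^-16`, i.e. one
#' quantisation step.
#'
#' @param x numeric signal.
#' @param amplitude noise amplitude in signal units; `NULL` (default) uses
#'   `diff(range(x)) * 2^-16`. `amplitude = 0` returns `x` unchanged.
#' @param dist `"gaussian"` (zero-mean normal with standard deviation
#'   `amplitude`, the default) or `"uniform"` (uniform on
#'   `[-amplitude, amplitude]`).
#' @param seed optional integer seed; when given, the caller's RNG state is
#'   left untouched and repeated calls are bit-identical.
#' @return the dithered signal, same length as `x`.
#' @examples
#' x <- round(sin(1:100), 1) # heavily quantised: many ties
#' d <- dither_signal(x, seed = 1)
#' any(duplicated(d))
#' @export
dither_signal <- function(x, amplitude = NULL,
                          dist = c("gaussian", "uniform"), seed = NULL) {
  x <- check_signal(x)
  dist <- match.arg(dist)
  if (is.null(amplitude)) amplitude <- diff(range(x)) * 2^-16
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude < 0)
    stop("`amplitude` must be a single non-negative number")
  if (amplitude == 0) return(x)
  noise <- with_local_seed(seed, switch(dist,
    gaussian = rnorm(length(x), 0, amplitude),
    uniform  = runif(length(x), -amplitude, amplitude)))
  x + noise
}

#' Read a univariate signal from a text file
#'
#' Reads a single-column numeric series (one magnitude per line, or one
#' column of a delimited file). A non-numeric first row is treated as a
#' header and skipped. Malformed rows are reported with their line numbers;
#' interior blank lines are an error (they usually indicate a truncated
#' export).
#'
#' @param path file to read.
#' @param delimiter field separator for multi-column files; `NULL` (default)
#'   auto-detects comma or tab.
#' @param column which column to take when the file has several.
#' @return numeric vector with attribute `"label"` set to the file name.
#' @export
read_signal <- function(path, delimiter = NULL, column = 1L) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  # trailing blank lines are tolerated, interior ones are not
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (!length(lines)) stop(sprintf("empty signal file: %s", path))
  blank <- which(!nzchar(trimws(lines)))
  if (length(blank))
    stop(sprintf("blank line at line %d of %s", blank[1L], path))
  if (is.null(delimiter)) {
    delimiter <- if (grepl(",", lines[1L], fixed = TRUE)) ","
                 else if (grepl("\t", lines[1L], fixed = TRUE)) "\t"
                 else NULL
  }
  fields <- if (is.null(delimiter)) trimws(lines)
            else vapply(strsplit(lines, delimiter, fixed = TRUE),
                        function(f) {
                          if (length(f) < column) NA_character_
                          else trimws(f[[column]])
                        }, character(1L))
  vals <- suppressWarnings(as.numeric(fields))
  start <- 1L
  if (is.na(vals[1L]) && length(vals) > 1L) start <- 2L # header row
  vals <- vals[seq.int(start, length(vals))]
  bad <- which(is.na(vals))
  if (length(bad))
    stop(sprintf("non-numeric value(s) in %s at line(s) %s", path,
                 paste(head(bad + start - 1L, 5L), collapse = ", ")))
  if (!length(vals)) stop(sprintf("no numeric data in %s", path))
  if (any(!is.finite(vals)))
    stop(sprintf("non-finite value(s) in %s", path))
  structure(vals, label = basename(path))
}
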