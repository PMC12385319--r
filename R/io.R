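#' @keywords internal
record_to_list <- function(record) {
  if (inherits(record, "op_summary")) {
    vab <- record$variability
    dist <- record$distribution
    list(
      H = record$H, H_inf = record$H_inf, H_max = record$H_max,
      avg_log2_sigma = vab$avg,
      per_j = list(mean_log_sigma = unname(vab$mean_log_sigma),
                   dispersion = unname(vab$dispersion)),
      per_alpha = list(alpha = seq_along(dist$counts),
                       count = dist$counts, p = dist$p,
                       included = unname(vab$included)),
      sigma = unname(as.data.frame(vab$sigma)),
      provenance = record$provenance)
  } else if (is.list(record)) {
    lapply(record, function(el)
      if (inherits(el, c("op_summary", "lyapunov_result", "scaling_curve")))
        record_to_list(unclass(el)) else el)
  } else record
}

#' Write an analysis record to disk
#'
#' Serialises an analysis result (an [op_summary()] object, or any list of
#' results) either as JSON -- numeric fields at full double precision, so
#' that [read_record()] round-trips them exactly -- or, for an
#' `"op_summary"`, as the per-pattern CSV table with one row per ordinal
#' pattern (`alpha, count, p, sigma_1..sigma_D`).
#'
#' @param record the result to write.
#' @param path output file.
#' @param format `"json"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    # I(17) significant digits: the shortest precision that round-trips
    # IEEE doubles exactly
    jsonlite::write_json(record_to_list(record), path,
                         auto_unbox = TRUE, digits = I(17), null = "null",
                         pretty = TRUE)
  } else {
    if (!inherits(record, "op_summary"))
      stop("csv output is only defined for op_summary records")
    vab <- record$variability
    dist <- record$distribution
    tab <- data.frame(alpha = seq_along(dist$counts),
                      count = dist$counts, p = dist$p)
    sig <- as.data.frame(vab$sigma)
    names(sig) <- paste0("sigma_", seq_len(ncol(sig)))
    write.csv(cbind(tab, sig), path, row.names = FALSE)
  }
  invisible(path)
}

#' Read back a JSON analysis record
#'
#' @param path a file written by [write_record()] with `format = "json"`.
#' @return the record as a plain list; numeric fields are recovered at
#'   full precision.
#' @export
read_record <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
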