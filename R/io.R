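#' Write / read a concentration profile as CSV
#'
#' Long-format CSV with header `epsilon,tau,C,source`, the package's exchange
#' format for spatial profiles (analytic or numeric).
#'
#' @param profile An `"sdd_profile"` data.frame.
#' @param path Output file path.
#' @return `write_profile_csv` returns `path` invisibly; `read_profile_csv`
#'   returns the profile data.frame (class `"sdd_profile"`).
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(all(c("epsilon", "tau", "C", "source") %in% names(profile)))
  utils::write.csv(profile[, c("epsilon", "tau", "C", "source")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("epsilon", "tau", "C", "source") %in% names(df)))
  class(df) <- c("sdd_profile", "data.frame")
  df
}

#' Read a plain key=value configuration file
#'
#' One `key=value` pair per line; blank lines and `#` comments are ignored.
#' Recognized keys include `R`, `bc`, `D`, `k`, `q`, `L`, `tau_list`
#' (comma-separated), `eps_points`, `max_terms`, `tol`, `b`, `d`, `h`.
#' Values that parse as numbers are returned numeric; comma-separated values
#' as numeric vectors; everything else as strings.
#'
#' @param path File path.
#' @return Named list of settings.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop(sprintf("malformed config line (expected key=value): '%s'", ln),
           call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(nums)) nums else val
  }
  out
}
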