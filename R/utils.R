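#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Seconds since local day start from "YYYY-MM-DDTHH:MM:SS" strings.
#' @keywords internal
parse_iso_seconds <- function(ts) {
  m <- regmatches(ts, regexec(
    "^\\d{4}-\\d{2}-\\d{2}[T ](\\d{2}):(\\d{2}):(\\d{2})", ts))
  vapply(m, function(g) {
    if (length(g) < 4) return(NA_real_)
    as.numeric(g[2]) * 3600 + as.numeric(g[3]) * 60 + as.numeric(g[4])
  }, numeric(1))
}

#' @keywords internal
format_iso <- function(date, secs) {
  sprintf("%sT%02d:%02d:%02d", date,
          secs %/% 3600L, (secs %% 3600L) %/% 60L, secs %% 60L)
}

# <pid>_<wave>_<day>.csv -> list(pid, wave, day); NAs if the name differs.
#' @keywords internal
parse_day_filename <- function(path) {
  b <- sub("\\.csv$", "", basename(path))
  parts <- strsplit(b, "_")[[1]]
  if (length(parts) == 3) {
    list(pid = parts[1], wave = parts[2], day = parts[3])
  } else {
    list(pid = NA_character_, wave = NA_character_, day = NA_character_)
  }
}

# Derive a reproducible 32-bit child seed from a run seed and a label.
#' @keywords internal
derive_seed <- function(seed, label) {
  bytes <- utils::head(charToRaw(paste0(label, ":")), 64)
  acc <- as.double(seed %% 2147483647L)
  for (b in as.integer(bytes)) {
    acc <- (acc * 31 + b) %% 2147483647
  }
  as.integer(acc)
}

#' @keywords internal
require_seed <- function(seed) {
  if (is.null(seed) || is.na(seed)) {
    stop("an explicit seed is required for stochastic generation")
  }
  invisible(as.integer(seed))
}
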