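# Internal validation helpers shared across modules.

check_count <- function(x, name, min = 1L) {
  if (length(x) == 0 || anyNA(x) || any(x < min) || any(x != as.integer(x))) {
    abort(
      sprintf("`%s` must be integer-valued and >= %d.", name, min),
      class = "protlfq_invalid_config"
    )
  }
  as.integer(x)
}

check_fraction <- function(x, name, upper_closed = TRUE) {
  hi_ok <- if (upper_closed) x <= 1 else x < 1
  if (length(x) != 1 || is.na(x) || x < 0 || !hi_ok) {
    abort(
      sprintf("`%s` must lie in [0, 1%s.", name, if (upper_closed) "]" else ")"),
      class = "protlfq_invalid_config"
    )
  }
  as.numeric(x)
}

check_nonneg <- function(x, name) {
  if (any(is.na(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be >= 0.", name), class = "protlfq_invalid_config")
  }
  as.numeric(x)
}

# injection key used throughout: one LC-MS run = sample x replicate
injection_id <- function(sample, replicate) {
  paste(sample, replicate, sep = ":")
}
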