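# Internal input validation. All user-input errors signal class
# "unli2d_validation_error" so the CLI can map them to exit status 2.

fail_validation <- function(...) {
  stop(structure(
    class = c("unli2d_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    fail_validation(name, " must be a single non-missing number")
  if (finite && !is.finite(x))
    fail_validation(name, " must be finite")
  as.numeric(x)
}

check_positive <- function(x, name) {
  x <- check_number(x, name)
  if (x <= 0) fail_validation(name, " must be strictly positive, got ", x)
  x
}

check_count <- function(x, name, min = 1L) {
  x <- check_number(x, name)
  if (x != round(x) || x < min)
    fail_validation(name, " must be an integer >= ", min, ", got ", x)
  as.integer(x)
}
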