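# Internal helpers: classed conditions and small numeric utilities.

stop_netcbi <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "netcbi_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_format <- function(msg, ...) stop_netcbi("netcbi_format_error", msg, ...)
stop_validation <- function(msg, ...) stop_netcbi("netcbi_validation_error", msg, ...)
stop_parameter <- function(msg, ...) stop_netcbi("netcbi_parameter_error", msg, ...)
stop_numerical <- function(msg, ...) stop_netcbi("netcbi_numerical_error", msg, ...)

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

check_in_unit_interval <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1) {
    stop_parameter("%s must be a single number in the open interval (0, 1), got %s",
                   name, paste(format(x), collapse = ","))
  }
  invisible(x)
}
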