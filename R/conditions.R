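# Classed conditions used across the package. The CLI maps these to exit
# codes: schema/config -> 2, estimation/insufficient data -> 3.

pf_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "phloemflow_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

invalid_parameter <- function(msg) pf_stop(msg, "phloemflow_invalid_parameter")
insufficient_data <- function(msg) pf_stop(msg, "phloemflow_insufficient_data")
estimation_error  <- function(msg) pf_stop(msg, "phloemflow_estimation_error")
schema_error      <- function(msg) pf_stop(msg, "phloemflow_schema_error")
config_error      <- function(msg) pf_stop(msg, "phloemflow_config_error")

# Positivity checks that name the offending field in the message.
check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) == 0 || anyNA(x)) {
    invalid_parameter(sprintf("'%s' must be a non-missing numeric value", name))
  }
  bad <- if (strict) any(x <= 0) else any(x < 0)
  if (bad) {
    invalid_parameter(sprintf(
      "'%s' must be strictly positive (got %s)", name,
      paste(signif(x[if (strict) x <= 0 else x < 0], 4), collapse = ", ")
    ))
  }
  invisible(x)
}

check_nonnegative <- function(x, name) check_positive(x, name, strict = FALSE)
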