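# Typed conditions: degenerate inputs are findings (e.g. "constant
# change"), not generic failures, so callers and the CLI can tell
# validation problems from computation problems by class.

prr_error <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "prr_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

degenerate_error <- function(message) {
  prr_error(message, "prr_degenerate_error")
}

insufficient_data_error <- function(message) {
  prr_error(message, "prr_insufficient_data_error")
}

domain_error <- function(message) {
  prr_error(message, "prr_domain_error")
}

validation_error <- function(message) {
  prr_error(message, "prr_validation_error")
}

generation_error <- function(message) {
  prr_error(message, "prr_generation_error")
}

config_error <- function(message) {
  prr_error(message, "prr_config_error")
}

inference_error <- function(message) {
  prr_error(message, "prr_inference_error")
}
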