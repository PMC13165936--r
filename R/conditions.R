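# Classed conditions so callers (and the command-line wrapper) can map
# failures to categories: config/usage, data/format, insufficient data.

pk_stop <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "pupilkit_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

#' @noRd
pk_config_error <- function(message) pk_stop("pupilkit_config_error", message)

#' @noRd
pk_format_error <- function(message) pk_stop("pupilkit_format_error", message)

#' @noRd
pk_contract_error <- function(message) pk_stop("pupilkit_contract_error", message)

#' @noRd
pk_insufficient_data_error <- function(message) {
  pk_stop("pupilkit_insufficient_data_error", message)
}

#' @noRd
pk_degenerate_error <- function(message) pk_stop("pupilkit_degenerate_error", message)
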