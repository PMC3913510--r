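# Classed conditions so callers can distinguish bad files from bad parameters
# without matching on message text. All inherit from "ssr_error".

abort_ssr <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "ssr_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

# condition classes used throughout:
#   ssr_parse_error      - unreadable / non-numeric input file
#   ssr_format_error     - readable but violates the trace contract
#   ssr_range_error      - time interval outside the trace
#   ssr_parameter_error  - b (or another tuning value) out of its domain
#   ssr_data_error       - too few samples / degenerate numeric input
#   ssr_degenerate_error - zero-SD baseline or apex on a window boundary
#   ssr_state_error      - population used before evaluation
#   ssr_encoding_error   - chromosome of the wrong length
#   ssr_io_error         - unwritable output path

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
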