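# Classed error conditions so callers (and the CLI) can react per failure mode
# rather than matching message strings.

abort_surfcutr <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "surfcutr_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

abort_format    <- function(msg) abort_surfcutr(msg, "surfcutr_format_error")
abort_metadata  <- function(msg) abort_surfcutr(msg, "surfcutr_metadata_error")
abort_parameter <- function(msg) abort_surfcutr(msg, "surfcutr_parameter_error")
abort_degenerate <- function(msg) abort_surfcutr(msg, "surfcutr_degenerate_error")
abort_extraction <- function(msg) abort_surfcutr(msg, "surfcutr_extraction_error")
abort_io         <- function(msg) abort_surfcutr(msg, "surfcutr_io_error")
abort_segmentation <- function(msg) abort_surfcutr(msg, "surfcutr_segmentation_error")
abort_matching   <- function(msg) abort_surfcutr(msg, "surfcutr_matching_error")
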