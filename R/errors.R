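# Classed conditions so callers can distinguish failure modes with
# tryCatch(..., NoBolusDetected = ...) etc.

mibg_error <- function(class, message, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "mibg_error"),
                      call = call))
}

#' @keywords internal
is_count_grid <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0)
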