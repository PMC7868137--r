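# Classed error conditions so callers can test failure modes precisely.

ct_error <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg,
                      class = c(paste0("ctinpaint_", class),
                                "ctinpaint_error", "error", "condition")))
}

# shorthand used across modules
err_shape <- function(msg) ct_error("shape_mismatch", msg)
err_config <- function(msg) ct_error("invalid_config", msg)
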