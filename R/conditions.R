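# Classed conditions so callers can handle pipeline failures programmatically.

stop_stridesla <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "stridesla_error")))
}

warn_stridesla <- function(class, message, ...) {
  warning(warningCondition(message, ..., class = c(class, "stridesla_warning")))
}
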