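# Classed conditions so callers (and the CLI) can distinguish failure modes.

dp_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "drugprop_error")))
}

dp_validation_error <- function(msg, ...) dp_stop(msg, "drugprop_validation_error", ...)
dp_parse_error      <- function(msg, ...) dp_stop(msg, "drugprop_parse_error", ...)
dp_config_error     <- function(msg, ...) dp_stop(msg, "drugprop_config_error", ...)

dp_convergence_error <- function(msg, residual = NA_real_, level = NA_character_) {
  dp_stop(msg, "drugprop_convergence_error", residual = residual, level = level)
}

# Informational logging (dropped rows, clamped entries, ...); warnings are kept
# for genuinely suspicious inputs. Silenced by options(drugprop.quiet = TRUE).
dp_log <- function(...) {
  if (!isTRUE(getOption("drugprop.quiet"))) message("drugprop: ", sprintf(...))
}
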