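# Classed conditions so the CLI can map failures to exit codes.

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("crsoil_config_error", "crsoil_error")))
}

stop_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("crsoil_input_error", "crsoil_error")))
}

stop_domain <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("crsoil_domain_error", "crsoil_error")))
}

stop_stage <- function(stage, parent_msg) {
  stop(errorCondition(sprintf("stage '%s' failed: %s", stage, parent_msg),
                      class = c("crsoil_stage_error", "crsoil_error")))
}
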