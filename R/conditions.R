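# Classed conditions so the CLI can map failures to its exit-code contract:
# vm_input_error -> exit 1, vm_anatomy_error -> exit 2.

stop_vm_input <- function(msg) {
  stop(structure(class = c("vm_input_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

stop_vm_anatomy <- function(msg) {
  stop(structure(class = c("vm_anatomy_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}
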