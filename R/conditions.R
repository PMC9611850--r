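# Classed conditions shared across modules. Every user-facing error carries a
# machine-readable class so callers (and the CLI) can branch without parsing
# messages.
vf_stop <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "vinefuse_error"),
                      call = call))
}

vf_warn <- function(message, class) {
  warning(warningCondition(message, class = c(class, "vinefuse_warning")))
}
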