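# Structured error conditions: every contract violation raises a condition of
# class c("voxseg_error_<what>", "voxseg_error", "error") so callers and tests
# can catch specific failures by name.

vox_abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "voxseg_error")))
}

vox_assert <- function(ok, message, class) {
  if (!isTRUE(ok)) vox_abort(message, class)
  invisible(TRUE)
}
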