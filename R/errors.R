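# Classed conditions so callers (and the CLI) can distinguish failure stages.
# All inherit "frfseg_error"; subclasses follow the pipeline stages:
#   io, format, annotation, parameter, config, training, evaluation,
#   serialization, incompatible.

stop_frfseg <- function(subclass, msg, call = sys.call(-1)) {
  cond <- structure(
    class = c(paste0("frfseg_", subclass, "_error"), "frfseg_error",
              "error", "condition"),
    list(message = msg, call = call)
  )
  stop(cond)
}

#' @noRd
assert_that <- function(ok, subclass, msg) {
  if (!isTRUE(ok)) stop_frfseg(subclass, msg, call = sys.call(-1))
  invisible(TRUE)
}
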