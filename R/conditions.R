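# Categorized error conditions. Every user-facing failure is raised through
# one of these so that callers (and the command-line wrapper) can map the
# failure category to a distinct exit code.

hdr_error <- function(message, category = c("input", "config", "degenerate", "internal"),
                      call = sys.call(-1)) {
  category <- match.arg(category)
  cls <- c(sprintf("hdrplan_%s_error", category), "hdrplan_error", "error", "condition")
  stop(structure(
    class = cls,
    list(message = message, call = call, category = category)
  ))
}

abort_input      <- function(message) hdr_error(message, "input", call = sys.call(-1))
abort_config     <- function(message) hdr_error(message, "config", call = sys.call(-1))
abort_degenerate <- function(message) hdr_error(message, "degenerate", call = sys.call(-1))

# scalar checks used across constructors
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopifnot_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is_number(x)) abort_input(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0) abort_input(sprintf("`%s` must be > 0", name))
  if (nonneg && x < 0) abort_input(sprintf("`%s` must be >= 0", name))
  invisible(x)
}
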