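# Structured error conditions. Every user-facing failure mode has its own
# condition class ("rfamtools_<class>") so callers and the CLI can dispatch on
# it rather than matching message text.

stop_rfam <- function(class, message, ..., call = sys.call(-1)) {
  stop(errorCondition(message, ..., class = c(paste0("rfamtools_", class), "rfamtools_error"),
                      call = call))
}

#' @export
print.rfamtools_error <- function(x, ...) {
  cat("<", class(x)[1L], "> ", conditionMessage(x), "\n", sep = "")
  invisible(x)
}

is_rfam_error <- function(x, class) {
  inherits(x, paste0("rfamtools_", class))
}
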