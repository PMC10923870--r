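# internal argument checks shared across model functions

check_conc <- function(x) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("concentrations/times must be finite and non-negative",
         call. = FALSE)
  invisible(x)
}

check_pos <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (is.null(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop(sprintf("parameter '%s' must be a single positive value", nm),
           call. = FALSE)
  }
  invisible(NULL)
}

# condition constructors used by the pipeline layer: input problems map to
# CLI exit code 2, numerical failures to 3
input_error <- function(msg, ...) {
  stop(structure(class = c("allokin_input_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = NULL)))
}

numerical_error <- function(msg, ...) {
  stop(structure(class = c("allokin_numerical_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = NULL)))
}
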