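# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random-number stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_config <- function(...) {
  stop(structure(class = c("parcubin_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("parcubin_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Lightweight logger: messages go to stderr; if `log_file` is set in options
# they are appended there too (used by the pipeline runners).
log_msg <- function(..., file = NULL) {
  txt <- paste0(...)
  message(txt)
  if (!is.null(file)) cat(txt, "\n", file = file, append = TRUE, sep = "")
  invisible(txt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
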