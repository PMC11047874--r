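# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("ecgdnn_param_error", "error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("ecgdnn_format_error", "error")))
}

stop_shape <- function(...) {
  stop(errorCondition(paste0(...), class = c("ecgdnn_shape_error", "error")))
}

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_param(...)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x > 0
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# local RNG scope: run expr under a seed without clobbering the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# write-then-rename so readers never observe a half-written artifact
atomic_write <- function(writer, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}
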