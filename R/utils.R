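#' @keywords internal
"_PACKAGE"

# Run an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards. seed = NULL uses the current
# stream (and therefore advances it).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_gliotrack <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "gliotrack_error")))
}

assert_scalar_num <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (strict && x <= min) || (!strict && x < min)) {
    stop_gliotrack(sprintf("`%s` must be a finite number %s %g", name,
                           if (strict) ">" else ">=", min),
                   "gliotrack_validation_error")
  }
  invisible(x)
}
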