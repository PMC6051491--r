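# Internal helpers: structured errors and parameter validation.

halopol_error <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "halopol_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' @noRd
check_that <- function(cond, field, msg) {
  if (!isTRUE(cond)) {
    halopol_error(sprintf("invalid parameter `%s`: %s", field, msg),
                  "halopol_validation_error", field = field)
  }
  invisible(TRUE)
}

# Run `expr` with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards so simulation calls do not perturb scripts.
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
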