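`%||%` <- function(a, b) if (is.null(a)) b else a

stop_trop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "trop_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

#' @keywords internal
assert_that <- function(ok, class, fmt, ...) {
  if (!isTRUE(ok)) stop_trop(class, fmt, ...)
  invisible(TRUE)
}

is_consecutive <- function(years) {
  length(years) >= 1 && all(diff(as.integer(years)) == 1L)
}

pad_fips <- function(x) {
  x <- trimws(as.character(x))
  num <- grepl("^[0-9]+$", x)
  x[num] <- sprintf("%05d", as.integer(x[num]))
  x
}

# seeded RNG scope: evaluates expr with a local L'Ecuyer-independent stream
# derived from (seed, label) without disturbing the caller's RNG state
with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  offset <- sum(utf8ToInt(label)) %% 10000L
  set.seed((as.integer(seed) %% 100000L) * 10000L + offset)
  force(expr)
}
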