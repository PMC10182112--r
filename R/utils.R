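`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible child seed from a master seed and a key
#'
#' Stable hashing of an arbitrary key (e.g. `c(split, dl, run)`) combined with
#' the master seed, so that adding experimental conditions never perturbs the
#' seeds of existing ones. The result always lies in `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param ... key components; coerced to character and joined.
#' @return A single integer seed.
#' @export
#' @examples
#' child_seed(1, "split", 2, "dl", 0.8)
child_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  key <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                      character(1)), collapse = "/")
  m <- 2147483629
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 131 + b) %% m
  as.integer((abs(master) %% m * 48271 + h) %% m + 1)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# stop() with sprintf formatting, never truncating the call stack info
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    abort("%s is missing required column(s): %s", what,
          paste(missing, collapse = ", "))
  invisible(df)
}
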