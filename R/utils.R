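#' Derive a reproducible sub-stream seed from a root seed
#'
#' All randomness in a pipeline run flows from one root seed; each stage
#' draws from its own named sub-stream so that adding a stage never
#' perturbs the draws of another.
#'
#' @param seed integer root seed.
#' @param label character stage label.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131)
  as.integer((abs(seed) * 48271 + h) %% (2^31 - 1))
}

assert_finite_coords <- function(x, y, what = "coordinates") {
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop(sprintf("non-finite %s", what), call. = FALSE)
  }
  invisible(TRUE)
}

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# uniform draw in a disc of radius r centred on (cx, cy); vectorised
runif_disc <- function(n, cx, cy, r) {
  rad <- r * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  list(x = cx + rad * cos(th), y = cy + rad * sin(th))
}
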