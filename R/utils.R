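# internal helpers

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# log-log interpolation on a tabulated positive function; errors outside range
loglog_interp <- function(x, xg, yg) {
  if (any(x < min(xg) | x > max(xg)))
    stop("energy ", paste(x[x < min(xg) | x > max(xg)], collapse = ", "),
         " keV outside tabulated range [", min(xg), ", ", max(xg), "] keV",
         call. = FALSE)
  exp(approx(log(xg), log(yg), xout = log(x), rule = 1)$y)
}

#' @importFrom stats approx
NULL
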