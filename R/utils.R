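# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Typed validation error so callers can distinguish bad input from bugs.
stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("episnet_validation_error", "error", "condition")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream. seed = NULL means "use the current stream as-is".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# x * log(d / x) with the 0 * log(1/0) := 0 convention, elementwise; x, d
# may be matrices. Used for entropy sums over sparse count tables.
xlog_ratio <- function(x, d, base) {
  out <- x
  out[] <- 0
  pos <- x > 0
  out[pos] <- x[pos] * log(d[pos] / x[pos], base = base)
  out
}

# Provenance header written at the top of every artifact file.
provenance_header <- function(seed = NULL, extra = NULL) {
  bits <- c(sprintf("episnet %s",
                    as.character(utils::packageVersion("episnet"))),
            if (!is.null(seed)) sprintf("seed=%s", seed),
            extra)
  paste0("# ", bits)
}
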