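# internal helpers shared across the package

# signal a classed error so callers can test for specific failure modes
# (condition classes look like "crowdfba_no_biomass", "crowdfba_duplicate_id")
mc_stop <- function(code, msg, call. = FALSE) {
  cond <- structure(
    class = c(paste0("crowdfba_", gsub("-", "_", code)), "crowdfba_error",
              "error", "condition"),
    list(message = sprintf("[%s] %s", code, msg), call = sys.call(-1))
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code with a private RNG stream derived from (seed, stream name),
# restoring the caller's .Random.seed afterwards. The derived seed stays
# within 32-bit integer range.
with_stream <- function(seed, name, code) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  derived <- (abs(as.numeric(seed)) * 69091 + h * 131) %% 2147483629
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(derived))
  force(code)
}

# linear interpolation onto a new grid; refuses to extrapolate
interp_series <- function(x, y, xout) {
  if (min(xout) < min(x) - 1e-12 || max(xout) > max(x) + 1e-12)
    mc_stop("no-extrapolation",
            "requested time points fall outside the observed range")
  stats::approx(x, y, xout = xout, rule = 1)$y
}
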