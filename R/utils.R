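#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG state seeded by `seed`, restoring the caller's
# .Random.seed afterwards. All stochastic entry points route through this so
# the global RNG stream is never perturbed.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv())
    else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

abort_msi <- function(..., class = "msidiscrim_error") {
  stop(errorCondition(paste0(...), class = c(class, "error", "condition"),
                      call = sys.call(-1)))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_msi(name, " must be a single finite number")
  if (strict_lower && x <= lower) abort_msi(name, " must be > ", lower)
  if (!strict_lower && x < lower) abort_msi(name, " must be >= ", lower)
  if (strict_upper && x >= upper) abort_msi(name, " must be < ", upper)
  if (!strict_upper && x > upper) abort_msi(name, " must be <= ", upper)
  invisible(x)
}

# formatted with enough digits for exact double round-trip
fmt_full <- function(x) sprintf("%.17g", x)

msi_log <- function(...) {
  if (isTRUE(getOption("msidiscrim.verbose", FALSE)))
    message("[msidiscrim] ", ...)
  invisible(NULL)
}
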