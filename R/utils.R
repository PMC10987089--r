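# Internal helpers shared across modules.

# Classed error so callers/tests can distinguish failure modes.
aff_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("affbound_", class), "affbound_error")))
}

aff_warn <- function(msg, class = "warning") {
  warning(warningCondition(msg, class = c(paste0("affbound_", class), "affbound_warning")))
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Scalar checks used by the config constructors.
is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_scalar_in <- function(x, name, lo = -Inf, hi = Inf,
                            open_lo = FALSE, open_hi = FALSE) {
  ok <- is_scalar_num(x) &&
    (if (open_lo) x > lo else x >= lo) &&
    (if (open_hi) x < hi else x <= hi)
  if (!ok)
    aff_stop(sprintf("`%s` must be a finite scalar in %s%s, %s%s (got %s)",
                     name, if (open_lo) "(" else "[", format(lo), format(hi),
                     if (open_hi) ")" else "]",
                     paste(format(x), collapse = ", ")),
             "value_error")
  invisible(x)
}

# Pearson correlations between consecutive rows of a matrix.
# Returns NA where a row is constant (zero variance).
row_cor_adjacent <- function(m) {
  stopifnot(is.matrix(m), nrow(m) >= 2L)
  ctr <- m - rowMeans(m)
  ss <- sqrt(rowSums(ctr * ctr))
  num <- rowSums(ctr[-nrow(m), , drop = FALSE] * ctr[-1L, , drop = FALSE])
  den <- ss[-length(ss)] * ss[-1L]
  r <- ifelse(den > 0, num / den, NA_real_)
  unname(r)
}
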