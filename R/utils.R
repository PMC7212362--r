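# Internal helpers shared across modules.

# Abort with a condition class the CLI maps to exit code 2.
mda_abort <- function(message, class = "heatmda_validation_error", ...) {
  abort(message, class = c(class, "heatmda_error"), ...)
}

mda_warn <- function(message, class = "heatmda_warning") {
  warn(message, class = class)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

# Stable check that two label vectors agree exactly (order included).
check_same_labels <- function(a, b, what) {
  if (length(a) != length(b) || !all(a == b)) {
    mda_abort(sprintf("label mismatch: %s", what), class = "heatmda_label_error")
  }
  invisible(TRUE)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_in_range <- function(x, name, lo = -Inf, hi = Inf,
                           lo_open = FALSE, hi_open = FALSE) {
  if (!is_scalar_number(x)) {
    mda_abort(sprintf("`%s` must be a single finite number", name),
              class = "heatmda_config_error")
  }
  ok <- (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    mda_abort(
      sprintf("`%s` = %g is outside its allowed range %s%g, %g%s", name, x,
              if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]"),
      class = "heatmda_config_error"
    )
  }
  invisible(TRUE)
}

# Format numbers for TSV output so that write -> read -> write is a fixed point
# at 12 significant digits.
format_score <- function(x) {
  formatC(x, digits = 12, format = "g")
}
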