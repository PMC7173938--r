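# Shared validation and formatting helpers (internal).

# Validate a single positive integer-valued scalar.
check_count <- function(x, name, min = 1) {
  if (length(x) != 1 || !is.numeric(x) || !is.finite(x) || x != as.integer(x)) {
    stop(sprintf("`%s` must be a single finite integer", name), call. = FALSE)
  }
  if (x < min) {
    stop(sprintf("`%s` must be at least %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

# Validate hit counts against a design; returns an integer vector.
check_hits <- function(hits, design, name = "hits") {
  if (length(hits) < 1 || !is.numeric(hits) || anyNA(hits) ||
      any(hits != as.integer(hits))) {
    stop(sprintf("`%s` must be integer-valued and non-missing", name),
         call. = FALSE)
  }
  if (any(hits < 0) || any(hits > design$trials)) {
    stop(sprintf("`%s` must lie between 0 and trials = %d", name,
                 design$trials), call. = FALSE)
  }
  as.integer(hits)
}

# Round half away from zero, the convention used when printing threshold
# tables (base round() rounds halves to even).
round_half_up <- function(x, digits = 3) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

# Tolerance for comparing a pmf value against the significance criterion:
# "chance-consistent" means P(k) > criterion by more than this, so that
# floating-point noise can never flip a table cell.
PMF_TOL <- 1e-12

verbose_message <- function(...) {
  if (isTRUE(getOption("chancelevel.verbose", FALSE))) {
    message(...)
  }
}
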