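# Shared internal helpers.

# Round half away from zero (paper-style table rounding), unlike base
# round()'s banker's rounding.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Instrument precision used before band comparisons: temperature is read to
# 0.1 degC, every other numeric parameter to the nearest integer.
snap_to_precision <- function(value, parameter) {
  if (parameter == "temperature") round(value * 10) / 10 else round(value)
}

avpu_levels <- c("Alert", "Voice", "Pain", "Unconscious")
risk_levels <- c("low", "moderate", "high")

as_risk_level <- function(x) {
  factor(x, levels = risk_levels, ordered = TRUE)
}

# Pairwise max of ordered risk levels, NA treated as low.
max_risk <- function(...) {
  args <- list(...)
  codes <- lapply(args, function(x) {
    i <- as.integer(as_risk_level(as.character(x)))
    i[is.na(i)] <- 1L
    i
  })
  as_risk_level(risk_levels[do.call(pmax, codes)])
}

stop_meowsri <- function(msg, class) {
  abort(msg, class = c(class, "meowsri_error"))
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop_meowsri(sprintf("`%s` must be a single probability in [0, 1].", name),
                 "meowsri_validation_error")
  }
  invisible(x)
}
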