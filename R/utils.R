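# Internal helpers shared across modules.

# Half-up rounding (round() in R rounds half to even; printed tables use
# conventional half-up at a fixed number of decimals).
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Lower edge of a "(a, b]" / "[a, b]" range label, NA for non-range labels.
# Used to order binned labels in cohort filters.
parse_bin_lower <- function(labels) {
  m <- stringr::str_match(as.character(labels), "^[\\(\\[]\\s*(-?[0-9.eE+-]+)\\s*,")
  suppressWarnings(as.numeric(m[, 2]))
}

is_scalar_chr <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

stop_clinexpo <- function(msg, class) {
  rlang::abort(msg, class = c(class, "clinexpo_error"))
}

# Tibble constructor without per-call validation; hot paths build one tibble
# per patient, where tibble() overhead dominates runtime.
fast_tbl <- function(cols) {
  n <- if (length(cols)) length(cols[[1]]) else 0L
  structure(cols, names = names(cols),
            class = c("tbl_df", "tbl", "data.frame"),
            row.names = .set_row_names(n))
}

# Row subset of a data frame by integer index, column-wise (fast).
fast_slice <- function(df, i) {
  fast_tbl(lapply(df, `[`, i))
}

# ISO year extraction from "YYYY", "YYYY-MM-DD" or "YYYY-MM-DDThh:mm:ss".
iso_year <- function(x) {
  suppressWarnings(as.integer(substr(as.character(x), 1, 4)))
}
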