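#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map_lgl map_chr imap
NULL

# round half away from zero, matching how published tables display values
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# log(exp(a) + b) computed without overflow; b >= 0 on the natural scale
log_add_exp <- function(a, log_b) {
  if (is.infinite(log_b) && log_b < 0) return(a)
  m <- max(a, log_b)
  m + log1p(exp(min(a, log_b) - m))
}

# full-precision numeric -> text round trip (classifier serialization)
num_to_chr <- function(x) formatC(x, digits = 17, format = "g")

`%||%` <- function(a, b) if (is.null(a)) b else a
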