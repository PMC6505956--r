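#' Round half away from zero
#'
#' Commercial rounding used when reproducing printed report tables:
#' `round_half_out(0.5) == 1`, `round_half_out(-0.5) == -1`, unlike base
#' [round()] which rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector of the same length as `x`.
#' @export
#' @examples
#' round_half_out(2.675, 2)
#' round_half_out(-0.0025, 3)
round_half_out <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stopifnot-style check with a readable message
abort_if <- function(cond, msg) {
  if (isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(NULL)
}

# columns that must be present in a pixel table
require_columns <- function(data, cols, what = "pixel table") {
  missing <- setdiff(cols, names(data))
  abort_if(
    length(missing) > 0,
    paste0("missing required ", what, " column(s): ", paste(missing, collapse = ", "))
  )
  invisible(NULL)
}
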