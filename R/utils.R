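#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for every percentage the package
#' reports. Base [round()] rounds half to even, which would turn e.g.
#' 0.125 into 0.12; report tables in this field round 0.125 up to 0.13.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(0.125, -0.125, 51.8689), 2)
round_half_up <- function(x, digits = 2) {
  stopifnot(is.numeric(x), length(digits) == 1, digits >= 0)
  scale <- 10^digits
  # tiny guard against decimal values sitting just under .5 in binary
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

abort_fmt <- function(..., class) {
  rlang::abort(sprintf(...), class = class)
}

inform_verbose <- function(...) {
  if (isTRUE(getOption("semarkr.verbose", FALSE))) {
    rlang::inform(sprintf(...))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
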