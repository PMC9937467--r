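# Small shared helpers.

#' Round half away from zero
#'
#' Commercial rounding: ties move away from zero (`round()` in base R rounds
#' ties to even, which does not match how detection tables are usually
#' presented).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' round_half_away(c(0.5, -0.5, 2.5))
#' @export
round_half_away <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Round half up (used for integer-percent presentation)
#' @param x numeric vector.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x) {
  floor(x + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ft_stop <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "facetouch_error")))
}

stop_format <- function(...) ft_stop(..., class = "facetouch_format_error")
stop_param  <- function(...) ft_stop(..., class = "facetouch_parameter_error")
stop_label  <- function(...) ft_stop(..., class = "facetouch_label_error")

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}
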