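# Fixed-point arithmetic emulation for the hardware datapath.
#
# The controller core runs on quantized arithmetic: bound-receptor fractions
# r(t) are stored as unsigned 0.18 fixed-point words, kinetic constants as
# unsigned 14-bit fractions, and the membrane displacement in a signed format
# with integer headroom. Raw words are carried as R doubles holding exact
# integers; all products stay far below 2^53 so every operation here is exact
# integer arithmetic.

#' Fixed-point format descriptor
#'
#' Describes a binary fixed-point format with `integer_bits` bits left of the
#' binary point, `fraction_bits` bits right of it, and an optional sign bit.
#' The resolution is `2^-fraction_bits`; an unsigned format represents
#' `[0, 2^integer_bits - 2^-fraction_bits]`, a signed (two's-complement)
#' format `[-2^integer_bits, 2^integer_bits - 2^-fraction_bits]`.
#'
#' @param integer_bits Non-negative integer count of integer bits.
#' @param fraction_bits Non-negative integer count of fraction bits.
#' @param signed Logical; add a two's-complement sign bit.
#' @return An object of class `fixed_format` with fields `integer_bits`,
#'   `fraction_bits`, `signed`, `resolution`, `raw_min`, `raw_max`,
#'   `min`, `max`.
#' @examples
#' fixed_format(0, 18)            # the r(t) storage format, U0.18
#' parse_fixed_format("S10.18")   # signed membrane format
#' @export
fixed_format <- function(integer_bits, fraction_bits, signed = FALSE) {
  stopifnot(
    length(integer_bits) == 1, length(fraction_bits) == 1,
    integer_bits >= 0, fraction_bits >= 0,
    integer_bits == floor(integer_bits), fraction_bits == floor(fraction_bits)
  )
  total <- integer_bits + fraction_bits + as.integer(signed)
  if (total <= 0) stop("fixed_format: total width must be positive")
  raw_max <- 2^(integer_bits + fraction_bits) - 1
  raw_min <- if (signed) -2^(integer_bits + fraction_bits) else 0
  structure(
    list(
      integer_bits = as.integer(integer_bits),
      fraction_bits = as.integer(fraction_bits),
      signed = isTRUE(signed),
      resolution = 2^-fraction_bits,
      raw_min = raw_min,
      raw_max = raw_max,
      min = raw_min * 2^-fraction_bits,
      max = raw_max * 2^-fraction_bits
    ),
    class = "fixed_format"
  )
}

#' @export
print.fixed_format <- function(x, ...) {
  cat(sprintf(
    "<fixed_format %s: range [%g, %g], resolution 2^-%d>\n",
    format_fixed_format(x), x$min, x$max, x$fraction_bits
  ))
  invisible(x)
}

#' Parse a fixed-point format string
#'
#' Formats are named `"U<int>.<frac>"` (unsigned) or `"S<int>.<frac>"`
#' (signed), e.g. `"U0.18"` for the receptor-fraction storage format or
#' `"U0.14"` for kinetic constants.
#'
#' @param s Format string.
#' @return A [fixed_format()] object.
#' @export
parse_fixed_format <- function(s) {
  stopifnot(is.character(s), length(s) == 1)
  m <- regmatches(s, regexec("^([USus])([0-9]+)\\.([0-9]+)$", s))[[1]]
  if (length(m) != 4) {
    stop("cannot parse fixed-point format string: ", s,
         " (expected e.g. \"U0.18\" or \"S10.18\")")
  }
  fixed_format(
    integer_bits = as.integer(m[3]),
    fraction_bits = as.integer(m[4]),
    signed = toupper(m[2]) == "S"
  )
}

#' @rdname parse_fixed_format
#' @param fmt A `fixed_format` object.
#' @export
format_fixed_format <- function(fmt) {
  sprintf("%s%d.%d", if (fmt$signed) "S" else "U",
          fmt$integer_bits, fmt$fraction_bits)
}

as_fixed_format <- function(fmt) {
  if (inherits(fmt, "fixed_format")) return(fmt)
  if (is.character(fmt)) return(parse_fixed_format(fmt))
  stop("expected a fixed_format or a format string")
}

#' Quantize a real value to a fixed-point format
#'
#' Converts real numbers to raw fixed-point words. `truncate` floors the
#' scaled value toward negative infinity (the default hardware behaviour of a
#' dropped-bit datapath), `round` rounds to nearest (half away from zero).
#' Out-of-range values always saturate to the nearest representable bound;
#' `mode = "saturate"` is truncation with (always-on) saturation, provided so
#' that configs can name the intent explicitly.
#'
#' @param x Numeric vector of real values.
#' @param fmt A [fixed_format()] or format string.
#' @param mode One of `"truncate"`, `"round"`, `"saturate"`.
#' @return A list with `raw` (integer-valued numeric vector) and `fmt`;
#'   class `fixed_value`.
#' @examples
#' quantize(0.5, "U0.18")$raw    # 131072, exact
#' fixed_real(quantize(0.9375, "U0.14"))  # representable exactly
#' @export
quantize <- function(x, fmt, mode = c("truncate", "round", "saturate")) {
  mode <- match.arg(mode)
  fmt <- as_fixed_format(fmt)
  if (any(!is.finite(x))) stop("quantize: non-finite input")
  scaled <- x * 2^fmt$fraction_bits
  raw <- if (mode == "round") round(scaled) else floor(scaled)
  raw <- pmin(pmax(raw, fmt$raw_min), fmt$raw_max)
  fixed_value(raw, fmt)
}

#' Construct a fixed-point value from raw words
#'
#' @param raw Integer-valued numeric vector of raw words.
#' @param fmt A [fixed_format()] or format string.
#' @return A `fixed_value` object.
#' @export
fixed_value <- function(raw, fmt) {
  fmt <- as_fixed_format(fmt)
  if (any(raw != floor(raw))) stop("fixed_value: raw words must be integers")
  if (any(raw < fmt$raw_min | raw > fmt$raw_max)) {
    stop("fixed_value: raw word outside representable range of ",
         format_fixed_format(fmt))
  }
  structure(list(raw = raw, fmt = fmt), class = "fixed_value")
}

#' Real value of a fixed-point word
#'
#' @param q A `fixed_value`.
#' @return Numeric vector `raw * 2^-fraction_bits`.
#' @export
fixed_real <- function(q) {
  q$raw * 2^-q$fmt$fraction_bits
}

#' @export
print.fixed_value <- function(x, ...) {
  cat(sprintf("<fixed_value %s>\n", format_fixed_format(x$fmt)))
  print(fixed_real(x))
  invisible(x)
}

#' Fixed-point multiply with truncation to an output format
#'
#' Emulates the hardware multiplier: the exact product of the two raw words is
#' rescaled to the output format by dropping low bits (floor). With the
#' operand fraction widths f_a + f_b >= f_out this is exact integer
#' arithmetic; the result differs from the real product by less than one
#' output resolution step.
#'
#' @param a,b `fixed_value` objects (vectors broadcast like `*`).
#' @param out_fmt Output [fixed_format()] or string.
#' @return A `fixed_value` in `out_fmt`, saturated at the format bounds.
#' @export
fx_mul <- function(a, b, out_fmt) {
  out_fmt <- as_fixed_format(out_fmt)
  drop_bits <- a$fmt$fraction_bits + b$fmt$fraction_bits - out_fmt$fraction_bits
  if (drop_bits < 0) {
    stop("fx_mul: output format finer than the product; widen the operands")
  }
  prod_raw <- a$raw * b$raw
  raw <- floor(prod_raw / 2^drop_bits)
  raw <- pmin(pmax(raw, out_fmt$raw_min), out_fmt$raw_max)
  fixed_value(raw, out_fmt)
}

#' Leak by arithmetic right shift
#'
#' The membrane leak multiplies by `2^-shift` using a right shift of the raw
#' word instead of a multiplier. The shift is arithmetic: flooring on the raw
#' integer, so negative words round toward negative infinity
#' (`-9 >> 3 == -2`), matching a two's-complement shifter.
#'
#' @param v A `fixed_value`.
#' @param shift Non-negative integer shift count.
#' @return A `fixed_value` in the same format.
#' @export
shift_leak <- function(v, shift) {
  stopifnot(length(shift) == 1, shift >= 0, shift == floor(shift))
  fixed_value(floor(v$raw / 2^shift), v$fmt)
}

# Raw-domain helpers used by the hot simulation loop (no object wrapping).

fx_raw_saturate <- function(raw, fmt) {
  pmin(pmax(raw, fmt$raw_min), fmt$raw_max)
}

fx_raw_mul <- function(raw_a, frac_a, raw_b, frac_b, fmt_out) {
  fx_raw_saturate(
    floor(raw_a * raw_b / 2^(frac_a + frac_b - fmt_out$fraction_bits)),
    fmt_out
  )
}
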