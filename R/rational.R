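#' Exact rational numbers
#'
#' Small vectorised exact-fraction class used for FMEA consensus scores and
#' risk priority numbers. Averaging three integer rater scores gives thirds
#' (16/3, 13/3, ...), and the product O x S x D must be carried exactly:
#' multiplying the two-decimal display values instead (4 x 5.33 x 4.33 =
#' 92.32) does not reproduce the exact product 832/9 = 92.44.
#'
#' Numerators and denominators are stored as doubles holding integer values;
#' FMEA scores are bounded by 10 and denominators by the rater count, so all
#' intermediates stay far below 2^53 and arithmetic is exact.
#'
#' @param num integer numerator(s).
#' @param den integer denominator(s), non-zero. Recycled against `num`.
#' @return An object of class `rational`.
#' @examples
#' r <- rational(16, 3)
#' as.numeric(r * rational(13, 3) * 4)   # 92.444...
#' format(rational(832, 9))              # "92.44"
#' @export
rational <- function(num, den = 1L) {
  if (any(!is.finite(num)) || any(!is.finite(den))) {
    stop("rational parts must be finite", call. = FALSE)
  }
  if (any(num != round(num)) || any(den != round(den))) {
    stop("rational parts must be integer-valued", call. = FALSE)
  }
  if (any(den == 0)) stop("zero denominator", call. = FALSE)
  n <- length(num)
  d <- length(den)
  len <- if (n == 0 || d == 0) 0L else max(n, d)
  if (len == 0L) {
    return(structure(list(num = numeric(0), den = numeric(0)),
                     class = "rational"))
  }
  num <- rep_len(as.double(num), len)
  den <- rep_len(as.double(den), len)
  # normalise sign into the numerator, reduce by gcd
  num <- ifelse(den < 0, -num, num)
  den <- abs(den)
  g <- mapply(gcd2, abs(num), den)
  g[g == 0] <- 1
  structure(list(num = num / g, den = den / g), class = "rational")
}

gcd2 <- function(a, b) {
  while (b > 0) {
    t <- a %% b
    a <- b
    b <- t
  }
  a
}

is_rational <- function(x) inherits(x, "rational")

as_rational <- function(x) {
  if (is_rational(x)) return(x)
  if (is.numeric(x)) {
    if (any(x != round(x))) {
      stop("cannot promote non-integer numeric to rational exactly; ",
           "use rational(num, den)", call. = FALSE)
    }
    return(rational(x))
  }
  stop("cannot coerce to rational", call. = FALSE)
}

#' @export
as.double.rational <- function(x, ...) x$num / x$den

#' @export
length.rational <- function(x) length(x$num)

#' @export
`[.rational` <- function(x, i) rational(x$num[i], x$den[i])

#' @export
c.rational <- function(...) {
  parts <- lapply(list(...), as_rational)
  rational(unlist(lapply(parts, `[[`, "num")),
           unlist(lapply(parts, `[[`, "den")))
}

#' @export
Ops.rational <- function(e1, e2) {
  if (nargs() == 1L) {
    if (.Generic == "-") return(rational(-e1$num, e1$den))
    if (.Generic == "+") return(e1)
    stop("unary ", .Generic, " not defined for rational", call. = FALSE)
  }
  a <- as_rational(e1)
  b <- as_rational(e2)
  switch(.Generic,
    "+" = rational(a$num * b$den + b$num * a$den, a$den * b$den),
    "-" = rational(a$num * b$den - b$num * a$den, a$den * b$den),
    "*" = rational(a$num * b$num, a$den * b$den),
    "/" = rational(a$num * b$den, a$den * b$num),
    "==" = a$num * b$den == b$num * a$den,
    "!=" = a$num * b$den != b$num * a$den,
    "<"  = a$num * b$den <  b$num * a$den,
    "<=" = a$num * b$den <= b$num * a$den,
    ">"  = a$num * b$den >  b$num * a$den,
    ">=" = a$num * b$den >= b$num * a$den,
    stop(.Generic, " not defined for rational", call. = FALSE)
  )
}

#' Exact mean of a rational vector
#' @param x a `rational` vector.
#' @return A length-1 `rational`.
#' @export
mean.rational <- function(x, ...) {
  out <- rational(0)
  for (i in seq_along(x)) out <- out + x[i]
  out / length(x)
}

#' Round a rational to decimals, half away from zero
#'
#' Exact integer rounding of `num/den` to `digits` decimals with ties going
#' away from zero, matching how published score tables round (832/9 prints as
#' 92.44, 1088/27 as 40.30). Ordinary [round()] on doubles rounds half to
#' even and works on an inexact binary value, so it is not used for display.
#'
#' @param x a `rational` vector (or numeric, rounded via the same rule).
#' @param digits number of decimal places.
#' @return numeric vector.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  if (is_rational(x)) {
    s <- sign(x$num)
    n <- abs(x$num)
    # floor((p*n)/den + 1/2) in exact integer arithmetic
    q <- (2 * p * n + x$den) %/% (2 * x$den)
    return(s * q / p)
  }
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
format.rational <- function(x, digits = 2, ...) {
  formatC(round_half_away(x, digits), format = "f", digits = digits)
}

#' @export
print.rational <- function(x, ...) {
  shown <- ifelse(x$den == 1, as.character(x$num),
                  paste0(x$num, "/", x$den))
  cat("<rational> ", paste(shown, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.rational <- function(x, ...) {
  ifelse(x$den == 1, as.character(x$num), paste0(x$num, "/", x$den))
}
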