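# Thin R wrappers over the C++ big-integer engine.  Big integers travel as
# decimal strings; they are exact at any size, and only become doubles at the
# reporting boundary (big_ratio).

big_add <- function(a, b) cpp_big_add(a, b)
big_sub <- function(a, b) cpp_big_sub(a, b)
big_mul <- function(a, b) cpp_big_mul(a, b)

# -1, 0, 1 as a < b, a == b, a > b
big_cmp <- function(a, b) cpp_big_cmp(a, b)
big_lt <- function(a, b) cpp_big_cmp(a, b) < 0L

big_pow <- function(base, exp) cpp_big_pow(base, exp)

# exact-rational quotient num/den as a double (accurate to ~1e-18 relative)
big_ratio <- function(num, den) cpp_big_ratio(num, den)

big_str <- function(x) {
  stopifnot(is.numeric(x), x == round(x), abs(x) < 2^53)
  sprintf("%.0f", x)
}

# A significance level as an exact rational, read at 12 decimal places, so
# strict p < alpha decisions are made in integer arithmetic.
alpha_rational <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single number in (0, 1)", call. = FALSE)
  }
  list(num = sprintf("%.0f", round(alpha * 1e12)), den = "1000000000000")
}
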