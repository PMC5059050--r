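# Exact rational arithmetic on (numerator, denominator) pairs.
#
# Supply durations are tablets / (tablets per day); with half- or third-tablet
# regimens these are non-terminating binary fractions, and the tablet-
# conservation invariant of a supply schedule is stated exactly. Numerators
# and denominators stay tiny (days x small dose denominators), far below the
# 2^53 limit of exact double integers, so doubles are a safe carrier.

rat_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) {
    t <- a %% b
    a <- b
    b <- t
  }
  max(a, 1)
}

rat <- function(num, den = 1) {
  if (den == 0) abort("rational with zero denominator")
  if (den < 0) {
    num <- -num
    den <- -den
  }
  g <- rat_gcd(num, den)
  c(num / g, den / g)
}

rat_add <- function(x, y) rat(x[1] * y[2] + y[1] * x[2], x[2] * y[2])
rat_sub <- function(x, y) rat(x[1] * y[2] - y[1] * x[2], x[2] * y[2])
rat_mul <- function(x, y) rat(x[1] * y[1], x[2] * y[2])
rat_div <- function(x, y) {
  if (y[1] == 0) abort("rational division by zero")
  rat(x[1] * y[2], x[2] * y[1])
}

# sign of x - y, exactly
rat_cmp <- function(x, y) sign(x[1] * y[2] - y[1] * x[2])

rat_num <- function(x) x[1] / x[2]

# exact ceiling (x assumed reduced, den > 0)
rat_ceil <- function(x) {
  q <- floor(x[1] / x[2])
  if (q * x[2] == x[1]) q else q + 1
}
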