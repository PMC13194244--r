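# Minimal exact rational arithmetic on integer-valued doubles.
#
# Used only for the small-n exact oracles (shape enumeration and moment
# recursions at n <= ~12), where denominators stay far below 2^53. Every
# operation reduces by the gcd and errors on overflow, so results are exact
# or the computation refuses — never silently approximate.

.rat_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { r <- a %% b; a <- b; b <- r }
  a
}

.rat_check <- function(x) {
  if (abs(x$num) >= 2^53 || x$den >= 2^53)
    stop("exact rational arithmetic overflowed 2^53; reduce n")
  x
}

rat <- function(num, den = 1) {
  if (den == 0) stop("zero denominator")
  if (den < 0) { num <- -num; den <- -den }
  g <- .rat_gcd(num, den)
  if (g > 0) { num <- num / g; den <- den / g }
  .rat_check(list(num = num, den = den))
}

# lcm-based addition and cross-reduced multiplication keep the intermediate
# products as small as the reduced result allows
rat_add <- function(x, y) {
  g <- .rat_gcd(x$den, y$den)
  dy <- y$den / g
  rat(x$num * dy + y$num * (x$den / g), x$den * dy)
}
rat_sub <- function(x, y) rat_add(x, list(num = -y$num, den = y$den))
rat_mul <- function(x, y) {
  g1 <- max(.rat_gcd(x$num, y$den), 1)
  g2 <- max(.rat_gcd(y$num, x$den), 1)
  rat((x$num / g1) * (y$num / g2), (x$den / g2) * (y$den / g1))
}
rat_div <- function(x, y) {
  if (y$num == 0) stop("division by zero rational")
  rat_mul(x, list(num = y$den * sign(y$num), den = abs(y$num)))
}
rat_eq <- function(x, y) x$num == y$num && x$den == y$den
rat_num <- function(x) x$num / x$den

rat_sum <- function(xs) Reduce(rat_add, xs, rat(0))

# exact harmonic number h_n = sum_{k<=n} 1/k
rat_harmonic <- function(n) {
  h <- rat(0)
  if (n >= 1) for (k in seq_len(n)) h <- rat_add(h, rat(1, k))
  h
}
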