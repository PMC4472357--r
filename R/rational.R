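#' Exact rational numbers
#'
#' Segregation and cross frequencies in incompatibility models are small
#' rationals (1/16, 37/60, 1/120, ...) and the package's predictions must be
#' testable exactly, so all probability bookkeeping in the cross engine runs
#' on reduced numerator/denominator pairs rather than floating point.
#' Numerators and denominators are held in doubles, which represent integers
#' exactly up to 2^53; any operation whose result would leave that range
#' signals an error instead of silently losing exactness.
#'
#' `rat()` builds a vector of rationals; the usual arithmetic and comparison
#' operators, `sum()`, `as.numeric()`, `format()` and subsetting work on it.
#'
#' @param num integer-valued numerator(s).
#' @param den integer-valued denominator(s), recycled against `num`.
#' @return An object of class `"rat"`: a list with components `num` and
#'   `den`, always reduced, with positive denominators.
#' @examples
#' rat(1, 16) + rat(1, 8)
#' sum(rat(c(37, 15, 21, 9, 1), c(60, 120, 120, 120, 120)))
#' @export
rat <- function(num, den = 1) {
  n <- max(length(num), length(den))
  num <- rep_len(as.numeric(num), n)
  den <- rep_len(as.numeric(den), n)
  if (any(den == 0)) stop("rational with zero denominator")
  if (any(num != trunc(num)) || any(den != trunc(den)))
    stop("rational parts must be integer-valued")
  .rat_check(num, den)
  neg <- den < 0
  num[neg] <- -num[neg]
  den[neg] <- -den[neg]
  g <- .gcd(abs(num), den)
  g[g == 0] <- 1
  structure(list(num = num / g, den = den / g), class = "rat")
}

.RAT_MAX <- 2^53

.rat_check <- function(num, den) {
  if (any(abs(num) > .RAT_MAX) || any(abs(den) > .RAT_MAX))
    stop("exact rational arithmetic overflow (magnitude exceeds 2^53)")
  invisible(NULL)
}

# vectorised Euclid; inputs non-negative integer-valued doubles
.gcd <- function(a, b) {
  repeat {
    i <- which(b != 0)
    if (!length(i)) return(a)
    r <- a[i] %% b[i]
    a[i] <- b[i]
    b[i] <- r
  }
}

.as_rat <- function(x) {
  if (inherits(x, "rat")) return(x)
  if (!is.numeric(x) || any(x != trunc(x)))
    stop("cannot coerce non-integer numeric to exact rational")
  rat(x, 1)
}

.r_add <- function(x, y) {
  g <- .gcd(x$den, y$den)
  d2 <- y$den / g
  num <- x$num * d2 + y$num * (x$den / g)
  den <- x$den * d2
  .rat_check(num, den)
  rat(num, den)
}

.r_mul <- function(x, y) {
  g1 <- .gcd(abs(x$num), y$den)
  g1[g1 == 0] <- 1
  g2 <- .gcd(abs(y$num), x$den)
  g2[g2 == 0] <- 1
  num <- (x$num / g1) * (y$num / g2)
  den <- (x$den / g2) * (y$den / g1)
  .rat_check(num, den)
  rat(num, den)
}

.r_recycle <- function(x, y) {
  n <- max(length(x$num), length(y$num))
  list(x = rat(rep_len(x$num, n), rep_len(x$den, n)),
       y = rat(rep_len(y$num, n), rep_len(y$den, n)))
}

# sign of x - y by cross multiplication (exact within range)
.r_cmp <- function(x, y) {
  a <- x$num * y$den
  b <- y$num * x$den
  .rat_check(a, b)
  sign(a - b)
}

#' @export
Ops.rat <- function(e1, e2) {
  if (nargs() == 1L) {
    if (.Generic == "-") return(rat(-e1$num, e1$den))
    if (.Generic == "+") return(e1)
    stop(sprintf("unary '%s' not defined for rationals", .Generic))
  }
  e1 <- .as_rat(e1)
  e2 <- .as_rat(e2)
  r <- .r_recycle(e1, e2)
  e1 <- r$x
  e2 <- r$y
  switch(.Generic,
    "+" = .r_add(e1, e2),
    "-" = .r_add(e1, rat(-e2$num, e2$den)),
    "*" = .r_mul(e1, e2),
    "/" = {
      if (any(e2$num == 0)) stop("division of rational by zero")
      .r_mul(e1, rat(e2$den, e2$num))
    },
    "==" = e1$num == e2$num & e1$den == e2$den,
    "!=" = e1$num != e2$num | e1$den != e2$den,
    "<"  = .r_cmp(e1, e2) < 0,
    "<=" = .r_cmp(e1, e2) <= 0,
    ">"  = .r_cmp(e1, e2) > 0,
    ">=" = .r_cmp(e1, e2) >= 0,
    stop(sprintf("'%s' not defined for rationals", .Generic))
  )
}

#' @export
Summary.rat <- function(..., na.rm = FALSE) {
  x <- do.call(c, lapply(list(...), .as_rat))
  switch(.Generic,
    sum = {
      acc <- rat(0)
      for (i in seq_along(x$num)) acc <- .r_add(acc, rat(x$num[i], x$den[i]))
      acc
    },
    min = x[which.min(as.numeric(x))],
    max = x[which.max(as.numeric(x))],
    stop(sprintf("'%s' not defined for rationals", .Generic))
  )
}

#' @export
length.rat <- function(x) length(x$num)

#' @export
`[.rat` <- function(x, i) rat(x$num[i], x$den[i])

#' @export
c.rat <- function(...) {
  xs <- lapply(list(...), .as_rat)
  rat(unlist(lapply(xs, `[[`, "num")), unlist(lapply(xs, `[[`, "den")))
}

#' @export
as.numeric.rat <- function(x, ...) x$num / x$den

#' @export
as.double.rat <- function(x, ...) x$num / x$den

#' @export
format.rat <- function(x, ...) {
  ifelse(x$den == 1, format(x$num, scientific = FALSE),
         paste0(format(x$num, scientific = FALSE, trim = TRUE), "/",
                format(x$den, scientific = FALSE, trim = TRUE)))
}

#' @export
print.rat <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
rep.rat <- function(x, ...) rat(rep(x$num, ...), rep(x$den, ...))

#' Numerator and denominator of a rational vector
#'
#' @param x a [rat()] vector.
#' @return Numeric vector of (reduced) numerators or denominators.
#' @export
rat_num <- function(x) .as_rat(x)$num

#' @rdname rat_num
#' @export
rat_den <- function(x) .as_rat(x)$den
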