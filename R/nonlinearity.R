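#' Static nonlinearity block
#'
#' Memoryless nonlinear map used for the input and output blocks of a
#' Hammerstein-Wiener model. Three families:
#' * `piecewise_linear`: continuous interpolation through `(breakpoints,
#'   values)` node pairs, linearly extrapolated beyond the end segments;
#' * `polynomial`: `sum(coefficients[j] * x^(j-1))` (coefficient for x^0
#'   first);
#' * `identity`: f(x) = x, no parameters.
#'
#' @param family One of `"piecewise_linear"`, `"polynomial"`, `"identity"`.
#' @param breakpoints Strictly increasing numeric vector (>= 2 points) for
#'   the piecewise-linear family.
#' @param values Node values at the breakpoints (defaults to the breakpoints
#'   themselves, i.e. an identity-shaped start).
#' @param coefficients Polynomial coefficients, constant term first; the
#'   polynomial degree must be >= 1.
#' @return A `static_nl` object.
#' @export
static_nl <- function(family = c("piecewise_linear", "polynomial", "identity"),
                      breakpoints = NULL, values = NULL,
                      coefficients = NULL) {
  family <- match.arg(family)
  obj <- list(family = family)
  if (family == "piecewise_linear") {
    if (is.null(breakpoints) || length(breakpoints) < 2L)
      stop("static_nl: piecewise_linear needs >= 2 breakpoints")
    if (any(diff(breakpoints) <= 0))
      stop("static_nl: breakpoints must be strictly increasing")
    if (is.null(values)) values <- breakpoints
    if (length(values) != length(breakpoints))
      stop("static_nl: values and breakpoints must have equal length")
    obj$breakpoints <- as.numeric(breakpoints)
    obj$values <- as.numeric(values)
  } else if (family == "polynomial") {
    if (is.null(coefficients) || length(coefficients) < 2L)
      stop("static_nl: polynomial needs degree >= 1 (>= 2 coefficients)")
    obj$coefficients <- as.numeric(coefficients)
  }
  structure(obj, class = "static_nl")
}

#' Evaluate a static nonlinearity
#'
#' @param nl A `static_nl`.
#' @param x Numeric vector.
#' @return f(x), same length as `x`.
#' @export
eval_nl <- function(nl, x) {
  stopifnot(inherits(nl, "static_nl"))
  switch(nl$family,
    identity = x,
    polynomial = {
      y <- numeric(length(x))
      for (j in rev(seq_along(nl$coefficients)))
        y <- y * x + nl$coefficients[j]
      y
    },
    piecewise_linear = pwl_eval(nl$breakpoints, nl$values, x)
  )
}

# Piecewise-linear evaluation with linear extrapolation from the end segments
# (approx() would clamp, which flattens the map outside the training range
# and hurts identification on validation data).
pwl_eval <- function(bp, val, x) {
  nb <- length(bp)
  y <- stats::approx(bp, val, xout = x, rule = 2)$y
  lo <- x < bp[1]
  if (any(lo)) {
    s <- (val[2] - val[1]) / (bp[2] - bp[1])
    y[lo] <- val[1] + s * (x[lo] - bp[1])
  }
  hi <- x > bp[nb]
  if (any(hi)) {
    s <- (val[nb] - val[nb - 1]) / (bp[nb] - bp[nb - 1])
    y[hi] <- val[nb] + s * (x[hi] - bp[nb])
  }
  y
}

# Hat-function (first-order B-spline) basis over the breakpoints: column m is
# the weight of node m when the piecewise-linear map is evaluated at x, with
# linear extrapolation consistent with pwl_eval. Node-value fitting is then
# ordinary least squares on this basis.
pwl_basis <- function(bp, x) {
  nb <- length(bp)
  B <- matrix(0, length(x), nb)
  for (m in seq_len(nb)) {
    e <- numeric(nb); e[m] <- 1
    B[, m] <- pwl_eval(bp, e, x)
  }
  B
}

# Number of free parameters a nonlinearity contributes to theta.
nl_npar <- function(nl) {
  switch(nl$family,
    identity = 0L,
    polynomial = length(nl$coefficients),
    piecewise_linear = length(nl$values)
  )
}

nl_get_par <- function(nl) {
  switch(nl$family,
    identity = numeric(0),
    polynomial = nl$coefficients,
    piecewise_linear = nl$values
  )
}

nl_set_par <- function(nl, par) {
  switch(nl$family,
    identity = nl,
    polynomial = { nl$coefficients <- par; nl },
    piecewise_linear = { nl$values <- par; nl }
  )
}
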