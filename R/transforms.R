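#' Symbolic covariate transformations
#'
#' A `transform_spec` represents a single-covariate expression
#' \deqn{f(x) = a + b \cdot g(c x + d)}
#' where `g` is one of the unary bases `identity`, `inverse` (1/u), `exp`,
#' `log`, or `sqrt`. This is the expression family searched by
#' [search_transforms()] and the family in which the published heart-failure
#' risk transformations (an exponential of age and reciprocals of ejection
#' fraction and serum creatinine) are expressed.
#'
#' The family is redundant: for `inverse`, `log` and `sqrt` the inner scale
#' `c` can be absorbed into the outer constants, and for `exp` the inner
#' offset `d` can be absorbed into `b`. [canonicalize()] removes this
#' redundancy (`c` becomes a sign for `inverse`/`log`/`sqrt`; `d` becomes 0
#' for `exp` and `identity`) without changing the function.
#'
#' @param base One of `"identity"`, `"inverse"`, `"exp"`, `"log"`, `"sqrt"`.
#' @param a,b Outer intercept and slope.
#' @param c Inner scale (the growth rate for `exp`).
#' @param d Inner offset.
#' @return An object of class `transform_spec`.
#' @examples
#' ef <- transform_spec("inverse", a = -2.1, b = 1.6, c = 0.066, d = -0.89)
#' evaluate(ef, c(20, 40, 60))
#' predict_probability(ef, 38.1)
#' canonicalize(ef)
#' @export
transform_spec <- function(base = c("identity", "inverse", "exp", "log", "sqrt"),
                           a = 0, b = 1, c = 1, d = 0) {
  base <- match.arg(base)
  for (nm in c("a", "b", "c", "d")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_symcox(sprintf("transform parameter `%s` must be a single finite number", nm))
    }
  }
  if (base != "identity" && c == 0) {
    stop_symcox("inner scale `c` must be nonzero for non-identity bases")
  }
  structure(
    list(base = base, a = as.numeric(a), b = as.numeric(b),
         c = as.numeric(c), d = as.numeric(d)),
    class = "transform_spec"
  )
}

transform_bases <- function() c("identity", "inverse", "exp", "log", "sqrt")

is_transform_spec <- function(x) inherits(x, "transform_spec")

#' Canonicalize a transformation
#'
#' Absorbs the redundant inner parameters: `identity` becomes `a + b*x`;
#' for `inverse`, `log` and `sqrt` the inner scale is folded into the outer
#' constants, leaving a sign `c` in `{-1, +1}`; for `exp` the inner offset
#' is folded into `b`, leaving the growth rate `c`. The returned spec is the
#' same function of `x` (up to floating-point rounding in the folded
#' constants).
#'
#' @param spec A [transform_spec()].
#' @return A canonical `transform_spec`.
#' @export
canonicalize <- function(spec) {
  stopifnot(is_transform_spec(spec))
  with(spec, switch(base,
    identity = transform_spec("identity", a = a + b * d, b = b * c),
    inverse  = transform_spec("inverse", a = a, b = b / abs(c),
                              c = sign(c), d = d / abs(c)),
    log      = transform_spec("log", a = a + b * log(abs(c)), b = b,
                              c = sign(c), d = d / abs(c)),
    sqrt     = transform_spec("sqrt", a = a, b = b * sqrt(abs(c)),
                              c = sign(c), d = d / abs(c)),
    exp      = transform_spec("exp", a = a, b = b * exp(d), c = c, d = 0)
  ))
}

transform_inner <- function(spec, x) spec$c * x + spec$d

check_transform_domain <- function(spec, x, what = "x") {
  if (!is.numeric(x)) stop_symcox("`x` must be numeric")
  if (anyNA(x) || any(!is.finite(x))) {
    stop_symcox("`x` contains missing or non-finite values")
  }
  u <- transform_inner(spec, x)
  bad <- switch(spec$base,
    identity = , exp = rep(FALSE, length(u)),
    inverse = u == 0,
    log = u <= 0,
    sqrt = u < 0
  )
  if (any(bad)) {
    i <- which(bad)[1L]
    stop_symcox(sprintf(
      "transformation %s is undefined at %s = %g (inner argument %g)",
      format(spec), what, x[i], u[i]
    ), class = "symcox_error_domain")
  }
  invisible(u)
}

#' Evaluate a transformation
#'
#' Computes `f(x) = a + b * g(c*x + d)` elementwise.
#'
#' @param spec A [transform_spec()].
#' @param x Numeric vector. Every value must lie in the domain of the base
#'   function; an out-of-domain value raises an error naming it.
#' @return Numeric vector of the same length as `x`.
#' @export
evaluate <- function(spec, x) {
  stopifnot(is_transform_spec(spec))
  u <- check_transform_domain(spec, x)
  g <- switch(spec$base,
    identity = u,
    inverse = 1 / u,
    exp = exp(u),
    log = log(u),
    sqrt = sqrt(u)
  )
  spec$a + spec$b * g
}

#' Logistic-wrapped death probability of a transformation
#'
#' Computes `1 / (1 + exp(-f(x)))`, the probability model under which
#' transformations are fitted and ranked. Output is strictly inside (0, 1).
#'
#' @inheritParams evaluate
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_probability <- function(spec, x) {
  p <- plogis(evaluate(spec, x))
  # keep strictly inside (0,1) so log-loss stays finite
  eps <- .Machine$double.xmin
  pmin(pmax(p, eps), 1 - .Machine$double.eps)
}

num_token <- function(v, digits = 17) {
  sprintf(paste0("%.", digits, "g"), v)
}

#' Serialize a transformation as a mathematical string
#'
#' The string is valid R syntax and round-trips exactly through
#' [parse_transform()] when `digits = 17`. For the `identity` base only the
#' canonical form (`c = 1`, `d = 0`) round-trips field-for-field; a
#' non-canonical identity parses back to the equivalent canonical spec.
#'
#' @param spec A [transform_spec()].
#' @param var Variable name to print, default `"x"`.
#' @param digits Significant digits for the constants; 17 preserves doubles
#'   exactly.
#' @return A single string such as `"-2.1 + 1.6/(0.066*x + -0.89)"`.
#' @export
format_transform <- function(spec, var = "x", digits = 17) {
  stopifnot(is_transform_spec(spec))
  tok <- function(v) num_token(v, digits)
  inner <- if (spec$c == 1) var else sprintf("%s*%s", tok(spec$c), var)
  if (spec$d != 0) inner <- sprintf("%s + %s", inner, tok(spec$d))
  core <- switch(spec$base,
    identity = if (spec$c == 1 && spec$d == 0) inner else sprintf("(%s)", inner),
    inverse = sprintf("1/(%s)", inner),
    exp = sprintf("exp(%s)", inner),
    log = sprintf("log(%s)", inner),
    sqrt = sprintf("sqrt(%s)", inner)
  )
  out <- if (spec$b == 1) core
         else if (spec$base == "inverse") sprintf("%s/(%s)", tok(spec$b), inner)
         else sprintf("%s*%s", tok(spec$b), core)
  if (spec$a != 0 || spec$b == 0) out <- sprintf("%s + %s", tok(spec$a), out)
  if (spec$b == 0) out <- tok(spec$a)
  out
}

#' @export
format.transform_spec <- function(x, var = "x", digits = 4, ...) {
  format_transform(x, var = var, digits = digits)
}

#' @export
print.transform_spec <- function(x, ...) {
  cat("<transform_spec> f(x) =", format(x), "\n")
  invisible(x)
}

#' @export
as.character.transform_spec <- function(x, ...) format_transform(x)

# --- parsing -----------------------------------------------------------------

# Extract (c, d) from a linear expression in `var`, walking the AST so that
# literal constants are recovered exactly as parsed.
lin_coefs <- function(e, var) {
  if (is.numeric(e)) return(c(c = 0, d = as.numeric(e)))
  if (is.symbol(e)) {
    if (identical(as.character(e), var)) return(c(c = 1, d = 0))
    stop_symcox(sprintf("unknown symbol `%s` in transform string", as.character(e)))
  }
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (op == "(") return(lin_coefs(e[[2L]], var))
    if (op == "+" && length(e) == 3L) return(lin_coefs(e[[2L]], var) + lin_coefs(e[[3L]], var))
    if (op == "-" && length(e) == 3L) return(lin_coefs(e[[2L]], var) - lin_coefs(e[[3L]], var))
    if (op == "-" && length(e) == 2L) return(-lin_coefs(e[[2L]], var))
    if (op == "+" && length(e) == 2L) return(lin_coefs(e[[2L]], var))
    if (op == "*") {
      l <- lin_coefs(e[[2L]], var); r <- lin_coefs(e[[3L]], var)
      if (l[["c"]] == 0) return(l[["d"]] * r)
      if (r[["c"]] == 0) return(r[["d"]] * l)
      stop_symcox("inner expression is not linear in the covariate")
    }
    if (op == "/") {
      r <- lin_coefs(e[[3L]], var)
      if (r[["c"]] != 0) stop_symcox("inner expression is not linear in the covariate")
      return(lin_coefs(e[[2L]], var) / r[["d"]])
    }
  }
  stop_symcox("unsupported construct in transform string")
}

# classify one additive term: constant, or (sign-adjusted) b * base(inner)
classify_term <- function(e, var) {
  if (is.numeric(e)) return(list(kind = "const", value = as.numeric(e)))
  if (is.symbol(e)) {
    lc <- lin_coefs(e, var)
    return(list(kind = "g", base = "identity", b = 1, c = lc[["c"]], d = lc[["d"]]))
  }
  op <- as.character(e[[1L]])
  if (op == "(") return(classify_term(e[[2L]], var))
  if (op == "-" && length(e) == 2L) {
    t <- classify_term(e[[2L]], var)
    if (t$kind == "const") t$value <- -t$value else t$b <- -t$b
    return(t)
  }
  if (op %in% c("exp", "log", "sqrt")) {
    lc <- lin_coefs(e[[2L]], var)
    return(list(kind = "g", base = op, b = 1, c = lc[["c"]], d = lc[["d"]]))
  }
  if (op == "/") {
    num <- e[[2L]]; den <- e[[3L]]
    den_lc <- tryCatch(lin_coefs(den, var), error = function(e) NULL)
    if (!is.null(den_lc) && den_lc[["c"]] != 0) {
      # b / (c*x + d): the reciprocal base
      if (!is.numeric(bnum <- tryCatch(eval(num, baseenv()), error = function(e) NULL))) {
        stop_symcox("numerator of a reciprocal term must be a constant")
      }
      return(list(kind = "g", base = "inverse", b = as.numeric(bnum),
                  c = den_lc[["c"]], d = den_lc[["d"]]))
    }
    t <- classify_term(num, var)
    dv <- eval(den, baseenv())
    if (t$kind == "const") t$value <- t$value / dv else t$b <- t$b / dv
    return(t)
  }
  if (op == "*") {
    l <- e[[2L]]; r <- e[[3L]]
    lconst <- tryCatch(eval(l, baseenv()), error = function(e) NULL)
    rconst <- tryCatch(eval(r, baseenv()), error = function(e) NULL)
    if (is.numeric(lconst) && is.null(rconst)) {
      t <- classify_term(r, var); t$b <- t$b * lconst; return(t)
    }
    if (is.numeric(rconst) && is.null(lconst)) {
      t <- classify_term(l, var); t$b <- t$b * rconst; return(t)
    }
    if (is.numeric(lconst) && is.numeric(rconst)) {
      return(list(kind = "const", value = lconst * rconst))
    }
    stop_symcox("unsupported product in transform string")
  }
  # a bare linear term like x + 3 handled by caller through term splitting
  stop_symcox("unsupported construct in transform string")
}

split_terms <- function(e, sign = 1) {
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (op == "+" && length(e) == 3L) {
      return(c(split_terms(e[[2L]], sign), split_terms(e[[3L]], sign)))
    }
    if (op == "-" && length(e) == 3L) {
      return(c(split_terms(e[[2L]], sign), split_terms(e[[3L]], -sign)))
    }
  }
  list(list(expr = e, sign = sign))
}

#' Parse a transformation from a mathematical string
#'
#' Accepts the restricted grammar `a + b*g(c*x + d)` (any sign arrangement,
#' any term order, R syntax) with `g` one of the five bases, including the
#' pure reciprocal written as `b/(c*x + d)`. Constants written with 17
#' significant digits round-trip exactly.
#'
#' @param text A single string, e.g. `"-2.1 + 1.6/(0.066*x - 0.89)"`.
#' @param var Variable name used in the string.
#' @return A [transform_spec()].
#' @export
parse_transform <- function(text, var = "x") {
  stopifnot(is.character(text), length(text) == 1L)
  e <- tryCatch(str2lang(text), error = function(err) {
    stop_symcox(sprintf("cannot parse transform string: %s", conditionMessage(err)))
  })
  terms <- split_terms(e)
  a <- 0; gterm <- NULL; lin <- c(c = 0, d = 0)
  for (t in terms) {
    cl <- tryCatch(classify_term(t$expr, var), error = function(err) NULL)
    if (is.null(cl)) {
      # fall back: a bare linear piece such as `x`
      lc <- lin_coefs(t$expr, var)
      lin <- lin + t$sign * lc
      next
    }
    if (cl$kind == "const") {
      a <- a + t$sign * cl$value
    } else if (cl$base == "identity") {
      lin <- lin + t$sign * c(c = cl$b * cl$c, d = cl$b * cl$d)
    } else {
      if (!is.null(gterm)) stop_symcox("transform string has more than one nonlinear term")
      cl$b <- t$sign * cl$b
      gterm <- cl
    }
  }
  if (is.null(gterm)) {
    return(transform_spec("identity", a = a + lin[["d"]], b = lin[["c"]]))
  }
  if (lin[["c"]] != 0) stop_symcox("transform string mixes a linear term with a nonlinear term")
  a <- a + lin[["d"]]
  transform_spec(gterm$base, a = a, b = gterm$b, c = gterm$c, d = gterm$d)
}

#' Key-value record form of a transformation
#'
#' @param spec A [transform_spec()].
#' @return A named list with entries `base`, `a`, `b`, `c`, `d`.
#' @export
transform_record <- function(spec) {
  stopifnot(is_transform_spec(spec))
  unclass(spec)
}

#' @rdname transform_record
#' @param record A named list as produced by `transform_record()`.
#' @export
transform_from_record <- function(record) {
  transform_spec(record$base, a = record$a, b = record$b, c = record$c, d = record$d)
}
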