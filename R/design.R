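#' Declarative model terms
#'
#' Covariate terms expanded into design-matrix columns by [build_design()]:
#' `term_linear()` a single numeric column (with the unit increment at which
#' its odds ratio is reported, e.g. 1 ug/m3 PM2.5, 1 % burned area, 10
#' g/m3/month dry matter); `term_ns()` a natural cubic spline basis with `df`
#' columns (boundary knots at the observed range, internal knots at equally
#' spaced quantiles), or with `cyclic = TRUE` a Fourier basis for periodic
#' covariates such as calendar month; `term_factor()` treatment-coded
#' indicators dropping the reference (lowest) level. Set-constant terms are
#' legal: the conditional likelihood cancels them and the fitter flags their
#' coefficients as non-identifiable.
#'
#' @param var column name in the analysis data.
#' @param increment unit increment for odds-ratio reporting.
#' @param label display label (defaults to `var`).
#' @param df spline degrees of freedom (>= 2; request a linear term instead
#'   of df = 1).
#' @param cyclic use a periodic (Fourier) basis instead of a natural spline.
#' @param period cycle length for `cyclic = TRUE`.
#' @param ref reference level for factors; default the lowest.
#' @return a `term_spec` object.
#' @examples
#' term_linear("fire", increment = 1)
#' term_ns("temperature", df = 3)
#' term_factor("conc_year")
#' @name term_spec
NULL

#' @rdname term_spec
#' @export
term_linear <- function(var, increment = 1, label = var) {
  structure(list(kind = "linear", var = var, increment = increment,
                 label = label), class = "term_spec")
}

#' @rdname term_spec
#' @export
term_ns <- function(var, df, cyclic = FALSE, period = 12, label = var) {
  if (df < 2) stop("spline df must be >= 2; use term_linear() for df = 1")
  structure(list(kind = "ns", var = var, df = as.integer(df),
                 cyclic = cyclic, period = period, label = label),
            class = "term_spec")
}

#' @rdname term_spec
#' @export
term_factor <- function(var, ref = NULL, label = var) {
  structure(list(kind = "factor", var = var, ref = ref, label = label),
            class = "term_spec")
}

#' The fully adjusted covariate specification
#'
#' The default adjustment set of the analysis: categorical maternal-age band,
#' natural splines for window-mean temperature (df 3), humidity (df 3) and
#' conception month (df 4), and calendar-year-of-conception indicators for
#' the secular trend. Exposure terms are prepended by the fitting helpers.
#'
#' @param month_cyclic use the periodic basis for conception month.
#' @return list of `term_spec`s.
#' @export
adjustment_terms <- function(month_cyclic = FALSE) {
  list(term_factor("age_band"),
       term_ns("temperature", df = 3),
       term_ns("humidity", df = 3),
       term_ns("conc_month", df = 4, cyclic = month_cyclic),
       term_factor("conc_year"))
}

#' Expand term specifications into a numeric design matrix
#'
#' @param data analysis data.frame.
#' @param terms list of `term_spec`s.
#' @return list with `X` (numeric matrix, named columns), `term_of` (term
#'   label per column), `increments` (named vector for single-column linear
#'   terms), and `bases` (fitted spline bases for later evaluation).
#' @export
build_design <- function(data, terms) {
  cols <- list()
  term_of <- character(0)
  increments <- numeric(0)
  bases <- list()
  for (tm in terms) {
    if (!tm$var %in% names(data)) stop("term variable not in data: ", tm$var)
    x <- data[[tm$var]]
    if (tm$kind == "linear") {
      m <- matrix(as.numeric(x), ncol = 1,
                  dimnames = list(NULL, tm$label))
      increments[tm$label] <- tm$increment
    } else if (tm$kind == "ns") {
      if (length(unique(x)) < 2L)
        stop("constant covariate cannot take a spline: ", tm$var)
      if (isTRUE(tm$cyclic)) {
        m <- fourier_basis(as.numeric(x), tm$df, tm$period)
      } else {
        m <- ns_basis(as.numeric(x), tm$df)
      }
      colnames(m) <- paste0(tm$label, "_s", seq_len(ncol(m)))
      bases[[tm$label]] <- attr(m, "basis_spec")
    } else if (tm$kind == "factor") {
      f <- factor(x)
      if (!is.null(tm$ref)) f <- stats::relevel(f, ref = tm$ref)
      if (nlevels(f) < 2L) {
        # single level: contributes a set-constant column; keep it explicit
        m <- matrix(1, nrow(data), 1,
                    dimnames = list(NULL, paste0(tm$label, "_const")))
      } else {
        m <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(m) <- paste0(tm$label, "_", levels(f)[-1])
      }
    } else {
      stop("unknown term kind: ", tm$kind)
    }
    cols[[length(cols) + 1L]] <- m
    term_of <- c(term_of, rep(tm$label, ncol(m)))
  }
  X <- do.call(cbind, cols)
  list(X = X, term_of = term_of, increments = increments, bases = bases)
}

#' Natural cubic spline basis
#'
#' Wrapper around [splines::ns()] with the package's knot policy: boundary
#' knots at the observed min/max, internal knots at equally spaced quantiles.
#' The returned matrix carries a `basis_spec` attribute so the identical
#' basis can be evaluated at new values (exposure-response grids).
#'
#' @param x numeric values.
#' @param df basis dimension (>= 2).
#' @return matrix with `df` columns.
#' @export
ns_basis <- function(x, df) {
  if (df < 2) stop("spline df must be >= 2")
  if (length(unique(x)) < 2L) stop("constant x has no spline basis")
  bk <- range(x)
  probs <- seq(0, 1, length.out = df + 1)[-c(1, df + 1)]
  knots <- if (df > 1) unname(stats::quantile(x, probs)) else numeric(0)
  knots <- knots[knots > bk[1] & knots < bk[2]]
  m <- splines::ns(x, knots = knots, Boundary.knots = bk)
  m <- m[, seq_len(ncol(m)), drop = FALSE]
  attr(m, "basis_spec") <- list(kind = "ns", knots = knots, boundary = bk)
  m
}

eval_basis <- function(spec, x) {
  if (spec$kind == "ns") {
    unclass(splines::ns(x, knots = spec$knots,
                        Boundary.knots = spec$boundary))
  } else {
    fourier_eval(x, spec$df, spec$period)
  }
}

fourier_basis <- function(x, df, period) {
  m <- fourier_eval(x, df, period)
  attr(m, "basis_spec") <- list(kind = "fourier", df = df, period = period)
  m
}

fourier_eval <- function(x, df, period) {
  k_max <- ceiling(df / 2)
  cols <- lapply(seq_len(k_max), function(k)
    cbind(sin(2 * pi * k * x / period), cos(2 * pi * k * x / period)))
  m <- do.call(cbind, cols)[, seq_len(df), drop = FALSE]
  m
}
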