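#' Fractional-polynomial basis specification
#'
#' Defines a fractional-polynomial (FP) basis of age for the trajectory
#' models. Powers are drawn from the conventional set
#' \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}, where power 0 denotes log(x) and a
#' repeated power p contributes the pair x^p and x^p * log(x). Ages are
#' affinely rescaled before exponentiation, t = (age - offset) / divisor,
#' and must be strictly positive after the transform.
#'
#' The default transform (offset 0, divisor 10) maps the study ages 10-25
#' to t in [1, 2.5], keeping all FP powers well-conditioned.
#'
#' @param powers numeric vector (degree <= 2) of FP powers, possibly with a
#'   repeat.
#' @param offset,divisor affine age transform parameters.
#' @return object of class \code{fp_basis}.
#' @export
fp_basis <- function(powers = c(1, 2), offset = 0, divisor = 10) {
  allowed <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)
  if (!length(powers) || length(powers) > 2L)
    stop_config("an FP basis has degree 1 or 2, got %d powers", length(powers))
  if (!all(powers %in% allowed))
    stop_config("FP powers must come from {%s}", paste(allowed, collapse = ", "))
  if (divisor <= 0) stop_config("divisor must be positive")
  structure(list(powers = sort(powers), offset = offset, divisor = divisor),
            class = "fp_basis")
}

#' @export
print.fp_basis <- function(x, ...) {
  cat(sprintf("FP basis: powers (%s), t = (age - %g)/%g\n",
              paste(x$powers, collapse = ", "), x$offset, x$divisor))
  invisible(x)
}

# single FP term t^p with the log-for-zero convention
fp_term <- function(t, p) if (p == 0) log(t) else t^p

#' Build a fractional-polynomial design matrix
#'
#' Evaluates an [fp_basis()] at a vector of ages, returning a design matrix
#' with an intercept column followed by the FP terms in ascending power
#' order. A repeated power p expands to columns t^p and t^p * log(t).
#'
#' @param ages numeric vector of ages in years.
#' @param basis an [fp_basis()].
#' @return numeric matrix with \code{length(ages)} rows.
#' @examples
#' build_fp_basis(10, fp_basis(c(1, 2), divisor = 1))  # (1, 10, 100)
#' @export
build_fp_basis <- function(ages, basis) {
  stopifnot(inherits(basis, "fp_basis"))
  t <- (ages - basis$offset) / basis$divisor
  if (any(t <= 0))
    stop_config("transformed age must be strictly positive for FP powers (min = %g)",
                min(t))
  p <- basis$powers
  if (length(p) == 2L && p[1L] == p[2L]) {
    cols <- cbind(fp_term(t, p[1L]), fp_term(t, p[1L]) * log(t))
    nm <- c(fp_name(p[1L]), paste0(fp_name(p[1L]), ".logt"))
  } else {
    cols <- vapply(p, function(pi) fp_term(t, pi), numeric(length(t)))
    cols <- matrix(cols, nrow = length(t))
    nm <- vapply(p, fp_name, character(1L))
  }
  out <- cbind(1, cols)
  colnames(out) <- c("(Intercept)", nm)
  out
}

fp_name <- function(p) if (p == 0) "logt" else paste0("t^", p)

#' Enumerate candidate fractional-polynomial bases
#'
#' All degree-1 bases over the power set plus, when \code{max_degree = 2},
#' all degree-2 multisets (unordered pairs with repetition). For the
#' conventional 8-power set this yields 8 + 36 = 44 candidate bases.
#'
#' @param powers the candidate power set.
#' @param max_degree 1 or 2.
#' @inheritParams fp_basis
#' @return list of [fp_basis()] objects.
#' @export
enumerate_fp_specs <- function(powers = c(-2, -1, -0.5, 0, 0.5, 1, 2, 3),
                               max_degree = 2, offset = 0, divisor = 10) {
  if (!length(powers)) stop_config("power set must be nonempty")
  powers <- sort(unique(powers))
  specs <- lapply(powers, function(p) fp_basis(p, offset, divisor))
  if (max_degree >= 2) {
    k <- length(powers)
    for (i in seq_len(k)) for (j in i:k)
      specs <- c(specs, list(fp_basis(c(powers[i], powers[j]), offset, divisor)))
  }
  specs
}
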