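#' B-spline basis with quantile knots
#'
#' Builds an `n x n_basis` B-spline design matrix over the range of `x`.
#' Interior knots sit at quantiles of `x`; boundary knots are clamped with
#' multiplicity `degree + 1`, so the basis is a partition of unity over the
#' whole span (including both endpoints).
#'
#' @param x Numeric vector of evaluation points.
#' @param n_basis Number of basis functions (>= degree + 1).
#' @param degree Polynomial degree (default cubic). Degree 0 gives interval
#'   indicator functions.
#' @param span Optional length-2 numeric giving the knot span; defaults to
#'   `range(x)`. Points of `x` must lie inside the span.
#' @return An object of class `basis_matrix`: list with `values` (matrix),
#'   `kind`, `knots` (full knot vector), `degree`.
#' @export
bspline_basis <- function(x, n_basis, degree = 3, span = range(x)) {
  x <- as.numeric(x)
  if (length(x) == 0) stop("x is empty")
  n_basis <- as.integer(n_basis); degree <- as.integer(degree)
  if (n_basis < degree + 1L)
    stop("n_basis (", n_basis, ") must be at least degree + 1 = ", degree + 1L)
  if (span[2] <= span[1]) stop("degenerate span")
  if (any(x < span[1] | x > span[2])) stop("x outside knot span")
  n_interior <- n_basis - degree - 1L
  interior <- if (n_interior > 0)
    stats::quantile(x, probs = seq_len(n_interior) / (n_interior + 1),
                    names = FALSE, type = 7)
  else numeric(0)
  # keep interior knots strictly inside the span and strictly increasing
  eps <- 1e-8 * (span[2] - span[1])
  interior <- pmin(pmax(interior, span[1] + eps), span[2] - eps)
  if (n_interior > 1) interior <- cummax(interior + seq_len(n_interior) * 0)
  if (anyDuplicated(interior))
    interior <- interior + seq_along(interior) * eps
  knots <- c(rep(span[1], degree + 1L), interior, rep(span[2], degree + 1L))
  values <- splines::splineDesign(knots, x, ord = degree + 1L, outer.ok = FALSE)
  structure(list(values = values, kind = "bspline", knots = knots,
                 degree = degree),
            class = "basis_matrix")
}

#' M-spline basis
#'
#' M-splines are the normalized, non-negative relatives of B-splines: each
#' basis function integrates to one over the knot span,
#' `M_i(x) = (degree + 1) / (t[i + degree + 1] - t[i]) * B_i(x)`.
#' Knot placement is as in [bspline_basis()].
#'
#' @inheritParams bspline_basis
#' @return A `basis_matrix` with `kind = "mspline"`.
#' @export
mspline_basis <- function(x, n_basis, degree = 3, span = range(x)) {
  b <- bspline_basis(x, n_basis, degree, span)
  ord <- b$degree + 1L
  supp <- b$knots[seq_len(n_basis) + ord] - b$knots[seq_len(n_basis)]
  b$values <- sweep(b$values, 2, ord / supp, `*`)
  b$kind <- "mspline"
  b
}

#' Row-wise tensor product of two bases
#'
#' The design matrix of a tensor-product smoother: row `i` of the result is
#' the Kronecker product of row `i` of `A` with row `i` of `P`, giving
#' `q_A * q_P` columns. This is the classical "z-model" random-effects design
#' for a smooth age x period interaction.
#'
#' @param A,P `basis_matrix` objects (or plain matrices) with equal row count.
#' @return A `basis_matrix` with `kind = "tensor"`.
#' @export
tensor_product_rows <- function(A, P) {
  Am <- if (inherits(A, "basis_matrix")) A$values else as.matrix(A)
  Pm <- if (inherits(P, "basis_matrix")) P$values else as.matrix(P)
  if (nrow(Am) != nrow(Pm))
    stop("row count mismatch: ", nrow(Am), " vs ", nrow(Pm))
  qa <- ncol(Am); qp <- ncol(Pm)
  values <- Am[, rep(seq_len(qa), each = qp), drop = FALSE] *
    Pm[, rep(seq_len(qp), times = qa), drop = FALSE]
  structure(list(values = values, kind = "tensor", knots = numeric(0),
                 degree = NA_integer_),
            class = "basis_matrix")
}

#' Second-order random-walk structure matrix
#'
#' The intrinsic precision structure of an rw2 prior: `Q = D' D` with `D` the
#' `(n - 2) x n` second-difference matrix. `Q` is positive semi-definite with
#' a two-dimensional null space (constant and linear vectors), so its rank
#' deficiency is 2; the quadratic form `x' Q x` is the sum of squared second
#' differences of `x`. The precision parameter multiplies `Q` at fit time.
#'
#' @param n Length of the effect vector (>= 3).
#' @return An object of class `structure_matrix`: list with `Q` (n x n),
#'   `rank_deficiency`, `kind`.
#' @export
rw2_structure <- function(n) {
  n <- as.integer(n)
  if (n < 3) stop("rw2 needs n >= 3")
  D <- diff(diag(n), differences = 2)
  structure(list(Q = crossprod(D), rank_deficiency = 2L, kind = "rw2"),
            class = "structure_matrix")
}

#' Independent-effects structure matrix
#'
#' Identity structure for an iid Gaussian effect (e.g. a per-cell
#' overdispersion term); full rank.
#'
#' @param n Length of the effect vector.
#' @return A `structure_matrix` with `kind = "iid"`.
#' @export
iid_structure <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1)
  structure(list(Q = diag(n), rank_deficiency = 0L, kind = "iid"),
            class = "structure_matrix")
}
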