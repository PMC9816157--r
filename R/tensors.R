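# Symmetric 3x3 tensors are stored either as full matrices or as the 6
# independent components in the fixed order xx, yy, zz, xy, xz, yz.
# Frobenius contractions over full tensors use weights (1,1,1,2,2,2) on the
# component form.

tensor_comp_names <- c("xx", "yy", "zz", "xy", "xz", "yz")
tensor_comp_weights <- c(1, 1, 1, 2, 2, 2)

#' Convert between 3x3 symmetric tensors and 6-component vectors
#'
#' Component order is xx, yy, zz, xy, xz, yz. `tensor_to_comps` symmetrizes
#' its input; `comps_to_tensor` builds the full symmetric matrix.
#'
#' @param m 3x3 numeric matrix.
#' @param v length-6 numeric vector.
#' @return length-6 vector or 3x3 matrix respectively.
#' @export
tensor_to_comps <- function(m) {
  m <- (m + t(m)) / 2
  c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])
}

#' @rdname tensor_to_comps
#' @export
comps_to_tensor <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}

#' Frobenius contraction A:B of two symmetric tensors in component form
#'
#' Off-diagonal components are double-counted, matching the full
#' \eqn{\sum_{\alpha\beta} A_{\alpha\beta} B_{\alpha\beta}}.
#'
#' @param a,b length-6 component vectors or n x 6 matrices (rowwise).
#' @return numeric contraction(s).
#' @export
frobenius_dot <- function(a, b = a) {
  if (is.matrix(a)) {
    drop((a * b) %*% tensor_comp_weights)
  } else {
    sum(a * b * tensor_comp_weights)
  }
}

#' Validate that a tensor is symmetric and traceless
#'
#' Point-charge EFG tensors away from sources are harmonic, hence traceless,
#' and symmetric by construction. The check is relative to the Frobenius
#' norm; zero tensors pass.
#'
#' @param m 3x3 matrix.
#' @param tol_sym relative symmetry tolerance.
#' @param tol_trace relative trace tolerance.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
check_efg_tensor <- function(m, tol_sym = 1e-10, tol_trace = 1e-8) {
  fn <- sqrt(sum(m^2))
  if (fn == 0) return(invisible(TRUE))
  asym <- max(abs(m - t(m))) / fn
  if (asym > tol_sym)
    stop(sprintf("tensor not symmetric: relative asymmetry %.3g", asym))
  rel_tr <- abs(sum(diag(m))) / fn
  if (rel_tr > tol_trace)
    stop(sprintf("tensor not traceless: |tr|/||V|| = %.3g", rel_tr))
  invisible(TRUE)
}

# Orthonormal basis of the 5-dimensional space of symmetric traceless 3x3
# tensors, orthonormal under the Frobenius inner product A:B.
traceless_basis <- function() {
  s2 <- sqrt(2) / 2
  list(
    diag(c(1, -1, 0)) / sqrt(2),
    diag(c(1, 1, -2)) / sqrt(6),
    matrix(c(0, s2, 0, s2, 0, 0, 0, 0, 0), 3, 3),
    matrix(c(0, 0, s2, 0, 0, 0, s2, 0, 0), 3, 3),
    matrix(c(0, 0, 0, 0, 0, s2, 0, s2, 0), 3, 3)
  )
}
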