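#' Kors regression matrix
#'
#' The published 3 x 8 regression matrix mapping the eight linearly
#' independent leads (I, II, V1--V6, in that order) onto the orthogonal
#' vectorcardiographic axes X, Y, Z.  Axis convention: X positive leftward,
#' Y positive inferior, Z positive posterior.  Users may supply their own
#' coefficients to [kors_transform()] and [project_to_leads()]; every
#' function in the package takes the matrix as an argument with this
#' constant as the default.
#'
#' @return A 3 x 8 numeric matrix with rownames `c("X","Y","Z")` and
#'   colnames `c("I","II","V1","V2","V3","V4","V5","V6")`.
#' @export
kors_matrix <- function() {
  K <- rbind(
    X = c(0.38, -0.07, -0.13, 0.05, -0.01, 0.14, 0.06, 0.54),
    Y = c(-0.07, 0.93, 0.06, -0.02, -0.05, 0.06, -0.17, 0.13),
    Z = c(0.11, -0.23, -0.43, -0.06, -0.14, -0.20, -0.11, 0.31)
  )
  colnames(K) <- vcg_independent_leads()
  K
}

#' Lead-name constants
#'
#' @return Character vectors of lead names: `vcg_lead_names()` the full
#'   12-lead set, `vcg_independent_leads()` the 8 linearly independent
#'   leads in Kors order.
#' @export
vcg_lead_names <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

#' @rdname vcg_lead_names
#' @export
vcg_independent_leads <- function() {
  c("I", "II", "V1", "V2", "V3", "V4", "V5", "V6")
}

#' Moore-Penrose right-inverse of a lead-transform matrix
#'
#' For a full-row-rank 3 x 8 matrix K this returns the 8 x 3 matrix
#' L = K' (K K')^-1 with K L = I3, used by the synthetic generator so the
#' Kors projection of the generated leads recovers the dipole trajectory
#' exactly.
#'
#' @param K 3 x 8 numeric matrix.
#' @return 8 x 3 numeric matrix.
#' @export
kors_right_inverse <- function(K = kors_matrix()) {
  if (!is.matrix(K) || nrow(K) != 3L) {
    stop("K must be a 3 x n matrix")
  }
  G <- K %*% t(K)
  if (abs(det(G)) < 1e-12) stop("K is rank-deficient; no right-inverse")
  t(K) %*% solve(G)
}
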