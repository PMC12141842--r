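#' Piecewise-linear displacement profile nodes
#'
#' A displacement profile maps relative position along the elongation axis
#' (0 = immobile plate, 1 = mobile plate) to relative displacement (fraction
#' of the total plate translation). Profiles are stored as ordered nodes and
#' evaluated by linear interpolation, which is exact for the piecewise-linear
#' deformation regimes seen in stretched pellicles.
#'
#' @param x_rel numeric vector of relative positions; strictly increasing,
#'   starting at 0 and ending at 1.
#' @param u_rel numeric vector of relative displacements at the nodes.
#' @return An object of class `profile_nodes`: a data frame with columns
#'   `x_rel` and `u_rel`.
#' @examples
#' nodes <- profile_nodes(c(0, 1), c(0, 1))   # affine (homogeneous) stretch
#' evaluate_profile(nodes, 0.37)
#' @export
profile_nodes <- function(x_rel, u_rel) {
  if (length(x_rel) != length(u_rel) || length(x_rel) < 2L) {
    stop_input("need at least two (x_rel, u_rel) nodes of equal length")
  }
  if (any(!is.finite(x_rel)) || any(!is.finite(u_rel))) {
    stop_input("profile nodes must be finite")
  }
  if (any(diff(x_rel) <= 0)) stop_input("node x_rel must be strictly increasing")
  if (abs(x_rel[1L]) > 1e-12 || abs(x_rel[length(x_rel)] - 1) > 1e-12) {
    stop_input("profile nodes must span x_rel = 0 to x_rel = 1")
  }
  structure(data.frame(x_rel = as.numeric(x_rel), u_rel = as.numeric(u_rel)),
            class = c("profile_nodes", "data.frame"))
}

#' Canonical rough-pellicle deformation profile
#'
#' The minimal piecewise-linear profile consistent with the four deformation
#' regimes of a stretched rough pellicle: a soft region near the immobile
#' plate absorbing one-third of the elongation over relative positions
#' 0 to 0.15, a central region elongating by a further 27 % up to 0.70, a
#' rigid region translating without deformation at constant relative
#' displacement 0.60 up to 0.95, and a narrow, almost discontinuous step that
#' takes up the remaining displacement next to the mobile plate.
#'
#' @return A [profile_nodes] object with nodes
#'   (0, 0), (0.15, 0.33), (0.70, 0.60), (0.95, 0.60), (1, 1).
#' @export
canonical_rough_nodes <- function() {
  profile_nodes(x_rel = c(0, 0.15, 0.70, 0.95, 1),
                u_rel = c(0, 0.33, 0.60, 0.60, 1))
}

#' Affine (homogeneous elastic) profile
#'
#' @return A [profile_nodes] object describing `u_rel = x_rel`, the expected
#'   profile of a homogeneous elastic sheet under uniaxial stretch.
#' @export
affine_nodes <- function() profile_nodes(c(0, 1), c(0, 1))

#' Evaluate a displacement profile
#'
#' Linear interpolation between the bracketing nodes; exact at nodes.
#'
#' @param nodes a [profile_nodes] object.
#' @param x_rel numeric vector of relative positions in \[0, 1\].
#' @return Relative displacement(s) at `x_rel`.
#' @export
evaluate_profile <- function(nodes, x_rel) {
  stopifnot(inherits(nodes, "profile_nodes"))
  if (any(!is.finite(x_rel)) || any(x_rel < -1e-12) || any(x_rel > 1 + 1e-12)) {
    stop_input("x_rel must lie in [0, 1]")
  }
  stats::approx(nodes$x_rel, nodes$u_rel, xout = pmin(pmax(x_rel, 0), 1),
                method = "linear", ties = "ordered")$y
}
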