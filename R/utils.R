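#' @keywords internal
"_PACKAGE"

#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   across left_join bind_rows distinct slice n row_number first pull rename
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats sd setNames approx lm coef rnorm runif
#' @importFrom utils head tail
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) abort("cannot normalise a zero-length vector")
  v / n
}

# Rodrigues rotation matrix: rotate by `angle_deg` about unit axis `axis`
rotation_about_axis <- function(axis, angle_deg) {
  k <- unit_vec(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# angle between two vectors in degrees, clamped against rounding
vec_angle <- function(a, b) {
  ca <- sum(unit_vec(a) * unit_vec(b))
  rad2deg(acos(pmin(1, pmax(-1, ca))))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_if_not_scalar <- function(x, what) {
  if (!is_scalar_number(x)) abort(paste0("`", what, "` must be a single finite number"))
  invisible(x)
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

# apply a 3x3 rotation + translation to an N x 3 matrix
apply_transform <- function(xyz, rotation, translation = c(0, 0, 0)) {
  sweep(xyz %*% t(rotation), 2, -translation, FUN = "-")
}

coords_matrix <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}

set_coords <- function(atoms, xyz) {
  atoms$x <- xyz[, 1]
  atoms$y <- xyz[, 2]
  atoms$z <- xyz[, 3]
  atoms
}
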