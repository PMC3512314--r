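#' Pull-direction and binding-pocket-plane geometry
#'
#' `pull_direction()` constructs the unit vector from the ligand's center of
#' mass to the centroid of three reference points — in the protocol this
#' emulates, the centroids of the side chains of three binding-pocket residues
#' that define the pocket threshold plane.
#'
#' @param ligand_com numeric length-3, ligand center of mass.
#' @param p1,p2,p3 numeric length-3, the three reference points.
#' @return unit-norm numeric length-3 vector pointing from the ligand toward
#'   the pocket threshold.
#' @examples
#' pull_direction(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(0, 0, 3))
#' @export
pull_direction <- function(ligand_com, p1, p2, p3) {
  for (v in list(ligand_com, p1, p2, p3)) {
    if (length(v) != 3 || !all(is.finite(v))) {
      stop("all points must be finite length-3 vectors", call. = FALSE)
    }
  }
  centroid <- (p1 + p2 + p3) / 3
  d <- centroid - ligand_com
  nrm <- sqrt(sum(d^2))
  if (nrm < 1e-12) {
    stop("degenerate geometry: ligand center of mass coincides with the ",
         "reference centroid", call. = FALSE)
  }
  d / nrm
}

#' First crossing of the binding-pocket threshold plane
#'
#' Finds the first trajectory sample at which the pulled point crosses the
#' plane through three reference points. The plane normal is oriented so its
#' projection on the pull direction is positive, which makes "crossing"
#' sign-unambiguous. A sample lying exactly on the plane counts as the
#' crossing sample.
#'
#' @param positions an n x 3 matrix of pulled-point positions (row per
#'   sample), or a numeric vector for a one-dimensional trajectory together
#'   with plane points on the same axis.
#' @param p1,p2,p3 numeric length-3 points spanning the plane (non-collinear).
#' @param pull_dir optional length-3 pull direction used to orient the
#'   normal; defaults to the net displacement of `positions`.
#' @return the 1-based index of the first sample on or beyond the plane, or
#'   `NA_integer_` if the trajectory never crosses it.
#' @export
plane_crossing_index <- function(positions, p1, p2, p3, pull_dir = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) {
    stop("positions must have 3 columns", call. = FALSE)
  }
  n <- cross3(p2 - p1, p3 - p1)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) {
    stop("degenerate geometry: plane points are collinear", call. = FALSE)
  }
  n <- n / nn
  if (is.null(pull_dir)) {
    pull_dir <- positions[nrow(positions), ] - positions[1, ]
  }
  proj <- sum(n * pull_dir)
  if (abs(proj) < 1e-12) {
    stop("pull direction lies in the plane; normal orientation is ambiguous",
         call. = FALSE)
  }
  if (proj < 0) n <- -n
  sdist <- as.numeric(sweep(positions, 2, p1) %*% n)
  # first sample whose signed distance is zero or has flipped sign relative
  # to the start
  s0 <- sign(sdist[1])
  if (s0 == 0) return(1L)
  hit <- which(sdist == 0 | sign(sdist) != s0)
  if (length(hit) == 0) return(NA_integer_)
  hit[1]
}

# 3-vector cross product (kept local; no dependency needed for one line)
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
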