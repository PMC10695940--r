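# Landmark-based anatomical reference frame: origin at the left auditory
# meatus; the horizontal plane passes through the nasion and both meatuses;
# z runs from the left to the right meatus, y is cranial, x posterior.

#' Rigid transform into the anatomical reference frame
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1 (rows are the
#'   frame axes expressed in source coordinates).
#' @param translation length-3 offset applied after rotation, mm.
#' @return object of class `frame_transform`.
#' @export
frame_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3, 3)))
  if (abs(det(rotation) - 1) > 1e-8 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "frame_transform")
}

#' Apply a frame transform to points
#'
#' @param tf a [frame_transform()].
#' @param points n x 3 matrix or length-3 vector, mm.
#' @return transformed points, same shape as the input.
#' @export
apply_transform <- function(tf, points) {
  stopifnot(inherits(tf, "frame_transform"))
  if (is.null(dim(points))) {
    as.numeric(tf$rotation %*% points + tf$translation)
  } else {
    sweep(points %*% Matrix::t(tf$rotation), 2, -tf$translation)
  }
}

#' Invert a frame transform
#' @param tf a [frame_transform()].
#' @return the inverse `frame_transform`.
#' @export
invert_transform <- function(tf) {
  R <- base::t(tf$rotation)
  frame_transform(R, as.numeric(-R %*% tf$translation))
}

#' Compose two frame transforms
#' @param tf2,tf1 transforms; the result applies `tf1` first, then `tf2`.
#' @return the composed `frame_transform`.
#' @export
compose_transforms <- function(tf2, tf1) {
  frame_transform(tf2$rotation %*% tf1$rotation,
                  as.numeric(tf2$rotation %*% tf1$translation) + tf2$translation)
}

#' Align a skull surface to the anatomical reference frame
#'
#' Places the origin at the left auditory meatus, the horizontal plane through
#' the nasion and both meatuses, the z axis along the left-to-right meatus
#' line, x in the horizontal plane perpendicular to z (positive posterior) and
#' y completing a right-handed frame (positive cranial).
#'
#' @param surface a `skull_surface` in any rigid pose.
#' @return `list(surface =, transform =)`: the aligned surface and the
#'   `frame_transform` that maps source coordinates into the frame.
#' @examples
#' al <- align_to_frame(generate_skull(skull_spec(mesh_edge_target = 10)))
#' al$surface$landmarks$meatus_left  # origin
#' @export
align_to_frame <- function(surface) {
  stopifnot(inherits(surface, "skull_surface"))
  lm <- surface$landmarks
  ml <- lm$meatus_left; mr <- lm$meatus_right; na <- lm$nasion
  ez <- mr - ml
  lz <- sqrt(sum(ez^2))
  v2 <- na - ml
  nrm <- c(ez[2] * v2[3] - ez[3] * v2[2],
           ez[3] * v2[1] - ez[1] * v2[3],
           ez[1] * v2[2] - ez[2] * v2[1])
  ln <- sqrt(sum(nrm^2))
  if (lz < 1e-9 || ln < 1e-9 * lz) {
    stop("degenerate frame: landmarks are collinear or coincident", call. = FALSE)
  }
  ez <- ez / lz
  ey <- nrm / ln
  # y must point to the cranial side (where the bulk of the shell lies)
  centroid <- colMeans(surface$vertices)
  if (sum((centroid - ml) * ey) < 0) ey <- -ey
  ex <- c(ey[2] * ez[3] - ey[3] * ez[2],
          ey[3] * ez[1] - ey[1] * ez[3],
          ey[1] * ez[2] - ey[2] * ez[1])
  # anatomically consistent landmarks put the nasion anterior (x < 0); if not,
  # the meatus labels are swapped and the frame would be mirrored
  if (sum((na - ml) * ex) > 0) {
    stop("landmarks appear left/right swapped: nasion falls posterior",
         call. = FALSE)
  }
  R <- rbind(ex, ey, ez)
  dimnames(R) <- NULL
  tf <- frame_transform(R, as.numeric(-R %*% ml))
  out <- surface
  out$vertices <- apply_transform(tf, surface$vertices)
  out$landmarks <- lapply(surface$landmarks, function(p) apply_transform(tf, p))
  list(surface = out, transform = tf)
}
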