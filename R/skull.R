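# Synthetic calvarium shells.  The generator builds a quasi-uniform point set
# on the unit sphere (mirror-symmetric about the midsagittal plane),
# triangulates it by its convex hull, opens a circular foramen magnum at the
# base, and maps the sphere onto an ellipsoidal dome with a flattened base so
# that skull length, width and height are independently controllable.

#' Specification of a synthetic skull
#'
#' Describes the geometry of a simplified paediatric calvarium shell:
#' a tri-axial ellipsoidal dome above the nasion-meatus horizontal plane and
#' a flattened ellipsoidal base just below it, with a circular foramen magnum
#' opening at the base centre.
#'
#' @param length_ap anterior-posterior extent, mm.
#' @param width_ml medio-lateral extent, mm.
#' @param height_cc cranio-caudal height above the horizontal plane, mm.
#' @param thickness uniform shell thickness, mm.
#' @param foramen_radius radius of the foramen magnum opening, mm.
#' @param mesh_edge_target target triangle edge length, mm.
#' @param bump_amplitude amplitude of smooth seeded surface bumps emulating
#'   patient variability, mm. `0` gives an exactly midline-symmetric shell.
#' @param seed integer seed for the bump field.
#' @return object of class `skull_spec`.
#' @examples
#' spec <- skull_spec(mesh_edge_target = 10)
#' skull <- generate_skull(spec)
#' @export
skull_spec <- function(length_ap = 170, width_ml = 140, height_cc = 100,
                       thickness = 3, foramen_radius = 15,
                       mesh_edge_target = 6, bump_amplitude = 1.5,
                       seed = 1L) {
  ext <- c(length_ap = length_ap, width_ml = width_ml, height_cc = height_cc)
  if (any(!is.finite(ext)) || any(ext <= 0)) {
    stop("all skull extents must be positive", call. = FALSE)
  }
  if (thickness <= 0 || thickness >= 0.1 * min(ext)) {
    stop("thickness must be positive and below 10% of the smallest extent",
         call. = FALSE)
  }
  if (foramen_radius < 0 || foramen_radius >= 0.3 * width_ml) {
    stop("foramen_radius must lie in [0, 0.3 * width_ml)", call. = FALSE)
  }
  if (mesh_edge_target <= 0) stop("mesh_edge_target must be positive", call. = FALSE)
  if (bump_amplitude < 0) stop("bump_amplitude must be non-negative", call. = FALSE)
  structure(list(length_ap = length_ap, width_ml = width_ml,
                 height_cc = height_cc, thickness = thickness,
                 foramen_radius = foramen_radius,
                 mesh_edge_target = mesh_edge_target,
                 bump_amplitude = bump_amplitude, seed = as.integer(seed)),
            class = "skull_spec")
}

#' @export
print.skull_spec <- function(x, ...) {
  cat(sprintf(paste0("<skull_spec> AP %.0f x ML %.0f x CC %.0f mm, ",
                     "thickness %.1f mm, foramen r=%.0f mm, edge %.1f mm, ",
                     "bumps %.1f mm, seed %d\n"),
              x$length_ap, x$width_ml, x$height_cc, x$thickness,
              x$foramen_radius, x$mesh_edge_target, x$bump_amplitude, x$seed))
  invisible(x)
}

# fraction of height_cc used as base depth below the horizontal plane; kept
# small so the base closure is nearly flat and the enclosed volume is governed
# by the dome semi-axes.
BASE_DEPTH_FRAC <- 0.008

# Mirror-symmetric quasi-uniform unit-sphere point set.  Build frame here:
# x posterior, y cranial, z lateral (mirror plane z = 0).
sphere_points_symmetric <- function(n_target) {
  m <- max(60L, as.integer(floor(n_target / 2)))
  golden <- pi * (3 - sqrt(5))
  k <- seq_len(m)
  zlat <- (k - 0.5) / m              # in (0, 1): open hemisphere
  rho <- sqrt(pmax(0, 1 - zlat^2))
  phi <- k * golden
  half <- cbind(rho * cos(phi), rho * sin(phi), zlat)
  # equator ring, spacing matched to the lattice density
  m_eq <- max(16L, round(2 * pi / sqrt(4 * pi / (2 * m) * 2 / sqrt(3))))
  ang <- 2 * pi * (seq_len(m_eq) - 0.5) / m_eq
  ring <- cbind(cos(ang), sin(ang), 0)
  pts <- rbind(half, cbind(half[, 1], half[, 2], -half[, 3]), ring)
  pts
}

# vertical semi-axis: full dome height above the horizontal plane, shallow
# ellipsoidal base closure below it (the base rim sits exactly on the plane)
blend_height <- function(uy, h_up, h_dn) {
  ifelse(uy >= 0, h_up, h_dn)
}

#' Generate a synthetic calvarium shell
#'
#' Builds a closed triangulated shell with paediatric-skull proportions, a
#' single foramen-magnum boundary loop at the base, and the three anatomical
#' landmarks (nasion, left/right auditory meatus) that define the horizontal
#' reference plane.  Output is already expressed in the anatomical frame
#' (origin at the left meatus, x posterior, y cranial, z towards the right
#' meatus), so [align_to_frame()] on it is the identity.
#'
#' @param spec a [skull_spec()].
#' @return object of class `skull_surface` with fields `vertices`, `faces`,
#'   `landmarks` (list `nasion`, `meatus_left`, `meatus_right`),
#'   `foramen_loop` (ordered boundary vertex indices), `thickness`, `spec`.
#' @examples
#' skull <- generate_skull(skull_spec(mesh_edge_target = 10))
#' mesh_volume(skull$vertices, rbind(skull$faces))
#' @export
generate_skull <- function(spec) {
  stopifnot(inherits(spec, "skull_spec"))
  a <- spec$length_ap / 2
  cw <- spec$width_ml / 2
  h_up <- spec$height_cc
  h_dn <- BASE_DEPTH_FRAC * spec$height_cc

  # point budget from the target edge length on an equivalent sphere
  p <- 1.6075  # Thomsen's approximation for the ellipsoid area
  area <- 4 * pi * (((a * cw)^p + (a * ((h_up + h_dn) / 2))^p +
                       (cw * ((h_up + h_dn) / 2))^p) / 3)^(1 / p) / 2 +
    pi * a * cw  # dome half + base disk
  n_target <- max(300L, round(2 * area / (sqrt(3) / 4 * spec$mesh_edge_target^2) / 2))

  unit <- sphere_points_symmetric(n_target)
  hull <- .quickhull_cpp(unit)
  faces <- hull$faces

  # map build frame (x posterior, y cranial, z lateral) onto the skull shape
  uy <- unit[, 2]
  h <- blend_height(uy, h_up, h_dn)
  vertices <- cbind(a * unit[, 1], h * uy, cw * unit[, 3])

  # open the foramen: remove faces whose centroid lies in the basal disc
  cx <- (vertices[faces[, 1], 1] + vertices[faces[, 2], 1] + vertices[faces[, 3], 1]) / 3
  cy <- (vertices[faces[, 1], 2] + vertices[faces[, 2], 2] + vertices[faces[, 3], 2]) / 3
  cz <- (vertices[faces[, 1], 3] + vertices[faces[, 2], 3] + vertices[faces[, 3], 3]) / 3
  rad <- sqrt(cx^2 + cz^2)
  drop <- cy < 0 & rad < spec$foramen_radius
  if (!any(drop)) {
    # foramen smaller than the mesh resolution: open a minimal one-ring hole
    low <- which.min(vertices[, 2])
    drop <- faces[, 1] == low | faces[, 2] == low | faces[, 3] == low
  }
  faces <- faces[!drop, , drop = FALSE]

  loops <- boundary_loops(faces)
  if (!mesh_is_manifold(faces) || length(loops) != 1L) {
    stop(paste("skull generation failed: mesh resolution too coarse for the",
               "requested foramen radius (expected a single boundary loop)"),
         call. = FALSE)
  }

  # drop the interior vertices of the removed foramen cap
  dv <- drop_unused_vertices(vertices, faces)
  vertices <- dv$vertices
  faces <- dv$faces
  unit <- unit[!is.na(dv$map), , drop = FALSE]   # map preserves vertex order
  loops <- list(dv$map[loops[[1L]]])

  # smooth seeded bumps along the outward normal (patient variability)
  if (spec$bump_amplitude > 0) {
    nrm <- vertex_normals(vertices, faces)
    bump <- with_seed(spec$seed, {
      n_b <- 10L
      dirs <- matrix(rnorm(3 * n_b), n_b, 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      amp <- runif(n_b, -1, 1) * spec$bump_amplitude
      wid <- runif(n_b, 0.25, 0.6)
      field <- numeric(nrow(unit))
      for (b in seq_len(n_b)) {
        cosang <- pmin(1, pmax(-1, unit %*% dirs[b, ]))
        ang <- acos(cosang)
        field <- field + amp[b] * exp(-(ang / wid[b])^2)
      }
      field
    })
    vertices <- vertices + as.vector(bump) * nrm
  }

  landmarks <- list(nasion = c(-a, 0, 0),
                    meatus_left = c(0, 0, -cw),
                    meatus_right = c(0, 0, cw))
  # shift to the anatomical frame: origin at the left auditory meatus
  shift <- c(0, 0, cw)
  vertices <- sweep(vertices, 2, -shift)
  landmarks <- lapply(landmarks, function(p) p + shift)

  surface <- structure(list(vertices = vertices, faces = faces,
                            landmarks = landmarks,
                            foramen_loop = loops[[1L]],
                            thickness = spec$thickness, spec = spec),
                       class = "skull_surface")
  surface
}

#' @export
print.skull_surface <- function(x, ...) {
  cat(sprintf(paste0("<skull_surface> %d vertices, %d faces, thickness %.1f mm,",
                     " foramen loop of %d vertices\n"),
              nrow(x$vertices), nrow(x$faces), x$thickness,
              length(x$foramen_loop)))
  invisible(x)
}

#' Validate the structural invariants of a skull surface
#'
#' Checks manifoldness, the single (foramen) boundary loop, consistent outward
#' orientation, landmark plausibility and affine independence of the landmark
#' triplet.
#'
#' @param surface a `skull_surface`.
#' @return `TRUE` invisibly; errors describe the first violated invariant.
#' @export
validate_skull_surface <- function(surface) {
  stopifnot(inherits(surface, "skull_surface"))
  if (!mesh_is_manifold(surface$faces)) stop("mesh is not manifold", call. = FALSE)
  loops <- boundary_loops(surface$faces)
  if (length(loops) != 1L) {
    stop(sprintf("expected 1 boundary loop, found %d", length(loops)), call. = FALSE)
  }
  if (mesh_volume(surface$vertices, surface$faces) <= 0) {
    stop("faces are not consistently oriented outward", call. = FALSE)
  }
  lm <- surface$landmarks
  m <- rbind(lm$nasion - lm$meatus_left, lm$meatus_right - lm$meatus_left)
  cr <- c(m[1, 2] * m[2, 3] - m[1, 3] * m[2, 2],
          m[1, 3] * m[2, 1] - m[1, 1] * m[2, 3],
          m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])
  if (sqrt(sum(cr^2)) < 1e-6) {
    stop("landmarks are collinear; they must define a plane", call. = FALSE)
  }
  edge <- if (!is.null(surface$spec)) surface$spec$mesh_edge_target else 10
  for (nm in names(lm)) {
    d2 <- sqrt(rowSums(sweep(surface$vertices, 2, lm[[nm]])^2))
    if (min(d2) > edge) {
      stop(sprintf("landmark %s is %.1f mm from the nearest mesh vertex", nm,
                   min(d2)), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Uniformly scale a skull for head growth
#'
#' Scales vertices, landmarks and thickness about the frame origin by a
#' user-supplied growth factor (for example derived from ICV growth curves
#' between the imaging date and the day of surgery).
#'
#' @param surface a `skull_surface`.
#' @param factor positive scalar growth factor; linear dimensions scale by
#'   `factor`, enclosed volume by `factor^3`.
#' @return the scaled `skull_surface`.
#' @export
scale_for_growth <- function(surface, factor) {
  stopifnot(inherits(surface, "skull_surface"))
  if (!is.finite(factor) || factor <= 0) {
    stop("growth factor must be a positive number", call. = FALSE)
  }
  surface$vertices <- surface$vertices * factor
  surface$landmarks <- lapply(surface$landmarks, function(p) p * factor)
  surface$thickness <- surface$thickness * factor
  surface
}

#' Generate a synthetic SAPVE cohort
#'
#' Draws per-case skull extents from a seeded log-normal distribution around a
#' base specification and assigns procedure labels, emulating a cohort split
#' into the three SAPVE strategies: two top springs (T2), two lateral springs
#' (L2), or four springs (TL4).
#'
#' @param n_t2,n_l2,n_tl4 number of cases per procedure group.
#' @param base_spec the central [skull_spec()].
#' @param variability fractional standard deviation of the log-normal extent
#'   multipliers (0 gives identical skulls).
#' @param seed integer seed controlling both the extent draws and the per-case
#'   bump fields.
#' @return list of cases, each `list(surface =, procedure =, case_id =)`.
#' @export
generate_cohort <- function(n_t2, n_l2, n_tl4, base_spec = skull_spec(),
                            variability = 0.05, seed = 1L) {
  stopifnot(n_t2 >= 0, n_l2 >= 0, n_tl4 >= 0, variability >= 0)
  labels <- c(rep("T2", n_t2), rep("L2", n_l2), rep("TL4", n_tl4))
  n <- length(labels)
  if (n == 0L) return(list())
  mult <- with_seed(seed, matrix(exp(rnorm(3 * n, 0, variability)), n, 3))
  lapply(seq_len(n), function(i) {
    sp <- base_spec
    sp$length_ap <- base_spec$length_ap * mult[i, 1]
    sp$width_ml <- base_spec$width_ml * mult[i, 2]
    sp$height_cc <- base_spec$height_cc * mult[i, 3]
    sp$seed <- if (variability > 0) derive_seed(seed, i) else base_spec$seed
    list(surface = generate_skull(sp), procedure = labels[i],
         case_id = sprintf("case_%02d_%s", i, labels[i]))
  })
}
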