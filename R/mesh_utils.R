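# Small triangle-mesh utilities shared by the geometry and FE modules.
# Meshes are plain lists: `vertices` (n x 3, mm) and `faces` (m x 3, 1-based,
# consistently oriented outward).

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so package functions never disturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Fold an integer stream id into a user seed, staying inside 32-bit range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1009 + 97 * as.double(k)) %% 2147483647)
}

# undirected edge table of a face matrix: one row per half-edge
half_edges <- function(faces) {
  rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(3L, 1L)])
}

edge_keys <- function(e) {
  paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
}

# edges that belong to exactly one face (as directed half-edges)
boundary_half_edges <- function(faces) {
  he <- half_edges(faces)
  key <- edge_keys(he)
  cnt <- table(key)
  he[cnt[key] == 1L, , drop = FALSE]
}

#' Ordered boundary loops of an oriented triangle mesh
#'
#' @param faces m x 3 integer matrix of consistently oriented triangles.
#' @return list of integer vectors, each an ordered cycle of vertex indices.
#' @keywords internal
#' @noRd
boundary_loops <- function(faces) {
  be <- boundary_half_edges(faces)
  if (nrow(be) == 0L) return(list())
  nxt <- setNames(be[, 2L], as.character(be[, 1L]))
  if (anyDuplicated(be[, 1L])) {
    stop("mesh boundary is not a disjoint union of simple loops", call. = FALSE)
  }
  todo <- setNames(rep(TRUE, nrow(be)), as.character(be[, 1L]))
  loops <- list()
  while (any(todo)) {
    start <- as.integer(names(todo)[which(todo)[1L]])
    loop <- start
    todo[as.character(start)] <- FALSE
    v <- nxt[[as.character(start)]]
    while (v != start) {
      loop <- c(loop, v)
      todo[as.character(v)] <- FALSE
      v <- nxt[[as.character(v)]]
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

# TRUE if every edge is shared by at most two faces and orientation is
# consistent (no directed edge repeats).
mesh_is_manifold <- function(faces) {
  he <- half_edges(faces)
  if (anyDuplicated(paste(he[, 1L], he[, 2L]))) return(FALSE)
  key <- edge_keys(he)
  all(table(key) <= 2L)
}

# connected components of faces, where faces sharing a VERTEX are connected
# (vertex connectivity is what matters mechanically).  Returns an integer
# component label per face.
face_components <- function(faces, n_vertices = max(faces)) {
  parent <- seq_len(n_vertices)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(faces))) {
    a <- find(faces[r, 1L]); b <- find(faces[r, 2L]); c <- find(faces[r, 3L])
    parent[b] <- a
    parent[find(c)] <- a
  }
  roots <- vapply(faces[, 1L], find, integer(1))
  match(roots, unique(roots))
}

# area-weighted outward vertex normals
vertex_normals <- function(vertices, faces) {
  v1 <- vertices[faces[, 1L], , drop = FALSE]
  v2 <- vertices[faces[, 2L], , drop = FALSE]
  v3 <- vertices[faces[, 3L], , drop = FALSE]
  e1 <- v2 - v1
  e2 <- v3 - v1
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- matrix(0, nrow(vertices), 3)
  for (k in 1:3) {
    for (d in 1:3) {
      acc <- tapply(fn[, d], faces[, k], sum)
      idx <- as.integer(names(acc))
      n[idx, d] <- n[idx, d] + acc
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# drop vertices not referenced by any face; returns reindexed mesh plus the
# old->new index map (NA for dropped vertices)
drop_unused_vertices <- function(vertices, faces, keep_extra = integer(0)) {
  used <- sort(unique(c(as.vector(faces), keep_extra)))
  map <- rep(NA_integer_, nrow(vertices))
  map[used] <- seq_along(used)
  list(vertices = vertices[used, , drop = FALSE],
       faces = matrix(map[faces], ncol = 3L),
       map = map)
}

#' Signed volume enclosed by a closed oriented triangle mesh
#'
#' Divergence-theorem volume; positive for outward-oriented closed surfaces.
#' Used as an independent lower-bound oracle for convex-hull volumes.
#'
#' @param vertices n x 3 matrix (mm).
#' @param faces m x 3 integer matrix.
#' @return volume in ml (1 ml = 1000 mm^3).
#' @export
mesh_volume <- function(vertices, faces) {
  a <- vertices[faces[, 1L], , drop = FALSE]
  b <- vertices[faces[, 2L], , drop = FALSE]
  c3 <- vertices[faces[, 3L], , drop = FALSE]
  det6 <- a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
          a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
          a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  sum(det6) / 6 / 1000
}

# 2D point-in-polygon (ray casting); poly is k x 2, closed implicitly
point_in_polygon <- function(pt, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if (((yi > pt[2]) != (yj > pt[2])) &&
        (pt[1] < (xj - xi) * (pt[2] - yi) / (yj - yi) + xi)) {
      inside <- !inside
    }
    j <- i
  }
  inside
}
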