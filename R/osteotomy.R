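# Parametrized osteotomy and spring-notch placement.
#
# The osteotomy is modelled as a planar cut extruded along the medio-lateral
# axis: in the sagittal (x-y) plane its trace is the straight line through the
# bottom end (L, H), inclined at alpha to the horizontal and rising
# anteriorly (at alpha = 90 deg the cut is coronal).  Faces whose vertex span
# crosses the kerf slab on the over-the-vertex branch of the trace are
# removed, from one bottom end up over the vertex and down to the mirrored
# bottom end.  The freed posterior segment stays hinged to the intact shell
# below the bottom ends, which is what anchors it besides the fixed
# foramen-magnum rim.

#' Osteotomy parameters
#'
#' @param L anterior-posterior position of the osteotomy bottom end on the
#'   horizontal axis, mm (positive towards the back of the skull).
#' @param H cranio-caudal position of the bottom end on the vertical axis, mm
#'   (positive towards the cranial side).
#' @param alpha angle between the osteotomy and the horizontal plane, degrees
#'   (the trace rises anteriorly from the bottom end; 90 is a coronal cut).
#' @param kerf width of the cut slab, mm; faces crossing it are removed.
#' @return object of class `osteotomy_params`.
#' @export
osteotomy_params <- function(L, H, alpha, kerf = 2) {
  if (!is.finite(kerf) || kerf <= 0) stop("kerf must be positive", call. = FALSE)
  stopifnot(is.finite(L), is.finite(H), is.finite(alpha))
  if (L <= 0 || H <= 0) {
    stop("osteotomy bottom-end offsets L and H must be positive", call. = FALSE)
  }
  structure(list(L = L, H = H, alpha = alpha, kerf = kerf),
            class = "osteotomy_params")
}

#' Spring placement descriptor
#'
#' Describes one spring straddling the osteotomy.  Top springs are placed at a
#' distance `offset` (S_T) from the midline plane along the cut rim and always
#' come as a midline-symmetric pair; lateral springs are placed at a distance
#' `offset` (S_L) from the bottom end of the osteotomy along the rim (positive
#' towards the front of the skull).
#'
#' @param kind `"top"` or `"lateral"`.
#' @param offset S_T or S_L, mm.
#' @param spring_model one of `"S10"`, `"S12"`, `"S14"`.
#' @param side `+1` (right) or `-1` (left).
#' @return object of class `spring_placement`.
#' @export
spring_placement <- function(kind = c("top", "lateral"), offset,
                             spring_model = "S12", side = 1L) {
  kind <- match.arg(kind)
  stopifnot(is.finite(offset), side %in% c(-1L, 1L))
  if (offset < 0) {
    stop("spring placement offset must be non-negative", call. = FALSE)
  }
  spring_model <- match.arg(spring_model, c("S10", "S12", "S14"))
  structure(list(kind = kind, offset = offset, spring_model = spring_model,
                 side = as.integer(side)),
            class = "spring_placement")
}

#' Standard spring placements for a SAPVE procedure
#'
#' @param procedure `"T2"` (two top springs), `"L2"` (two lateral springs) or
#'   `"TL4"` (two top plus two lateral).
#' @param s_t top-spring distance from the midline plane, mm.
#' @param s_l lateral-spring distance from the osteotomy bottom end, mm.
#' @param spring_model spring model used for every spring of the case.
#' @return list of [spring_placement()] objects.
#' @export
procedure_placements <- function(procedure = c("T2", "L2", "TL4"),
                                 s_t = 25, s_l = 15, spring_model = "S12") {
  procedure <- match.arg(procedure)
  top <- list(spring_placement("top", s_t, spring_model, side = 1L),
              spring_placement("top", s_t, spring_model, side = -1L))
  lat <- list(spring_placement("lateral", s_l, spring_model, side = 1L),
              spring_placement("lateral", s_l, spring_model, side = -1L))
  switch(procedure, T2 = top, L2 = lat, TL4 = c(top, lat))
}

#' Apply a parametrized osteotomy to an aligned skull
#'
#' Removes the kerf band of faces along the cut path (from the bottom end at
#' `(L, H)` on one side, up over the vertex, down to the mirrored bottom end)
#' and classifies the remaining faces into an anterior and a posterior region
#' by their side of the cut plane.  The freed posterior segment stays hinged
#' to the intact shell below the bottom ends, matching the surgical situation
#' in which the skull base is never cut.
#'
#' @param surface an aligned `skull_surface` (see [align_to_frame()]).
#' @param params an [osteotomy_params()].
#' @return object of class `cut_skull`: `vertices`, `faces` (remaining),
#'   `region` (factor `anterior`/`posterior` per face), `removed_faces`,
#'   original `n_faces_original`, `notch_pairs` (empty until
#'   [place_springs()]), bottom-end positions and cut-frame metadata.
#' @export
apply_osteotomy <- function(surface, params) {
  stopifnot(inherits(surface, "skull_surface"), inherits(params, "osteotomy_params"))
  V <- surface$vertices
  lm <- surface$landmarks
  if (sqrt(sum(lm$meatus_left^2)) > 1e-6) {
    stop("surface must be aligned to the anatomical frame first", call. = FALSE)
  }
  z_mid <- (lm$meatus_left[3] + lm$meatus_right[3]) / 2
  arad <- params$alpha * pi / 180
  # sagittal trace rises anteriorly from the bottom end (clockwise-positive
  # angle seen from the right); at alpha = 90 deg the cut is coronal
  that <- c(-cos(arad), sin(arad))
  nhat <- c(sin(arad), cos(arad))        # posterior side of the cut is d > 0
  p0 <- c(params$L, params$H)

  # the bottom end must project onto the sagittal silhouette of the shell
  sil <- grDevices::chull(V[, 1], V[, 2])
  if (!point_in_polygon(p0, cbind(V[sil, 1], V[sil, 2]))) {
    stop("osteotomy bottom end (L, H) lies outside the skull silhouette",
         call. = FALSE)
  }

  d <- (V[, 1] - p0[1]) * nhat[1] + (V[, 2] - p0[2]) * nhat[2]
  s <- (V[, 1] - p0[1]) * that[1] + (V[, 2] - p0[2]) * that[2]
  F <- surface$faces
  dmin <- pmin(d[F[, 1]], d[F[, 2]], d[F[, 3]])
  dmax <- pmax(d[F[, 1]], d[F[, 2]], d[F[, 3]])
  smin <- pmin(s[F[, 1]], s[F[, 2]], s[F[, 3]])
  smax <- pmax(s[F[, 1]], s[F[, 2]], s[F[, 3]])
  crossing <- dmin < params$kerf / 2 & dmax > -params$kerf / 2
  band <- crossing & smin >= 0
  # faces crossed by the cut plane that straddle the bottom-end cutoff are
  # only partially severed: they keep a thickness fraction proportional to
  # the part of their extent below the bottom ends, which makes the hinge
  # position (and hence the response) continuous in L, H and alpha
  partial <- crossing & smin < 0 & smax > 0
  frac_above <- ifelse(smax > smin, smax / (smax - smin), 0)

  if (!any(band)) {
    stop("osteotomy does not intersect the shell: check L, H, alpha",
         call. = FALSE)
  }

  keep_faces <- F[!band, , drop = FALSE]
  removed <- which(band)
  zrel <- V[, 3] - z_mid
  band_verts <- unique(as.vector(F[band, , drop = FALSE]))
  bottom_ends <- list()
  for (side in c(1, -1)) {
    bv <- band_verts[side * zrel[band_verts] > 0]
    if (length(bv) == 0L) {
      stop("osteotomy band does not reach both lateral sides", call. = FALSE)
    }
    bottom_ends[[if (side > 0) "right" else "left"]] <- V[bv[which.min(s[bv])], ]
  }

  # hinged cut: the shell stays continuous below the bottom ends; the two
  # regions are the sides of the cut plane (face sets disjoint and connected,
  # mechanically joined along the hinge)
  faces2 <- keep_faces
  face_scale <- rep(1, nrow(faces2))
  face_scale[partial[!band]] <- pmax(1 - frac_above[!band][partial[!band]], 0.02)
  if (max(face_components(faces2, nrow(V))) != 1L) {
    stop(paste("osteotomy disconnected the shell: L/H/alpha outside the",
               "feasible band"), call. = FALSE)
  }
  dcen <- (d[faces2[, 1]] + d[faces2[, 2]] + d[faces2[, 3]]) / 3
  region <- factor(ifelse(dcen > 0, "posterior", "anterior"),
                   levels = c("anterior", "posterior"))
  if (any(table(region) == 0L)) {
    stop("cut leaves an empty region: L/H/alpha outside the feasible band",
         call. = FALSE)
  }

  structure(list(vertices = V, faces = faces2, region = region,
                 face_scale = face_scale,
                 removed_faces = removed, n_faces_original = nrow(F),
                 notch_pairs = list(),
                 bottom_ends = bottom_ends,
                 landmarks = lm, foramen_loop = surface$foramen_loop,
                 thickness = surface$thickness, params = params,
                 z_mid = z_mid, that = that, nhat = nhat, spec = surface$spec),
            class = "cut_skull")
}

#' @export
print.cut_skull <- function(x, ...) {
  cat(sprintf(paste0("<cut_skull> %d faces kept (%d anterior / %d posterior), ",
                     "%d removed; %d spring notch pair(s)\n"),
              nrow(x$faces), sum(x$region == "anterior"),
              sum(x$region == "posterior"), length(x$removed_faces),
              length(x$notch_pairs)))
  invisible(x)
}

# boundary vertices of one region that are not on the foramen loop (cut rim)
region_rim <- function(cut, which_region) {
  f <- cut$faces[cut$region == which_region, , drop = FALSE]
  rim <- unique(as.vector(boundary_half_edges(f)))
  setdiff(rim, cut$foramen_loop)
}

# greedy walk along the rim graph (boundary edges restricted to `rim`),
# starting at `start`; among branch choices the first step maximizes
# `dir_score`, later steps prefer the straightest continuation
rim_walk <- function(V, edges, rim, start, dir_score) {
  inrim <- edges[, 1L] %in% rim & edges[, 2L] %in% rim
  e <- edges[inrim, , drop = FALSE]
  adj <- list()
  for (r in seq_len(nrow(e))) {
    a <- as.character(e[r, 1L]); b <- as.character(e[r, 2L])
    adj[[a]] <- c(adj[[a]], e[r, 2L])
    adj[[b]] <- c(adj[[b]], e[r, 1L])
  }
  chain <- start
  visited <- start
  repeat {
    cur <- chain[length(chain)]
    nb <- setdiff(unique(adj[[as.character(cur)]]), visited)
    if (length(nb) == 0L) break
    if (length(chain) == 1L) {
      sc <- vapply(nb, function(v) dir_score(V[v, ] - V[cur, ]), numeric(1))
      nxt <- nb[which.max(sc)]
    } else {
      prevdir <- V[cur, ] - V[chain[length(chain) - 1L], ]
      prevdir <- prevdir / sqrt(sum(prevdir^2))
      sc <- vapply(nb, function(v) {
        d <- V[v, ] - V[cur, ]
        sum(d * prevdir) / sqrt(sum(d^2))
      }, numeric(1))
      nxt <- nb[which.max(sc)]
    }
    chain <- c(chain, nxt)
    visited <- c(visited, nxt)
  }
  chain
}

# walk along an ordered polyline from its first point, returning the point at
# arc-length `dist`, or NULL if the polyline is shorter than `dist`
walk_polyline <- function(pts, dist) {
  if (dist <= 0) return(pts[1L, ])
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  cum <- cumsum(seg)
  if (dist > cum[length(cum)]) return(NULL)
  i <- which(cum >= dist)[1L]
  prev <- if (i == 1L) 0 else cum[i - 1L]
  frac <- (dist - prev) / seg[i]
  pts[i, ] + frac * (pts[i + 1L, ] - pts[i, ])
}

#' Place spring notches on a cut skull
#'
#' Realizes each [spring_placement()] as a pair of notch vertices, one on the
#' anterior and one on the posterior rim of the osteotomy, nearest to the
#' placement's target point: top targets sit at arc-length S_T from the
#' midline along the cut rim (one per side for the symmetric pair), lateral
#' targets at arc-length S_L from the osteotomy bottom end.
#'
#' @param cut a `cut_skull`.
#' @param placements list of [spring_placement()]s, e.g. from
#'   [procedure_placements()].
#' @return the `cut_skull` with `notch_pairs` filled: each element holds
#'   `anterior`, `posterior` (vertex ids), `spring_model`, `kind`, `offset`,
#'   `side`.
#' @export
place_springs <- function(cut, placements) {
  stopifnot(inherits(cut, "cut_skull"))
  if (inherits(placements, "spring_placement")) placements <- list(placements)
  tops <- Filter(function(p) p$kind == "top", placements)
  if (length(tops) > 0) {
    offs <- unique(vapply(tops, `[[`, numeric(1), "offset"))
    sides <- sort(vapply(tops, `[[`, integer(1), "side"))
    if (length(offs) != 1L || !identical(sides, c(-1L, 1L))) {
      stop("top springs must form a midline-symmetric pair sharing one offset",
           call. = FALSE)
    }
  }
  V <- cut$vertices
  rim_a <- region_rim(cut, "anterior")
  rim_p <- region_rim(cut, "posterior")
  hinge <- intersect(rim_a, rim_p)  # shared border in the hinged variant
  rim_a <- setdiff(rim_a, hinge)
  rim_p <- setdiff(rim_p, hinge)
  zrel <- V[, 3] - cut$z_mid

  # rim graph: boundary edges of the anterior region between cut-rim vertices
  f_a <- cut$faces[cut$region == "anterior", , drop = FALSE]
  be_a <- boundary_half_edges(f_a)
  svals <- (V[, 1] - cut$params$L) * cut$that[1] +
    (V[, 2] - cut$params$H) * cut$that[2]

  pairs <- list()
  for (p in placements) {
    if (p$kind == "top") {
      # start at the topmost near-midline rim vertex, walk towards p$side
      top0 <- rim_a[which.min(abs(zrel[rim_a]) - 1e-6 * V[rim_a, 2])]
      chain <- rim_walk(V, be_a, rim_a, top0,
                        dir_score = function(d) p$side * d[3])
      if (length(chain) < 2L) stop("cut rim too short for top placement", call. = FALSE)
      target <- walk_polyline(V[chain, , drop = FALSE], abs(p$offset))
    } else {
      # lateral spring: arc-distance |S_L| from the osteotomy bottom end,
      # walking up the main cut rim on that side (negative offsets walk down
      # the basal relief slit instead)
      key <- if (p$side > 0) "right" else "left"
      bottom <- cut$bottom_ends[[key]]
      if (p$offset < 0) {
        stop(paste("lateral spring offset must be non-negative: the osteotomy",
                   "ends at its bottom end"), call. = FALSE)
      } else {
        side_rim <- rim_a[p$side * zrel[rim_a] > 0]
        if (length(side_rim) < 2L) {
          stop("cut rim too short for lateral placement", call. = FALSE)
        }
        start <- side_rim[which.min(rowSums(sweep(V[side_rim, , drop = FALSE],
                                                  2, bottom)^2))]
        chain <- rim_walk(V, be_a, side_rim, start,
                          dir_score = function(d) sum(d[1:2] * cut$that))
        target <- walk_polyline(V[chain, , drop = FALSE], p$offset)
      }
    }
    if (is.null(target)) {
      stop("spring placement offset runs beyond the cut rim extent", call. = FALSE)
    }
    da <- sqrt(rowSums(sweep(V[rim_a, , drop = FALSE], 2, target)^2))
    if (min(da) > 10) {
      stop(sprintf("spring notch target is %.1f mm from the nearest rim vertex",
                   min(da)), call. = FALSE)
    }
    ia <- rim_a[order(da, rim_a)][1L]   # ties broken by lowest vertex index
    # partner notch: nearest posterior-rim vertex across the kerf
    dp <- sqrt(rowSums(sweep(V[rim_p, , drop = FALSE], 2, V[ia, ])^2))
    ip <- rim_p[order(dp, rim_p)][1L]
    gap <- sqrt(sum((V[ia, ] - V[ip, ])^2))
    if (gap < cut$params$kerf / 2) {
      stop("notch pair does not straddle the kerf; move the placement", call. = FALSE)
    }
    # smooth anchors: the spring tip acts at a virtual point interpolated
    # over nearby rim vertices, so notch positions vary continuously with
    # the placement parameters instead of snapping vertex to vertex
    anchor <- function(rim, dd) {
      h <- max(stats::median(sort(dd)[1:min(4, length(dd))]), 2)
      keep <- dd <= min(dd) + 2 * h
      w <- exp(-((dd[keep] - min(dd)) / h)^2)
      list(nodes = rim[keep], w = w / sum(w))
    }
    aa <- anchor(rim_a, da)
    dpt <- sqrt(rowSums(sweep(V[rim_p, , drop = FALSE], 2, target)^2))
    pp <- anchor(rim_p, dpt)
    pairs[[length(pairs) + 1L]] <-
      list(anterior = ia, posterior = ip,
           anterior_nodes = aa$nodes, anterior_w = aa$w,
           posterior_nodes = pp$nodes, posterior_w = pp$w,
           spring_model = p$spring_model,
           kind = p$kind, offset = p$offset, side = p$side)
  }
  cut$notch_pairs <- pairs
  cut
}

#' Patient-specific surgical parameter space
#'
#' Variation bounds follow the study design: L and H vary by +/-10% of the
#' total skull length and height, alpha by +/-20% of its baseline magnitude,
#' and each spring offset is allowed a 3-cm movement (+/-15 mm) with the top
#' pair linked symmetrically.  T2 and L2 procedures give a 4-parameter space,
#' TL4 a 5-parameter one.
#'
#' @param surface the aligned `skull_surface`.
#' @param baseline list with elements `params` (an [osteotomy_params()]) and
#'   `placements` (list of [spring_placement()]s).
#' @param procedure `"T2"`, `"L2"` or `"TL4"`.
#' @return object of class `parameter_space`: data frame `bounds` with
#'   columns name/lower/upper/units/baseline plus linkage metadata.
#' @export
build_parameter_space <- function(surface, baseline,
                                  procedure = c("T2", "L2", "TL4")) {
  procedure <- match.arg(procedure)
  stopifnot(inherits(surface, "skull_surface"),
            inherits(baseline$params, "osteotomy_params"))
  ap_length <- diff(range(surface$vertices[, 1]))
  height <- max(surface$vertices[, 2])
  if (ap_length <= 0 || height <= 1e-9) {
    stop("degenerate skull extents: cannot build parameter bounds", call. = FALSE)
  }
  b <- baseline$params
  alpha_hw <- 0.20 * abs(b$alpha)
  if (alpha_hw == 0) {
    warning("baseline alpha is 0; falling back to an absolute +/-10 degree interval")
    alpha_hw <- 10
  }
  rows <- data.frame(
    name = c("L", "H", "alpha"),
    lower = c(b$L - 0.10 * ap_length, b$H - 0.10 * height, b$alpha - alpha_hw),
    upper = c(b$L + 0.10 * ap_length, b$H + 0.10 * height, b$alpha + alpha_hw),
    units = c("mm", "mm", "deg"),
    baseline = c(b$L, b$H, b$alpha),
    stringsAsFactors = FALSE)
  offs <- function(kind) {
    pl <- Filter(function(p) p$kind == kind, baseline$placements)
    if (length(pl) == 0) NULL else pl[[1L]]$offset
  }
  if (procedure %in% c("T2", "TL4")) {
    st <- offs("top")
    if (is.null(st)) stop("baseline is missing the top spring placement", call. = FALSE)
    rows <- rbind(rows, data.frame(name = "S_T", lower = st - 15, upper = st + 15,
                                   units = "mm", baseline = st))
  }
  if (procedure %in% c("L2", "TL4")) {
    sl <- offs("lateral")
    if (is.null(sl)) stop("baseline is missing the lateral spring placement", call. = FALSE)
    rows <- rbind(rows, data.frame(name = "S_L", lower = sl - 15, upper = sl + 15,
                                   units = "mm", baseline = sl))
  }
  stopifnot(all(rows$lower < rows$upper))
  structure(list(bounds = rows, procedure = procedure,
                 linkage = "top springs move symmetrically (one shared S_T)"),
            class = "parameter_space")
}

#' @export
print.parameter_space <- function(x, ...) {
  cat(sprintf("<parameter_space> %s, %d parameters\n", x$procedure, nrow(x$bounds)))
  print(x$bounds, row.names = FALSE)
  invisible(x)
}
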