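#' Convex-hull volume of a 3D point set
#'
#' Computes the convex hull of the points, tessellates it into
#' non-overlapping simplices (tetrahedra fanned from the hull-vertex
#' centroid) and sums the simplex volumes
#' \eqn{|\det(v_1-v_0, v_2-v_0, v_3-v_0)|/3!}. The facet extraction is
#' an incremental hull in compiled code; the volume sum itself is done
#' here so it can be cross-checked against independent integration.
#'
#' @param points n x 3 numeric matrix (n >= 4, not all coplanar).
#' @return list with `volume` (Angstrom^3), `faces` (m x 3 matrix of
#'   1-based vertex indices into `points`, outward-oriented),
#'   `simplices` (m x 4 matrix: each facet plus the centroid index 0),
#'   `vertices` (indices of hull vertices), and `centroid` (the fan
#'   apex used for the tessellation).
#' @export
convex_hull_volume <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must be an n x 3 matrix")
  if (nrow(points) < 4) stop("need at least 4 points for a 3D hull")
  if (!all(is.finite(points))) stop("non-finite points")
  h <- hull3d_cpp(points)
  faces <- h$faces
  vidx <- h$vertices
  ctr <- colMeans(points[vidx, , drop = FALSE])
  # Eq.-style simplex sum: fan of tetrahedra (ctr, v0, v1, v2)
  v0 <- points[faces[, 1], , drop = FALSE]
  e1 <- points[faces[, 2], , drop = FALSE] - v0
  e2 <- points[faces[, 3], , drop = FALSE] - v0
  e0 <- sweep(v0, 2, ctr)  # v0 - ctr
  dets <- e0[, 1] * (e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]) -
          e0[, 2] * (e1[, 1] * e2[, 3] - e1[, 3] * e2[, 1]) +
          e0[, 3] * (e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  vol <- sum(abs(dets)) / factorial(3)
  list(volume = vol, faces = faces,
       simplices = cbind(0L, faces),
       vertices = vidx, centroid = ctr)
}

#' Test points for hull membership
#'
#' @param hull result of [convex_hull_volume()].
#' @param points the point matrix the hull was built from.
#' @param query m x 3 matrix of query points.
#' @param tol plane tolerance in Angstrom.
#' @return logical vector: query point inside (or on) the hull.
#' @export
in_hull <- function(hull, points, query, tol = 1e-9) {
  query <- as.matrix(query)
  inside <- rep(TRUE, nrow(query))
  for (f in seq_len(nrow(hull$faces))) {
    tri <- hull$faces[f, ]
    a <- points[tri[1], ]
    nrm <- cross3(points[tri[2], ] - a, points[tri[3], ] - a)
    d <- (query %*% nrm) - sum(nrm * a)
    inside <- inside & (d <= tol * sqrt(sum(nrm^2)) + tol)
  }
  inside
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Per-frame convex-hull volume change of a fibril
#'
#' Volume change of each frame relative to a fixed reference, using the
#' chitosan heavy atoms (selection configurable). The reference defaults
#' to the first frame of the trajectory when no reference structure is
#' given; with MD data the energy-minimized start structure is the
#' natural reference.
#'
#' @param traj a `cf_trajectory`.
#' @param reference optional `cf_structure` providing the reference V0.
#' @param sel optional logical atom selection (default: chitosan heavy
#'   atoms).
#' @return data.frame with columns `frame`, `volume`, `delta_volume`
#'   (Angstrom^3), plus attribute `v0`.
#' @export
delta_volume <- function(traj, reference = NULL, sel = NULL) {
  if (is.null(sel)) {
    sel <- traj$atoms$resname != "HOH" & guess_element(traj$atoms$name) != "H"
  }
  if (is.null(reference)) {
    v0 <- convex_hull_volume(traj$frames[[1]][sel, , drop = FALSE])$volume
  } else {
    rsel <- is_heavy(reference) & !is_water(reference)
    v0 <- convex_hull_volume(coords(reference, rsel))$volume
  }
  vols <- vapply(seq_along(traj$frames), function(i) {
    convex_hull_volume(traj$frames[[i]][sel, , drop = FALSE])$volume
  }, numeric(1))
  out <- data.frame(frame = seq_along(vols), volume = vols,
                    delta_volume = vols - v0)
  attr(out, "v0") <- v0
  out
}

#' Chain end-to-end distance
#'
#' Distance between the O4 atoms of the first and last glucosamine unit
#' of a chain, per frame, with the chain contour length (sum of
#' consecutive O4-O4 separations in the same frame) for context.
#'
#' @param traj a `cf_trajectory` (or `cf_structure` for one frame).
#' @param chain chain id.
#' @return data.frame with columns `frame`, `chain`, `end_to_end`,
#'   `contour` (Angstrom).
#' @export
end_to_end <- function(traj, chain) {
  if (inherits(traj, "cf_structure")) {
    traj <- new_trajectory(traj$atoms, list(coords(traj)), traj$box)
  }
  a <- traj$atoms
  o4 <- which(a$chain == chain & a$name == "O4")
  if (length(o4) < 2) stop("chain ", chain, " lacks terminal O4 atoms")
  o4 <- o4[order(a$resid[o4])]
  res <- a$resid[o4]
  i1 <- o4[1]; i2 <- o4[length(o4)]
  out <- lapply(seq_along(traj$frames), function(f) {
    m <- traj$frames[[f]]
    p <- m[o4, , drop = FALSE]
    seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
    data.frame(frame = f, chain = chain,
               end_to_end = sqrt(sum((m[i2, ] - m[i1, ])^2)),
               contour = sum(seg))
  })
  do.call(rbind, out)
}

#' Root mean square fluctuation per atom
#'
#' Frames are rigid-body superposed (Kabsch) onto the mean structure of
#' the selection; the mean is then recomputed once and RMSF_i =
#' sqrt(mean_f |r_i(f) - <r_i>|^2).
#'
#' @param traj a `cf_trajectory` with at least 2 frames.
#' @param sel logical or integer atom selection (default: chitosan heavy
#'   atoms).
#' @param superpose superpose frames before computing fluctuations
#'   (default TRUE).
#' @return data.frame with columns `atom` (index into the atom table),
#'   `name`, `chain`, `resid`, `rmsf` (Angstrom).
#' @export
atomic_rmsf <- function(traj, sel = NULL, superpose = TRUE) {
  if (length(traj$frames) < 2) stop("RMSF needs at least 2 frames")
  if (is.null(sel)) {
    sel <- which(traj$atoms$resname != "HOH" &
                 guess_element(traj$atoms$name) != "H")
  } else if (is.logical(sel)) sel <- which(sel)
  if (length(sel) == 0) stop("empty atom selection")
  mats <- lapply(traj$frames, function(m) m[sel, , drop = FALSE])
  if (superpose) {
    ref <- Reduce(`+`, mats) / length(mats)
    mats <- lapply(mats, kabsch_fit, ref = ref)
    ref <- Reduce(`+`, mats) / length(mats)   # recompute mean once
  } else {
    ref <- Reduce(`+`, mats) / length(mats)
  }
  ss <- Reduce(`+`, lapply(mats, function(m) rowSums((m - ref)^2)))
  data.frame(atom = sel,
             name = traj$atoms$name[sel],
             chain = traj$atoms$chain[sel],
             resid = traj$atoms$resid[sel],
             rmsf = sqrt(ss / length(mats)))
}

# Kabsch superposition of m onto ref (both n x 3); returns transformed m.
kabsch_fit <- function(m, ref) {
  cm <- colMeans(m); cr <- colMeans(ref)
  A <- crossprod(sweep(m, 2, cm), sweep(ref, 2, cr))
  sv <- svd(A)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(sweep(m, 2, cm) %*% t(R), 2, cr, FUN = "+")
}

#' Sheet-sheet stacking distance
#'
#' Distance between the centres of mass of the middle chains of sheets 2
#' and 3, per frame. With an even number of chains per sheet the mean of
#' the two central chains' COMs is used.
#'
#' @param traj a `cf_trajectory` (or `cf_structure`).
#' @param topology a `cf_topology` with at least 4 sheets.
#' @return data.frame with columns `frame`, `stacking_distance` (Angstrom).
#' @export
sheet_stacking_distance <- function(traj, topology) {
  if (topology$n_sheets < 4) stop("stacking distance needs at least 4 sheets")
  if (inherits(traj, "cf_structure")) {
    traj <- new_trajectory(traj$atoms, list(coords(traj)), traj$box)
  }
  heavy <- traj$atoms$resname != "HOH" & guess_element(traj$atoms$name) != "H"
  mid_idx <- middle_chain_atoms(traj$atoms, topology, heavy)
  out <- vapply(seq_along(traj$frames), function(f) {
    m <- traj$frames[[f]]
    c2 <- colMeans(m[mid_idx$s2, , drop = FALSE])
    c3 <- colMeans(m[mid_idx$s3, , drop = FALSE])
    sqrt(sum((c3 - c2)^2))
  }, numeric(1))
  data.frame(frame = seq_along(out), stacking_distance = out)
}

middle_chain_atoms <- function(atoms, topology, heavy) {
  mid_of <- function(sheet) {
    ch <- topology$chain_ids[topology$chain_to_sheet == sheet]
    pos <- topology$chain_pos[ch]
    k <- length(ch)
    mids <- if (k %% 2 == 1) ch[order(pos)][(k + 1) / 2] else
      ch[order(pos)][c(k / 2, k / 2 + 1)]
    which(atoms$chain %in% mids & heavy)
  }
  list(s2 = mid_of(2L), s3 = mid_of(3L))
}

#' Fibril dimension along the sheet-growth direction
#'
#' Heavy-atom extent along x per frame (the fibril must be in its
#' canonical orientation; see [orient_fibril()]).
#'
#' @param traj a `cf_trajectory` (or `cf_structure`).
#' @param topology a `cf_topology` (restricts to chitosan atoms).
#' @return data.frame with columns `frame`, `growth_dimension` (Angstrom).
#' @export
sheet_growth_dimension <- function(traj, topology = NULL) {
  if (inherits(traj, "cf_structure")) {
    traj <- new_trajectory(traj$atoms, list(coords(traj)), traj$box)
  }
  sel <- traj$atoms$resname != "HOH" & guess_element(traj$atoms$name) != "H"
  out <- vapply(seq_along(traj$frames), function(f) {
    x <- traj$frames[[f]][sel, 1]
    max(x) - min(x)
  }, numeric(1))
  data.frame(frame = seq_along(out), growth_dimension = out)
}
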