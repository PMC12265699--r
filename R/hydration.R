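#' Classify waters as bound, bulk or neither
#'
#' A water is *bound* when its oxygen lies within `bound_cutoff` of any
#' chitosan heavy atom and *bulk* when it is at least `bulk_cutoff` away
#' from every chitosan heavy atom; anything in between is `neither`.
#'
#' @param frame a `cf_structure` containing waters (resname `HOH`).
#' @param topology a `cf_topology` (interior flag needs >= 4 sheets).
#' @param bound_cutoff bound-shell radius in Angstrom (default 3.5).
#' @param bulk_cutoff bulk distance in Angstrom (default 10).
#' @return data.frame with one row per water: `water` (residue id),
#'   `oxygen` (atom index), `min_dist` (Angstrom), `class` in
#'   \{bound, bulk, neither\}, and `interior` (logical; water lies in the
#'   slab between the interior sheets, `NA` when < 4 sheets).
#' @export
assign_waters <- function(frame, topology, bound_cutoff = 3.5,
                          bulk_cutoff = 10) {
  if (bound_cutoff >= bulk_cutoff) stop("bound cutoff must be below bulk cutoff")
  wat_o <- which(is_water(frame) & frame$atoms$name == "O")
  if (length(wat_o) == 0) stop("no waters present")
  chit <- which(!is_water(frame) & is_heavy(frame))
  xyz <- coords(frame)
  dmin <- min_dist_to_set(xyz[wat_o, , drop = FALSE],
                          xyz[chit, , drop = FALSE], frame$box)
  cls <- ifelse(dmin < bound_cutoff, "bound",
                ifelse(dmin >= bulk_cutoff, "bulk", "neither"))
  interior <- if (topology$n_sheets >= 4) {
    slab <- interior_slab(frame, topology)
    in_slab(xyz[wat_o, , drop = FALSE], slab)
  } else NA
  data.frame(water = frame$atoms$resid[wat_o], oxygen = wat_o,
             min_dist = dmin, class = cls, interior = interior)
}

# Minimum distance from each point of `q` to the point set `ref`.
min_dist_to_set <- function(q, ref, box = NULL) {
  out <- numeric(nrow(q))
  chunk <- 512L
  for (lo in seq(1L, nrow(q), by = chunk)) {
    hi <- min(lo + chunk - 1L, nrow(q))
    ii <- lo:hi
    d2 <- matrix(0, length(ii), nrow(ref))
    for (k in 1:3) {
      dx <- outer(q[ii, k], ref[, k], "-")
      if (!is.null(box)) dx <- dx - box[k] * round(dx / box[k])
      d2 <- d2 + dx * dx
    }
    out[ii] <- sqrt(apply(d2, 1, min))
  }
  out
}

# Geometric slab between the centre-of-mass y-planes of sheets 2 and 3,
# restricted to the padded xz bounding rectangle of those two sheets.
interior_slab <- function(frame, topology, pad = 2) {
  if (topology$n_sheets < 4) stop("interior sheets need at least 4 sheets")
  heavy <- is_heavy(frame) & !is_water(frame)
  xyz <- coords(frame)
  sheet_of <- topology$chain_to_sheet[frame$atoms$chain]
  i2 <- which(heavy & sheet_of == 2)
  i3 <- which(heavy & sheet_of == 3)
  y2 <- mean(xyz[i2, 2]); y3 <- mean(xyz[i3, 2])
  both <- c(i2, i3)
  list(ylo = min(y2, y3), yhi = max(y2, y3),
       xlo = min(xyz[both, 1]) - pad, xhi = max(xyz[both, 1]) + pad,
       zlo = min(xyz[both, 3]) - pad, zhi = max(xyz[both, 3]) + pad)
}

in_slab <- function(p, slab) {
  p[, 2] > slab$ylo & p[, 2] < slab$yhi &
    p[, 1] > slab$xlo & p[, 1] < slab$xhi &
    p[, 3] > slab$zlo & p[, 3] < slab$zhi
}

#' Count waters between the two interior sheets
#'
#' Waters whose oxygen lies in the slab bounded by the centre-of-mass
#' y-planes of sheets 2 and 3, restricted to the padded xz bounding
#' footprint of those sheets. An H-bond based alternative is available
#' via `method = "hbond"`: waters simultaneously H-bonded to both
#' interior sheets.
#'
#' @param traj a `cf_trajectory` (or `cf_structure`).
#' @param topology a `cf_topology` with >= 4 sheets.
#' @param method `"slab"` (default, geometric) or `"hbond"`.
#' @param criteria [hbond_criteria()] for `method = "hbond"`.
#' @return data.frame with columns `frame`, `n_interior`.
#' @export
interior_water_count <- function(traj, topology, method = c("slab", "hbond"),
                                 criteria = hbond_criteria()) {
  method <- match.arg(method)
  if (topology$n_sheets < 4) stop("interior water needs at least 4 sheets")
  if (inherits(traj, "cf_structure")) {
    traj <- new_trajectory(traj$atoms, list(coords(traj)), traj$box)
  }
  out <- vapply(seq_len(n_frames(traj)), function(f) {
    fr <- get_frame(traj, f)
    wat_o <- which(is_water(fr) & fr$atoms$name == "O")
    if (length(wat_o) == 0) return(0L)
    if (method == "slab") {
      slab <- interior_slab(fr, topology)
      sum(in_slab(coords(fr)[wat_o, , drop = FALSE], slab))
    } else {
      br <- detect_water_bridges(fr, criteria, topology,
                                 restrict = "inter_sheet")
      if (nrow(br) == 0) return(0L)
      sheets <- cbind(topology$chain_to_sheet[br$chain1],
                      topology$chain_to_sheet[br$chain2])
      length(unique(br$water[rowSums(sheets == 2) > 0 &
                             rowSums(sheets == 3) > 0]))
    }
  }, integer(1))
  data.frame(frame = seq_along(out), n_interior = out)
}

#' Detect water-bridged hydrogen bonds
#'
#' A water bridge is a single water simultaneously hydrogen-bonded (as
#' donor or acceptor) to two chitosan atoms. A water bonded to n
#' chitosan partners yields choose(n, 2) bridges; each unordered partner
#' pair is counted once per water per frame. The bridge category comes
#' from the two partners' topology: different sheets -> `inter_sheet`,
#' same sheet different chains -> `intra_sheet`, same chain ->
#' `intra_chain`.
#'
#' @param frame a `cf_structure`.
#' @param criteria a [hbond_criteria()].
#' @param topology a `cf_topology`.
#' @param restrict optional category filter: `"inter_sheet"`,
#'   `"intra_sheet"`, `"intra_chain"` or `NULL` (all).
#' @param events optional precomputed event table for this frame.
#' @return data.frame with columns `water` (residue id), `atom1`,
#'   `atom2` (chitosan partner atom indices, atom1 < atom2), `chain1`,
#'   `chain2`, `category`.
#' @export
detect_water_bridges <- function(frame, criteria = hbond_criteria(),
                                 topology, restrict = NULL, events = NULL) {
  if (is.null(events)) events <- detect_hbonds(frame, criteria, topology)
  ev <- events[events$category == "chitosan_water", , drop = FALSE]
  out <- data.frame(water = integer(0), atom1 = integer(0), atom2 = integer(0),
                    chain1 = character(0), chain2 = character(0),
                    category = character(0))
  if (nrow(ev) == 0) return(out)
  a <- frame$atoms
  dwat <- a$resname[ev$donor] == "HOH"
  wat_res <- ifelse(dwat, a$resid[ev$donor], a$resid[ev$acceptor])
  partner <- ifelse(dwat, ev$acceptor, ev$donor)
  # unique (water, partner-atom) links, then all partner pairs per water
  links <- unique(data.frame(water = wat_res, partner = partner))
  rows <- list()
  for (w in unique(links$water)) {
    p <- sort(links$partner[links$water == w])
    if (length(p) < 2) next
    cmb <- utils::combn(p, 2)
    rows[[length(rows) + 1L]] <- data.frame(
      water = w, atom1 = cmb[1, ], atom2 = cmb[2, ],
      chain1 = a$chain[cmb[1, ]], chain2 = a$chain[cmb[2, ]])
  }
  if (length(rows) == 0) return(out)
  br <- do.call(rbind, rows)
  s1 <- topology$chain_to_sheet[br$chain1]
  s2 <- topology$chain_to_sheet[br$chain2]
  br$category <- ifelse(br$chain1 == br$chain2, "intra_chain",
                        ifelse(s1 == s2, "intra_sheet", "inter_sheet"))
  if (!is.null(restrict)) br <- br[br$category == restrict, , drop = FALSE]
  rownames(br) <- NULL
  br
}

#' Per-frame hydration summary
#'
#' @param traj a `cf_trajectory`.
#' @param topology a `cf_topology`.
#' @param criteria a [hbond_criteria()].
#' @param events optional per-frame event list from [detect_hbonds_all()].
#' @return data.frame with columns `frame`, `n_bound`, `n_bulk`,
#'   `n_interior`, `n_bridges_inter`, `n_bridges_intra`.
#' @export
hydration_summary <- function(traj, topology, criteria = hbond_criteria(),
                              events = NULL) {
  out <- lapply(seq_len(n_frames(traj)), function(f) {
    fr <- get_frame(traj, f)
    has_w <- any(is_water(fr))
    wa <- if (has_w) assign_waters(fr, topology) else NULL
    br <- if (has_w) {
      detect_water_bridges(fr, criteria, topology,
                           events = if (!is.null(events)) events[[f]])
    } else NULL
    data.frame(
      frame = f,
      n_bound = if (has_w) sum(wa$class == "bound") else 0L,
      n_bulk = if (has_w) sum(wa$class == "bulk") else 0L,
      n_interior = if (has_w && topology$n_sheets >= 4)
        sum(wa$interior) else 0L,
      n_bridges_inter = if (has_w) sum(br$category == "inter_sheet") else 0L,
      n_bridges_intra = if (has_w) sum(br$category == "intra_sheet") else 0L)
  })
  do.call(rbind, out)
}

#' Chitosan-water hydrogen bonds by chitosan atom role
#'
#' Mean per-frame counts of chitosan-water H-bonds in which an interior
#' chain atom acts as donor (O6H, O3H, NH) or acceptor (O6, O3, O5, O4,
#' N). Only the chains of the two interior sheets are counted; the
#' solvent-facing exterior sheets are excluded.
#'
#' @param traj a `cf_trajectory`.
#' @param topology a `cf_topology` with >= 4 sheets.
#' @param criteria a [hbond_criteria()].
#' @param events optional per-frame event list from [detect_hbonds_all()].
#' @return data.frame with columns `role` (donor/acceptor), `atom`
#'   (chitosan atom name), `mean_count`, `n_frames`.
#' @export
chitosan_water_table <- function(traj, topology, criteria = hbond_criteria(),
                                 events = NULL) {
  if (topology$n_sheets < 4) stop("interior chains undefined: need >= 4 sheets")
  interior_chains <- topology$chain_ids[topology$chain_to_sheet %in% c(2L, 3L)]
  donors <- c("O6", "O3", "N")
  acceptors <- c("O6", "O3", "O5", "O4", "N")
  nf <- n_frames(traj)
  dsum <- setNames(numeric(length(donors)), donors)
  asum <- setNames(numeric(length(acceptors)), acceptors)
  for (f in seq_len(nf)) {
    fr <- get_frame(traj, f)
    ev <- if (is.null(events)) detect_hbonds(fr, criteria, topology)
          else events[[f]]
    ev <- ev[ev$category == "chitosan_water", , drop = FALSE]
    if (nrow(ev) == 0) next
    a <- fr$atoms
    dwat <- a$resname[ev$donor] == "HOH"
    # chitosan as donor
    cd <- ev[!dwat & a$chain[ev$donor] %in% interior_chains, , drop = FALSE]
    if (nrow(cd) > 0) {
      t1 <- table(factor(a$name[cd$donor], levels = donors))
      dsum <- dsum + as.numeric(t1)
    }
    # chitosan as acceptor
    ca <- ev[dwat & a$chain[ev$acceptor] %in% interior_chains, , drop = FALSE]
    if (nrow(ca) > 0) {
      t2 <- table(factor(a$name[ca$acceptor], levels = acceptors))
      asum <- asum + as.numeric(t2)
    }
  }
  rbind(
    data.frame(role = "donor", atom = donors,
               mean_count = unname(dsum) / nf, n_frames = nf),
    data.frame(role = "acceptor", atom = acceptors,
               mean_count = unname(asum) / nf, n_frames = nf)
  )
}
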