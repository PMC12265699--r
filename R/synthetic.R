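#' Configuration for the synthetic trajectory generator
#'
#' Every planted parameter of the generator. Schedules may be scalars
#' (flat) or length-`n_frames` vectors.
#'
#' @param seed integer RNG seed; identical config + seed gives
#'   bit-identical output.
#' @param n_frames number of frames.
#' @param jitter_sigma per-axis Gaussian thermal disorder of chitosan
#'   atoms in Angstrom (default 0.1; chosen so planted H-bonds keep a
#'   > 2.5 sigma margin to the 3.5 A criterion).
#' @param planted_occupancy named numeric vector of per-frame formation
#'   probabilities for named H-bond pairs (see [named_pairs()]), or NULL.
#' @param stacking_schedule planted sheet-stacking distance in Angstrom,
#'   measured as the COM-COM distance of the middle chains of sheets 2
#'   and 3 (exactly what [sheet_stacking_distance()] reports); NULL keeps
#'   the as-built distance.
#' @param n_interior_waters per-frame count of waters planted between
#'   the two interior sheets (scalar or schedule).
#' @param n_bridge_sites number of planted inter-sheet water-bridge
#'   sites between sheets 2 and 3.
#' @param n_intra_bridge_sites number of planted intra-sheet bridge
#'   sites (within sheet 2 or 3).
#' @param bridge_survival_p probability a planted bridge is occupied in
#'   a frame (otherwise its water is expelled to the bulk region).
#' @param n_bulk_waters waters kept in the bulk region (>= 12 A from
#'   chitosan).
#' @param kappa concentration of the axial Boltzmann orientation
#'   distribution P(theta) ~ sin(theta) exp(kappa cos(theta)) for
#'   bulk-region water dipoles; 0 = isotropic.
#' @param field_axis `"x"`, `"y"`, `"z"` or `"none"`; the dipole
#'   reference axis (orientation sampling falls back to z when "none").
#' @return An object of class `cf_synth_config`.
#' @export
synthetic_config <- function(seed = 1L, n_frames = 100L, jitter_sigma = 0.1,
                             planted_occupancy = NULL,
                             stacking_schedule = NULL,
                             n_interior_waters = 0,
                             n_bridge_sites = 0,
                             n_intra_bridge_sites = 0,
                             bridge_survival_p = 1.0,
                             n_bulk_waters = 0,
                             kappa = 0,
                             field_axis = c("none", "x", "y", "z")) {
  field_axis <- match.arg(field_axis)
  stopifnot(n_frames >= 1, jitter_sigma >= 0, kappa >= 0,
            bridge_survival_p >= 0, bridge_survival_p <= 1,
            n_bridge_sites >= 0, n_intra_bridge_sites >= 0,
            n_bulk_waters >= 0)
  if (!is.null(planted_occupancy)) {
    stopifnot(!is.null(names(planted_occupancy)),
              all(names(planted_occupancy) %in% named_pairs()),
              all(planted_occupancy >= 0 & planted_occupancy <= 1))
  }
  as_sched <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (length(x) == 1) x <- rep(x, n_frames)
    if (length(x) != n_frames) {
      stop(what, " schedule length ", length(x), " != n_frames ", n_frames)
    }
    x
  }
  structure(list(
    seed = as.integer(seed), n_frames = as.integer(n_frames),
    jitter_sigma = jitter_sigma,
    planted_occupancy = planted_occupancy,
    stacking_schedule = as_sched(stacking_schedule, "stacking"),
    n_interior_waters = as_sched(n_interior_waters, "interior water"),
    n_bridge_sites = as.integer(n_bridge_sites),
    n_intra_bridge_sites = as.integer(n_intra_bridge_sites),
    bridge_survival_p = bridge_survival_p,
    n_bulk_waters = as.integer(n_bulk_waters),
    kappa = kappa, field_axis = field_axis
  ), class = "cf_synth_config")
}

# Sample cos(theta) from p(u) ~ exp(kappa * u) on [-1, 1].
sample_axial_cos <- function(n, kappa) {
  if (kappa < 1e-12) return(runif(n, -1, 1))
  u <- runif(n)
  1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
}

# Random unit vectors at the sampled axial angle about `axis`.
sample_axial_dirs <- function(n, kappa, axis) {
  ct <- sample_axial_cos(n, kappa)
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- runif(n, 0, 2 * pi)
  # orthonormal frame around axis
  a <- axis / sqrt(sum(axis^2))
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- cross3(a, ref); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(a, e1)
  t(vapply(seq_len(n), function(i) {
    ct[i] * a + st[i] * (cos(phi[i]) * e1 + sin(phi[i]) * e2)
  }, numeric(3)))
}

# 3-site water coordinates: O at pos, H-O-H bisector along dir.
TIP3_OH <- 0.9572
TIP3_HALF_ANGLE <- 104.52 / 2 * pi / 180
water_coords <- function(pos, dir) {
  d <- dir / sqrt(sum(dir^2))
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- cross3(d, ref); e1 <- e1 / sqrt(sum(e1^2))
  roll <- runif(1, 0, 2 * pi)
  e2 <- cross3(d, e1)
  ep <- cos(roll) * e1 + sin(roll) * e2
  h1 <- pos + TIP3_OH * (cos(TIP3_HALF_ANGLE) * d + sin(TIP3_HALF_ANGLE) * ep)
  h2 <- pos + TIP3_OH * (cos(TIP3_HALF_ANGLE) * d - sin(TIP3_HALF_ANGLE) * ep)
  rbind(pos, h1, h2)
}

# Disjoint planted-instance assignment: a donor hydrogen shared by
# several pair types is assigned to one of them, alternating within
# each conflict group so instance counts stay balanced.
assign_instances <- function(instances) {
  sp <- split(seq_len(nrow(instances)), instances$hydrogen)
  drop <- logical(nrow(instances))
  groups <- list()
  for (rows in sp) {
    if (length(rows) == 1) next
    key <- paste(sort(instances$pair[rows]), collapse = "|")
    groups[[key]] <- c(groups[[key]], list(rows))
  }
  for (key in names(groups)) {
    types <- strsplit(key, "|", fixed = TRUE)[[1]]
    for (gi in seq_along(groups[[key]])) {
      rows <- groups[[key]][[gi]]
      keep_pair <- types[(gi - 1) %% length(types) + 1]
      drop[rows[instances$pair[rows] != keep_pair]] <- TRUE
    }
  }
  instances[!drop, , drop = FALSE]
}

# Orthonormal frame perpendicular to a unit vector (deterministic).
perp_frame <- function(n) {
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- cross3(n, ref); e1 <- e1 / sqrt(sum(e1^2))
  list(e1 = e1, e2 = cross3(n, e1))
}

# Donor-H-X angle (degrees) when the hydrogen sits at D + u (|u| = 1)
# and X is at D + v.
planted_angle <- function(u, v) {
  w <- v - u
  acos(max(-1, min(1, sum(-u * w) / sqrt(sum(w^2))))) * 180 / pi
}

# Choose, per planted instance, a hydrogen direction (tilt tau from the
# donor->acceptor axis at azimuth phi) that keeps the target bond well
# above the 135-degree criterion while every competing acceptor near
# the donor stays well below it. The same (tau, phi) is re-applied to
# the jittered axis each frame.
plan_instance_dirs <- function(s0, instances, acc_idx) {
  xyz0 <- coords(s0)
  taus <- numeric(nrow(instances))
  phis <- numeric(nrow(instances))
  for (k in seq_len(nrow(instances))) {
    D <- xyz0[instances$donor[k], ]
    A <- xyz0[instances$acceptor[k], ]
    n0 <- (A - D) / sqrt(sum((A - D)^2))
    near <- acc_idx[acc_idx != instances$acceptor[k] &
                    acc_idx != instances$donor[k]]
    dd <- sqrt(colSums((t(xyz0[near, , drop = FALSE]) - D)^2))
    vs <- lapply(near[dd < 3.8], function(x) xyz0[x, ] - D)
    fr <- perp_frame(n0)
    found <- FALSE
    for (tau in c(0, 20, 35) * pi / 180) {
      for (phi in seq(0, 330, by = 30) * pi / 180) {
        u <- cos(tau) * n0 + sin(tau) * (cos(phi) * fr$e1 + sin(phi) * fr$e2)
        if (planted_angle(u, A - D) <= 145) next
        clean <- all(vapply(vs, function(v) planted_angle(u, v) < 123,
                            logical(1)))
        if (clean) {
          taus[k] <- tau; phis[k] <- phi; found <- TRUE
          break
        }
        if (tau == 0) break   # phi is irrelevant on-axis
      }
      if (found) break
    }
    if (!found) { taus[k] <- 0; phis[k] <- 0 }  # accept residual contacts
  }
  instances$tau <- taus
  instances$phi <- phis
  instances
}

# Find water-bridge sites. Inter-sheet sites pair acceptors across
# sheets 2/3 (water at the midpoint, inside the interior slab).
# Intra-sheet sites pair acceptors of adjacent chains within sheet 2 or
# 3; their water sits offset perpendicular to the sheet plane, on the
# side facing away from the interior slab (the in-plane midpoint is too
# crowded). Every site's water position must be clear of non-partner
# atoms and keep a stable side of the slab boundaries.
find_bridge_sites <- function(s0, topology, n_inter, n_intra) {
  empty <- data.frame(atom1 = integer(0), atom2 = integer(0),
                      kind = character(0), interior = logical(0),
                      off_y = numeric(0))
  if (n_inter + n_intra == 0) return(empty)
  if (topology$n_sheets < 4) stop("bridge sites need at least 4 sheets")
  a <- s0$atoms
  xyz <- coords(s0)
  heavy <- which(is_heavy(s0) & !is_water(s0))
  acc <- which(a$resname != "HOH" & a$name %in% acceptor_names_chitosan)
  sheet <- topology$chain_to_sheet[a$chain[acc]]
  i2 <- acc[sheet == 2]; i3 <- acc[sheet == 3]
  com2 <- mean(xyz[which(a$chain %in% topology$chain_ids[
    topology$chain_to_sheet == 2] & is_heavy(s0)), 2])
  com3 <- mean(xyz[which(a$chain %in% topology$chain_ids[
    topology$chain_to_sheet == 3] & is_heavy(s0)), 2])
  slab_dir <- sign(com3 - com2)

  candidate_pairs <- function(setA, setB, same_sheet, win) {
    out <- list()
    for (i in setA) {
      d <- sqrt(colSums((t(xyz[setB, , drop = FALSE]) - xyz[i, ])^2))
      j <- setB[d >= win[1] & d <= win[2]]
      if (same_sheet) j <- j[a$chain[j] != a$chain[i] & j > i]
      for (jj in j) out[[length(out) + 1L]] <- c(i, jj)
    }
    if (length(out) == 0) return(NULL)
    do.call(rbind, out)
  }
  water_pos <- function(p, off_y) (xyz[p[1], ] + xyz[p[2], ]) / 2 +
    c(0, off_y, 0)
  # Functional site check: the planted water must bond its two partners
  # and nothing else. Nearby non-partner acceptors are tolerated as long
  # as the water's hydrogens (which aim at the partners) cannot reach
  # the 135-degree angle criterion with them, with a 15-degree margin.
  site_ok <- function(p, off_y) {
    o <- water_pos(p, off_y)
    if (min(abs(o[2] - com2), abs(o[2] - com3)) < 0.15) return(FALSE)
    other_h <- setdiff(heavy, p)
    dh <- sqrt(colSums((t(xyz[other_h, , drop = FALSE]) - o)^2))
    if (any(dh < 2.0)) return(FALSE)
    h1 <- o + TIP3_OH * (xyz[p[1], ] - o) / sqrt(sum((xyz[p[1], ] - o)^2))
    h2 <- o + TIP3_OH * (xyz[p[2], ] - o) / sqrt(sum((xyz[p[2], ] - o)^2))
    other_acc <- setdiff(acc, p)
    da <- sqrt(colSums((t(xyz[other_acc, , drop = FALSE]) - o)^2))
    for (q in other_acc[da < 3.9]) {
      for (h in list(h1, h2)) {
        u <- o - h; v <- xyz[q, ] - h
        ang <- acos(pmin(1, pmax(-1, sum(u * v) /
                                   sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
        if (ang >= 120) return(FALSE)
      }
    }
    TRUE
  }
  pick <- function(cand, n, kind, off_y) {
    if (n == 0) return(NULL)
    if (is.null(cand)) stop("no candidate ", kind, " bridge sites found")
    ord <- sample(nrow(cand))
    chosen <- list(); offs <- numeric(0); pos <- NULL; used <- integer(0)
    for (r in ord) {
      p <- cand[r, ]
      oy <- if (length(off_y) == 1) off_y else
        off_y[topology$chain_to_sheet[a$chain[p[1]]] - 1L]
      if (any(p %in% used) || !site_ok(p, oy)) next
      o <- water_pos(p, oy)
      if (!is.null(pos) && any(sqrt(rowSums(sweep(pos, 2, o)^2)) < 5)) next
      chosen[[length(chosen) + 1L]] <- p
      offs <- c(offs, oy)
      pos <- rbind(pos, o)
      used <- c(used, p)
      if (length(chosen) == n) break
    }
    if (length(chosen) < n) {
      stop("only ", length(chosen), " of ", n, " requested ", kind,
           " bridge sites available")
    }
    m <- do.call(rbind, chosen)
    data.frame(atom1 = m[, 1], atom2 = m[, 2], kind = kind,
               interior = vapply(seq_len(nrow(m)), function(k) {
                 y <- pos[k, 2]
                 y > min(com2, com3) && y < max(com2, com3)
               }, logical(1)),
               off_y = offs)
  }
  # intra offsets indexed by sheet (2 -> away from slab, 3 -> away)
  intra_off <- c(-1.8 * slab_dir, 1.8 * slab_dir)
  rbind(pick(candidate_pairs(i2, i3, FALSE, c(4.6, 6.2)), n_inter,
             "inter", 0),
        pick(rbind(candidate_pairs(i2, i2, TRUE, c(4.0, 5.4)),
                   candidate_pairs(i3, i3, TRUE, c(4.0, 5.4))), n_intra,
             "intra", intra_off))
}

#' Generate a synthetic fibril trajectory with planted ground truth
#'
#' Produces frames in which (i) chitosan atoms carry Gaussian thermal
#' jitter on top of optional per-sheet stacking displacements, (ii)
#' named hydrogen bonds are toggled on/off geometrically -- the donor
#' hydrogen is moved onto (or off) the donor-acceptor axis -- with the
#' planted per-frame probability, so the detector is exercised end to
#' end, (iii) waters are planted at bridge sites, inside the interior
#' slab, and in a far bulk region with axially distributed dipoles.
#'
#' @param fibril result of [build_fibril()].
#' @param config a [synthetic_config()].
#' @return list with `trajectory` (a `cf_trajectory`) and `truth`
#'   (ground-truth record: planted instance tables, bridge sites,
#'   per-frame planted values, and the config).
#' @export
generate_trajectory <- function(fibril, config) {
  stopifnot(inherits(config, "cf_synth_config"))
  s0 <- fibril$structure
  topo <- fibril$topology
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  a0 <- s0$atoms
  nchit <- nrow(a0)
  xyz0 <- coords(s0)
  heavy0 <- is_heavy(s0)
  sheet_of_atom <- topo$chain_to_sheet[a0$chain]
  acc_idx <- which(a0$resname != "HOH" & a0$name %in% acceptor_names_chitosan)

  # planted H-bond instances (disjoint per donor hydrogen)
  occ <- config$planted_occupancy
  instances <- NULL
  if (!is.null(occ)) {
    instances <- enumerate_pair_instances(s0, topo, pairs = names(occ),
                                          max_ref_dist = 3.45)
    instances <- assign_instances(instances)
    if (nrow(instances) == 0) stop("no plantable instances for requested pairs")
    instances <- plan_instance_dirs(s0, instances, acc_idx)
  }

  # stacking geometry: planted COM-COM distance -> sheet y-spacing
  can_stack <- topo$n_sheets >= 4
  if (can_stack) {
    mid <- middle_chain_atoms(a0, topo, heavy0)
    com2 <- colMeans(xyz0[mid$s2, , drop = FALSE])
    com3 <- colMeans(xyz0[mid$s3, , drop = FALSE])
    czx <- sqrt((com3[1] - com2[1])^2 + (com3[3] - com2[3])^2)
    h0 <- abs(com3[2] - com2[2])
    base_stack <- sqrt(czx^2 + h0^2)
  } else {
    czx <- 0; h0 <- NA_real_; base_stack <- NA_real_
  }
  sched <- config$stacking_schedule
  if (!is.null(sched)) {
    if (!can_stack) stop("stacking schedule needs at least 4 sheets")
    if (any(sched <= czx)) {
      stop(sprintf("stacking schedule below the geometric floor %.3f A", czx))
    }
  }
  int_sched <- config$n_interior_waters
  if (is.null(int_sched)) int_sched <- rep(0L, config$n_frames)
  if (any(int_sched > 0) && topo$n_sheets < 4) {
    stop("interior waters need at least 4 sheets")
  }

  sites <- find_bridge_sites(s0, topo, config$n_bridge_sites,
                             config$n_intra_bridge_sites)

  # interior slab footprint from the base sheets 2+3 (inset 1 A)
  if (topo$n_sheets >= 4) {
    both <- which(heavy0 & sheet_of_atom %in% c(2, 3))
    fx <- range(xyz0[both, 1]); fz <- range(xyz0[both, 3])
    com2y0 <- mean(xyz0[which(heavy0 & sheet_of_atom == 2), 2])
    com3y0 <- mean(xyz0[which(heavy0 & sheet_of_atom == 3), 2])
  }

  # bulk/parking grid, >= 12 A beyond the fibril in +x
  n_pool <- max(int_sched)
  n_wat <- nrow(sites) + n_pool + config$n_bulk_waters
  grid <- NULL
  if (n_wat > 0) {
    gx0 <- max(xyz0[, 1]) + 12
    zr <- range(xyz0[, 3]); yr <- range(xyz0[, 2])
    ny <- max(1L, floor(diff(yr) / 3.2) + 1L)
    nz <- max(1L, floor(diff(zr) / 3.2) + 1L)
    need <- n_wat
    nx <- ceiling(need / (ny * nz))
    grid <- as.matrix(expand.grid(x = gx0 + 3.2 * (seq_len(nx) - 1),
                                  y = yr[1] + 3.2 * (seq_len(ny) - 1),
                                  z = zr[1] + 3.2 * (seq_len(nz) - 1)))
    grid <- grid[seq_len(n_wat), , drop = FALSE]
  }
  axis_vec <- switch(config$field_axis, x = c(1, 0, 0), y = c(0, 1, 0),
                     z = c(0, 0, 1), none = c(0, 0, 1))

  # fixed atom table: chitosan then waters (3 sites each)
  atoms <- a0
  if (n_wat > 0) {
    wat <- data.frame(
      name = rep(c("O", "H1", "H2"), n_wat),
      resname = "HOH", chain = "W",
      resid = rep(seq_len(n_wat), each = 3),
      x = 0, y = 0, z = 0,
      element = rep(c("O", "H", "H"), n_wat), stringsAsFactors = FALSE)
    atoms <- rbind(a0, wat)
  }
  # box: generous padding so no content pair can alias under minimum image
  xspan <- if (!is.null(grid)) max(grid[, 1]) - min(xyz0[, 1])
           else diff(range(xyz0[, 1]))
  box <- c(xspan + 20, diff(range(xyz0[, 2])) + 20,
           diff(range(xyz0[, 3])) + 20)

  frames <- vector("list", config$n_frames)
  gt_rows <- vector("list", config$n_frames)
  pair_names <- if (!is.null(occ)) names(occ) else character(0)

  for (f in seq_len(config$n_frames)) {
    xyz <- xyz0
    if (!is.null(sched)) {
      dy_f <- sqrt(sched[f]^2 - czx^2)
      shift <- (sheet_of_atom - 1) * (dy_f - h0)
      xyz[, 2] <- xyz[, 2] + shift
    } else {
      dy_f <- h0
    }
    if (config$jitter_sigma > 0) {
      xyz <- xyz + matrix(rnorm(3 * nchit, 0, config$jitter_sigma), ncol = 3)
    }
    # plant/unplant H-bonds on the jittered geometry
    n_on <- setNames(integer(length(pair_names)), pair_names)
    if (!is.null(instances)) {
      on <- runif(nrow(instances)) < occ[instances$pair]
      for (k in seq_len(nrow(instances))) {
        D <- xyz[instances$donor[k], ]
        A <- xyz[instances$acceptor[k], ]
        nv <- A - D
        dda <- sqrt(sum(nv^2))
        nv <- nv / dda
        # an "on" bond is only realisable while thermal disorder keeps
        # the donor-acceptor pair inside the distance criterion; record
        # what is actually planted in the frame
        if (on[k] && dda >= 3.5) on[k] <- FALSE
        if (on[k]) {
          tau <- instances$tau[k]
          if (tau > 0) {
            fr2 <- perp_frame(nv)
            phi <- instances$phi[k]
            nv <- cos(tau) * nv +
              sin(tau) * (cos(phi) * fr2$e1 + sin(phi) * fr2$e2)
          }
          xyz[instances$hydrogen[k], ] <- D + nv
        } else {
          # off: return the hydrogen to its inward resting direction,
          # which satisfies the angle criterion with no acceptor
          base_dir <- xyz0[instances$hydrogen[k], ] - xyz0[instances$donor[k], ]
          xyz[instances$hydrogen[k], ] <- D + base_dir
        }
      }
      tab <- tapply(on, instances$pair, sum)
      n_on[names(tab)] <- tab
    }
    # waters
    wcoords <- NULL
    n_park <- 0L
    n_surv_inter <- 0L; n_surv_intra <- 0L; n_surv_interior <- 0L
    if (n_wat > 0) {
      wlist <- vector("list", n_wat)
      park_slot <- 0L
      park <- function() {
        park_slot <<- park_slot + 1L
        n_park <<- n_park + 1L
        pos <- grid[park_slot, ] + rnorm(3, 0, min(config$jitter_sigma, 0.3))
        dirs <- sample_axial_dirs(1, config$kappa, axis_vec)
        water_coords(pos, dirs[1, ])
      }
      wi <- 0L
      if (nrow(sites) > 0) {
        surv <- runif(nrow(sites)) < config$bridge_survival_p
        for (sidx in seq_len(nrow(sites))) {
          wi <- wi + 1L
          if (surv[sidx]) {
            p1 <- xyz[sites$atom1[sidx], ]; p2 <- xyz[sites$atom2[sidx], ]
            o <- (p1 + p2) / 2 + c(0, sites$off_y[sidx], 0)
            h1 <- o + TIP3_OH * (p1 - o) / sqrt(sum((p1 - o)^2))
            h2 <- o + TIP3_OH * (p2 - o) / sqrt(sum((p2 - o)^2))
            wlist[[wi]] <- rbind(o, h1, h2)
            if (sites$kind[sidx] == "inter") n_surv_inter <- n_surv_inter + 1L
            else n_surv_intra <- n_surv_intra + 1L
            if (sites$interior[sidx]) n_surv_interior <- n_surv_interior + 1L
          } else {
            wlist[[wi]] <- park()
          }
        }
      }
      # interior pool
      if (n_pool > 0) {
        k_f <- int_sched[f]
        p2y <- com2y0 + 1 * (dy_f - h0)   # sheet 2 COM plane this frame
        p3y <- com3y0 + 2 * (dy_f - h0)
        ylo <- min(p2y, p3y) + 1.2; yhi <- max(p2y, p3y) - 1.2
        if (k_f > 0 && yhi <= ylo) {
          stop("interior slab too thin for planted waters at frame ", f)
        }
        near23 <- xyz[which(heavy0 & sheet_of_atom %in% c(2, 3)), ,
                      drop = FALSE]
        placed_o <- if (wi > 0) {
          do.call(rbind, lapply(wlist[seq_len(wi)], function(m) m[1, ]))
        } else NULL
        for (j in seq_len(n_pool)) {
          wi <- wi + 1L
          if (j <= k_f) {
            # rejection-sample a clash-free slab position (the slab is
            # crowded: typical nearest-atom distances are 1.7-2.5 A, so
            # the steric floor is 2.0 A and H-bond cleanliness is
            # enforced by orientation rejection below)
            pos <- NULL
            for (try in 1:400) {
              cand <- c(runif(1, fx[1] + 1, fx[2] - 1),
                        runif(1, ylo, yhi),
                        runif(1, fz[1] + 1, fz[2] - 1))
              dmin <- min(sqrt(colSums((t(near23) - cand)^2)))
              if (dmin < 2.0) next
              if (!is.null(placed_o) &&
                  min(sqrt(rowSums(sweep(placed_o, 2, cand)^2))) < 2.4) next
              pos <- cand
              break
            }
            if (is.null(pos)) {
              stop("could not place interior water ", j, " at frame ", f)
            }
            # orientation rejection: interior waters must not H-bond
            # chitosan, so planted bridge counts stay exact
            dacc <- sqrt(colSums((t(xyz[acc_idx, , drop = FALSE]) - pos)^2))
            near_acc <- xyz[acc_idx[dacc < 3.6], , drop = FALSE]
            w <- NULL
            for (otry in 1:80) {
              dir <- sample_axial_dirs(1, 0, c(0, 0, 1))
              cand_w <- water_coords(pos, dir[1, ])
              ok <- TRUE
              if (nrow(near_acc) > 0) {
                for (hh in 2:3) {
                  u <- cand_w[1, ] - cand_w[hh, ]
                  v <- t(near_acc) - cand_w[hh, ]
                  ang <- acos(pmin(1, pmax(-1, colSums(u * v) /
                    (sqrt(sum(u^2)) * sqrt(colSums(v^2)))))) * 180 / pi
                  if (any(ang >= 130)) { ok <- FALSE; break }
                }
              }
              if (ok) { w <- cand_w; break }
            }
            if (is.null(w)) {
              stop("could not orient interior water ", j, " at frame ", f)
            }
            wlist[[wi]] <- w
            placed_o <- rbind(placed_o, pos)
          } else {
            wlist[[wi]] <- park()
          }
        }
      }
      if (config$n_bulk_waters > 0) {
        for (j in seq_len(config$n_bulk_waters)) {
          wi <- wi + 1L
          wlist[[wi]] <- park()
        }
      }
      wcoords <- do.call(rbind, wlist)
    }
    frames[[f]] <- unname(rbind(xyz, wcoords))
    gt_rows[[f]] <- data.frame(
      frame = f,
      stacking = if (!is.null(sched)) sched[f] else base_stack,
      n_interior = int_sched[f] + n_surv_interior,
      n_bridges_inter = n_surv_inter,
      n_bridges_intra = n_surv_intra,
      n_bulk = n_park,
      t(n_on))
  }

  truth <- list(config = config,
                instances = instances,
                bridge_sites = sites,
                per_frame = do.call(rbind, gt_rows),
                base_stacking = base_stack,
                stacking_floor = czx,
                base_sheet_spacing = h0)
  list(trajectory = new_trajectory(atoms, frames, box = box), truth = truth)
}

#' Fully hydrogen-bonded reference state of a fibril
#'
#' The as-built lattice keeps donor hydrogens in resting (inward)
#' positions, so it has no inter-chain hydrogen bonds. This helper
#' returns a jitter-free frame with every named pair planted "on" --
#' the synthetic analogue of the energy-minimized reference used to
#' normalise the fraction of maximal inter-chain H-bonds.
#'
#' @param fibril result of [build_fibril()].
#' @return A `cf_structure`.
#' @export
bonded_reference <- function(fibril) {
  cfg <- synthetic_config(seed = 0L, n_frames = 1L, jitter_sigma = 0,
                          planted_occupancy = setNames(rep(1, 4),
                                                       named_pairs()))
  get_frame(generate_trajectory(fibril, cfg)$trajectory, 1)
}

#' Generate a paired field-off / field-on dewetting scenario
#'
#' Two trajectories from one base fibril emulating the qualitative
#' dewetting signatures: the "field-on" arm has raised inter-chain
#' H-bond occupancies, a contracting stacking schedule, decaying
#' interior-water counts, reduced bridge survival and field-aligned
#' bulk-water dipoles; the "field-off" arm is stationary with broad
#' interior hydration and isotropic bulk dipoles.
#'
#' @param fibril result of [build_fibril()].
#' @param n_frames frames per arm (default 150).
#' @param seed base seed (the two arms use `seed` and `seed + 1`).
#' @param contraction planted mean stacking contraction in Angstrom
#'   (default 0.6, the centre of the reported 0.5-0.7 A range).
#' @param field_axis field direction of the "on" arm (default `"z"`).
#' @param n_bulk_waters bulk waters per arm (default 120).
#' @return list with elements `field_off` and `field_on`, each a
#'   `generate_trajectory()` result, plus `planted_contrast` (the
#'   planted difference in mean stacking distance, on - off).
#' @export
generate_dewetting_scenario <- function(fibril = build_fibril(),
                                        n_frames = 150, seed = 1,
                                        contraction = 0.6,
                                        field_axis = "z",
                                        n_bulk_waters = 120) {
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  # base stacking distance of this fibril
  s0 <- fibril$structure; topo <- fibril$topology
  d0 <- sheet_stacking_distance(s0, topo)$stacking_distance[1]

  set.seed(seed * 1000L + 7L)
  off_interior <- pmax(0L, round(rnorm(n_frames, 30, 6)))
  on_interior <- pmax(0L, round(seq(30, 5, length.out = n_frames) +
                                  rnorm(n_frames, 0, 2)))
  ramp <- ceiling(n_frames / 3)
  on_stacking <- c(seq(d0, d0 - contraction, length.out = ramp),
                   rep(d0 - contraction, n_frames - ramp))

  occ_off <- c("O3'H-O5" = 0.74, "O6H-O3'" = 0.08,
               "N'H-O6" = 0.45, "N'H-O4" = 0.50)
  occ_on <- c("O3'H-O5" = 0.80, "O6H-O3'" = 0.08,
              "N'H-O6" = 0.58, "N'H-O4" = 0.63)

  cfg_off <- synthetic_config(
    seed = seed, n_frames = n_frames, planted_occupancy = occ_off,
    stacking_schedule = d0, n_interior_waters = off_interior,
    n_bridge_sites = 6, n_intra_bridge_sites = 4,
    bridge_survival_p = 0.9, n_bulk_waters = n_bulk_waters,
    kappa = 0, field_axis = "none")
  cfg_on <- synthetic_config(
    seed = seed + 1L, n_frames = n_frames, planted_occupancy = occ_on,
    stacking_schedule = on_stacking, n_interior_waters = on_interior,
    n_bridge_sites = 6, n_intra_bridge_sites = 4,
    bridge_survival_p = 0.35, n_bulk_waters = n_bulk_waters,
    kappa = 2, field_axis = field_axis)

  off <- generate_trajectory(fibril, cfg_off)
  on <- generate_trajectory(fibril, cfg_on)
  list(field_off = off, field_on = on,
       planted_contrast = mean(on_stacking) - d0)
}
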