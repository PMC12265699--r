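#' Geometric hydrogen-bond criteria
#'
#' A donor-H...acceptor triple is a hydrogen bond when the donor-acceptor
#' heavy-atom distance is below `max_dist` and the donor-H-acceptor angle
#' (vertex at the hydrogen) is greater than `min_angle`.
#'
#' @param max_dist maximum donor-acceptor heavy-atom distance in Angstrom
#'   (default 3.5).
#' @param min_angle minimum donor-H-acceptor angle in degrees (default 135).
#' @return An object of class `cf_hbond_criteria`.
#' @export
hbond_criteria <- function(max_dist = 3.5, min_angle = 135) {
  stopifnot(max_dist > 0, min_angle > 0, min_angle <= 180)
  structure(list(max_dist = max_dist, min_angle = min_angle),
            class = "cf_hbond_criteria")
}

# Donor hydrogen -> parent heavy atom name map (chitosan + 3-site water).
donor_h_map <- c(HN = "N", HO3 = "O3", HO6 = "O6", H1 = "O", H2 = "O")
acceptor_names_chitosan <- c("N", "O3", "O4", "O5", "O6")

# Build the (hydrogen, donor-heavy) index table for a structure.
donor_table <- function(s) {
  a <- s$atoms
  h_idx <- which(a$name %in% names(donor_h_map))
  parent <- donor_h_map[a$name[h_idx]]
  key_all <- paste(a$chain, a$resid, a$name, sep = "\r")
  d <- match(paste(a$chain[h_idx], a$resid[h_idx], parent, sep = "\r"), key_all)
  if (anyNA(d)) {
    bad <- h_idx[is.na(d)][1]
    stop("donor hydrogen ", a$name[bad], " (chain ", a$chain[bad],
         " resid ", a$resid[bad], ") has no parent heavy atom")
  }
  # every donor-capable heavy atom must carry its hydrogen
  heavies <- which((a$resname != "HOH" & a$name %in% c("N", "O3", "O6")) |
                   (a$resname == "HOH" & a$name == "O"))
  if (!all(heavies %in% d)) {
    bad <- setdiff(heavies, d)[1]
    stop("donor heavy atom ", a$name[bad], " (chain ", a$chain[bad],
         " resid ", a$resid[bad], ") has no covalently assigned hydrogen")
  }
  data.frame(h = h_idx, d = d)
}

acceptor_indices <- function(s) {
  a <- s$atoms
  which((a$resname != "HOH" & a$name %in% acceptor_names_chitosan) |
        (a$resname == "HOH" & a$name == "O"))
}

#' Detect hydrogen bonds in one frame
#'
#' Scans all donor-H...acceptor triples (chitosan hydroxyl/amine donors,
#' water donors, chitosan N/O3/O4/O5/O6 and water O acceptors) against
#' the geometric criteria. Distances and the angle vectors use the
#' minimum-image convention when the frame has an orthorhombic box.
#'
#' @param frame a `cf_structure`.
#' @param criteria a [hbond_criteria()].
#' @param topology optional `cf_topology`; when given, events are
#'   classified (see [classify_hbonds()]).
#' @return data.frame of events: `donor`, `hydrogen`, `acceptor` (atom
#'   indices), `distance` (Angstrom), `angle` (degrees), and when a
#'   topology is supplied `category` and `pair`.
#' @export
detect_hbonds <- function(frame, criteria = hbond_criteria(), topology = NULL) {
  stopifnot(inherits(frame, "cf_structure"),
            inherits(criteria, "cf_hbond_criteria"))
  dt <- donor_table(frame)
  acc <- acceptor_indices(frame)
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0))
  if (nrow(dt) == 0 || length(acc) == 0) {
    return(if (is.null(topology)) empty else
             classify_hbonds(empty, frame, topology))
  }
  xyz <- coords(frame)
  box <- frame$box
  Dm <- xyz[dt$d, , drop = FALSE]
  Hm <- xyz[dt$h, , drop = FALSE]
  Am <- xyz[acc, , drop = FALSE]

  ev <- list()
  chunk <- 512L
  for (lo in seq(1L, nrow(dt), by = chunk)) {
    hi <- min(lo + chunk - 1L, nrow(dt))
    ii <- lo:hi
    d2 <- matrix(0, length(ii), length(acc))
    for (k in 1:3) {
      dx <- outer(Dm[ii, k], Am[, k], "-")
      if (!is.null(box)) dx <- dx - box[k] * round(dx / box[k])
      d2 <- d2 + dx * dx
    }
    hit <- which(d2 < criteria$max_dist^2, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    di <- ii[hit[, 1]]
    aj <- hit[, 2]
    keep <- dt$d[di] != acc[aj]   # acceptor must differ from the donor atom
    di <- di[keep]; aj <- aj[keep]
    hit_d2 <- d2[cbind(match(di, ii), aj)]
    if (length(di) == 0) next
    hd <- min_image(Dm[di, , drop = FALSE], Hm[di, , drop = FALSE], box)
    ha <- min_image(Am[aj, , drop = FALSE], Hm[di, , drop = FALSE], box)
    cosang <- rowSums(hd * ha) /
      (sqrt(rowSums(hd^2)) * sqrt(rowSums(ha^2)))
    cosang <- pmin(1, pmax(-1, cosang))
    ang <- acos(cosang) * 180 / pi
    ok <- ang > criteria$min_angle
    if (!any(ok)) next
    ev[[length(ev) + 1L]] <- data.frame(
      donor = dt$d[di[ok]], hydrogen = dt$h[di[ok]], acceptor = acc[aj[ok]],
      distance = sqrt(hit_d2[ok]), angle = ang[ok])
  }
  events <- if (length(ev) == 0) empty else do.call(rbind, ev)
  rownames(events) <- NULL
  if (!is.null(topology)) events <- classify_hbonds(events, frame, topology)
  events
}

#' Classify hydrogen-bond events by fibril topology
#'
#' Adds a `category` column (`intra_chain`, `intra_sheet`, `inter_sheet`,
#' `chitosan_water`, `water_water`) and a `pair` label. Named pairs use
#' the prime convention where the prime marks the neighbouring
#' residue/chain partner: `O3'H-O5` (donor hydroxyl of residue i+1 to O5
#' of residue i), `O6H-O3'` (donor O6 of residue i to O3 of residue
#' i+1), `N'H-O6` (amine donor of the adjacent chain in the same sheet),
#' `N'H-O4` (amine donor of the adjacent sheet). Everything else is
#' `other`.
#'
#' @param events event data.frame from [detect_hbonds()].
#' @param frame the `cf_structure` the events refer to.
#' @param topology a `cf_topology`.
#' @return The event data.frame with `category` and `pair` columns.
#' @export
classify_hbonds <- function(events, frame, topology) {
  a <- frame$atoms
  n <- nrow(events)
  if (n == 0) {
    events$category <- character(0)
    events$pair <- character(0)
    return(events)
  }
  dch <- a$chain[events$donor];   ach <- a$chain[events$acceptor]
  dres <- a$resid[events$donor];  ares <- a$resid[events$acceptor]
  dnm <- a$name[events$donor];    anm <- a$name[events$acceptor]
  dwat <- a$resname[events$donor] == "HOH"
  awat <- a$resname[events$acceptor] == "HOH"
  unknown <- (!dwat & !(dch %in% topology$chain_ids)) |
             (!awat & !(ach %in% topology$chain_ids))
  if (any(unknown)) {
    stop("event involves an atom neither in the topology nor water (chain ",
         paste(unique(c(dch[unknown], ach[unknown])), collapse = ","), ")")
  }
  category <- character(n)
  category[dwat & awat] <- "water_water"
  category[xor(dwat, awat)] <- "chitosan_water"
  cc <- !dwat & !awat
  same_chain <- cc & dch == ach
  category[same_chain] <- "intra_chain"
  dsheet <- topology$chain_to_sheet[dch]
  asheet <- topology$chain_to_sheet[ach]
  category[cc & !same_chain & dsheet == asheet] <- "intra_sheet"
  category[cc & !same_chain & dsheet != asheet] <- "inter_sheet"

  pair <- rep("other", n)
  dpos <- topology$chain_pos[dch]
  apos <- topology$chain_pos[ach]
  pair[same_chain & dnm == "O3" & anm == "O5" & dres == ares + 1] <- "O3'H-O5"
  pair[same_chain & dnm == "O6" & anm == "O3" & ares == dres + 1] <- "O6H-O3'"
  pair[category == "intra_sheet" & dnm == "N" & anm == "O6" &
       abs(dpos - apos) == 1] <- "N'H-O6"
  pair[category == "inter_sheet" & dnm == "N" & anm == "O4" &
       abs(dsheet - asheet) == 1] <- "N'H-O4"
  events$category <- category
  events$pair <- pair
  events
}

# Named-pair rule table used for instance enumeration.
named_pairs <- function() c("O3'H-O5", "O6H-O3'", "N'H-O6", "N'H-O4")

#' Enumerate symmetry-equivalent instances of the named H-bond pairs
#'
#' Lists every (donor, hydrogen, acceptor) triple on the reference
#' structure that matches a named pair's atom names and topological
#' relation and whose reference donor-acceptor distance is at most
#' `max_ref_dist` (drops geometrically impossible symmetry partners).
#'
#' @param reference a `cf_structure` (typically the built fibril).
#' @param topology a `cf_topology`.
#' @param pairs character vector of pair labels (default all four named
#'   pairs).
#' @param max_ref_dist enumeration distance cutoff in Angstrom (default 4).
#' @return data.frame with columns `pair`, `donor`, `hydrogen`,
#'   `acceptor`, `ref_distance`.
#' @export
enumerate_pair_instances <- function(reference, topology,
                                     pairs = named_pairs(),
                                     max_ref_dist = 4.0) {
  loose <- hbond_criteria(max_dist = max_ref_dist, min_angle = 1e-6)
  ev <- detect_hbonds(reference, loose, topology)
  ev <- ev[ev$pair %in% pairs, c("pair", "donor", "hydrogen", "acceptor",
                                 "distance")]
  names(ev)[names(ev) == "distance"] <- "ref_distance"
  rownames(ev) <- NULL
  ev[order(ev$pair, ev$donor, ev$acceptor), ]
}

#' Hydrogen-bond occupancy table
#'
#' Occupancy of each named pair instance = bonded frames / total frames;
#' pooled per pair as the mean over its symmetry-equivalent instances.
#'
#' @param traj a `cf_trajectory`.
#' @param topology a `cf_topology`.
#' @param criteria a [hbond_criteria()].
#' @param pairs pair labels to report (default the four named pairs).
#' @param reference `cf_structure` used to enumerate instances (default:
#'   frame 1 of `traj`).
#' @param instances optional pre-computed instance table from
#'   [enumerate_pair_instances()] (overrides `reference`).
#' @param events optional per-frame event list from [detect_hbonds_all()].
#' @return list with `table` (per-pair data.frame: `pair`, `category`,
#'   `occupancy`, `mean_count`, `n_frames`, `n_instances`) and
#'   `per_instance` (per-instance occupancies for diagnostics).
#' @export
hbond_occupancy <- function(traj, topology, criteria = hbond_criteria(),
                            pairs = named_pairs(), reference = NULL,
                            instances = NULL, events = NULL) {
  nf <- n_frames(traj)
  if (nf < 1) stop("empty trajectory")
  bad <- setdiff(pairs, named_pairs())
  if (length(bad) > 0) stop("unknown pair label: ", paste(bad, collapse = ", "))
  if (is.null(instances)) {
    if (is.null(reference)) reference <- get_frame(traj, 1)
    instances <- enumerate_pair_instances(reference, topology, pairs)
  }
  instances <- instances[instances$pair %in% pairs, ]
  ikey <- paste(instances$donor, instances$acceptor)
  bonded <- matrix(0L, nrow(instances), nf)
  counts <- matrix(0, length(pairs), nf, dimnames = list(pairs, NULL))
  for (f in seq_len(nf)) {
    ev <- if (is.null(events)) {
      detect_hbonds(get_frame(traj, f), criteria, topology)
    } else events[[f]]
    ekey <- paste(ev$donor, ev$acceptor)
    bonded[, f] <- as.integer(ikey %in% ekey)
    tab <- table(factor(ev$pair, levels = pairs))
    counts[, f] <- as.numeric(tab)
  }
  inst_occ <- rowMeans(bonded)
  per_instance <- cbind(instances, occupancy = inst_occ)
  cat_of <- c("O3'H-O5" = "intra_chain", "O6H-O3'" = "intra_chain",
              "N'H-O6" = "intra_sheet", "N'H-O4" = "inter_sheet")
  tabdf <- data.frame(
    pair = pairs,
    category = unname(cat_of[pairs]),
    occupancy = vapply(pairs, function(p) {
      o <- inst_occ[instances$pair == p]
      if (length(o) == 0) 0 else mean(o)
    }, numeric(1)),
    mean_count = rowMeans(counts)[pairs],
    n_frames = nf,
    n_instances = vapply(pairs, function(p) sum(instances$pair == p),
                         integer(1)),
    row.names = NULL
  )
  list(table = tabdf, per_instance = per_instance)
}

#' Detect hydrogen bonds for every frame of a trajectory
#'
#' Convenience wrapper returning one classified event table per frame;
#' several aggregators accept this list to avoid re-detection.
#'
#' @param traj a `cf_trajectory`.
#' @param criteria a [hbond_criteria()].
#' @param topology a `cf_topology`.
#' @return list of event data.frames, one per frame.
#' @export
detect_hbonds_all <- function(traj, criteria = hbond_criteria(), topology) {
  lapply(seq_len(n_frames(traj)), function(f) {
    detect_hbonds(get_frame(traj, f), criteria, topology)
  })
}

#' Per-frame hydrogen-bond counts by category
#'
#' @param traj a `cf_trajectory`.
#' @param topology a `cf_topology`.
#' @param criteria a [hbond_criteria()].
#' @param events optional per-frame event list from [detect_hbonds_all()].
#' @return data.frame with one row per frame and columns `frame`,
#'   `intra_chain`, `intra_sheet`, `inter_sheet`, `chitosan_water`,
#'   `water_water`, `inter_chain` (= intra_sheet + inter_sheet).
#' @export
hbond_counts <- function(traj, topology, criteria = hbond_criteria(),
                         events = NULL) {
  cats <- c("intra_chain", "intra_sheet", "inter_sheet",
            "chitosan_water", "water_water")
  out <- lapply(seq_len(n_frames(traj)), function(f) {
    ev <- if (is.null(events)) {
      detect_hbonds(get_frame(traj, f), criteria, topology)
    } else events[[f]]
    n <- table(factor(ev$category, levels = cats))
    c(frame = f, as.numeric(n))
  })
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("frame", cats)
  df$inter_chain <- df$intra_sheet + df$inter_sheet
  df
}

#' Fraction of maximal inter-chain hydrogen bonds
#'
#' Each frame's inter-chain (intra-sheet + inter-sheet) H-bond count
#' divided by the count in a reference structure analysed under the same
#' criteria. Values may exceed 1.
#'
#' @param traj a `cf_trajectory`.
#' @param topology a `cf_topology`.
#' @param reference reference `cf_structure` (e.g. the energy-minimized
#'   or built fibril).
#' @param criteria a [hbond_criteria()].
#' @param events optional per-frame event list from [detect_hbonds_all()].
#' @return data.frame with columns `frame`, `inter_chain`, `fraction`,
#'   plus attribute `reference_count`.
#' @export
fraction_of_max <- function(traj, topology, reference,
                            criteria = hbond_criteria(), events = NULL) {
  rev <- detect_hbonds(reference, criteria, topology)
  ref_n <- sum(rev$category %in% c("intra_sheet", "inter_sheet"))
  if (ref_n == 0) stop("reference structure has zero inter-chain H-bonds")
  cts <- hbond_counts(traj, topology, criteria, events = events)
  out <- data.frame(frame = cts$frame, inter_chain = cts$inter_chain,
                    fraction = cts$inter_chain / ref_n)
  attr(out, "reference_count") <- ref_n
  out
}
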