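test_that("distance and angle thresholds behave at the boundary", {
  # donor O - H - acceptor O, perfectly collinear
  mk <- function(d_oo) {
    toy_structure(c("O6", "HO6", "O5"), rep("GCS", 3), c("A", "A", "B"),
                  c(1, 1, 1),
                  rbind(c(0, 0, 0), c(1, 0, 0), c(d_oo, 0, 0)))
  }
  expect_equal(nrow(detect_hbonds(mk(3.6))), 0)     # just over 3.5
  ev <- detect_hbonds(mk(2.8))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$angle, 180, tolerance = 1e-9)
  expect_equal(ev$distance, 2.8, tolerance = 1e-12)
  # angle exactly at the threshold is excluded (criterion is strict)
  expect_equal(nrow(detect_hbonds(mk(2.8),
                                  hbond_criteria(min_angle = 180))), 0)
})

test_that("detector equals the brute-force O(N^2) oracle on toy frames", {
  # hand-placed 6-atom frame: two hydroxyls + one water
  fr <- toy_structure(
    c("O6", "HO6", "O3", "HO3", "O", "H1", "H2"),
    c("GCS", "GCS", "GCS", "GCS", "HOH", "HOH", "HOH"),
    c("A", "A", "A", "A", "W", "W", "W"), c(1, 1, 2, 2, 1, 1, 1),
    rbind(c(0, 0, 0), c(0.9, 0.3, 0), c(3.0, 0.5, 0), c(2.2, 0.4, 0.3),
          c(1.5, 2.6, 0.2), c(1.0, 1.8, 0.1), c(2.3, 2.9, 0.2)))
  crit <- hbond_criteria()
  got <- detect_hbonds(fr, crit)
  ora <- brute_force_hbonds(fr, crit)
  expect_gt(nrow(ora), 0)
  expect_identical(event_key(got), event_key(ora))

  # random solvated frames (<= 200 atoms), with and without a box
  for (seed in 1:6) {
    box <- if (seed %% 2 == 0) c(25, 25, 30) else NULL
    tf <- random_toy_frame(seed, n_waters = 18, box = box)
    got <- detect_hbonds(tf$frame, crit)
    ora <- brute_force_hbonds(tf$frame, crit)
    expect_identical(event_key(got), event_key(ora))
  }
})

test_that("minimum-image convention finds bonds across the box", {
  # donor near one box face, acceptor near the opposite face
  fr <- toy_structure(c("O6", "HO6", "O5"), rep("GCS", 3), c("A", "A", "B"),
                      c(1, 1, 1),
                      rbind(c(0.5, 5, 5), c(-0.5, 5, 5), c(18.0, 5, 5)),
                      box = c(20, 20, 20))
  ev <- detect_hbonds(fr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$distance, 2.5, tolerance = 1e-9)
  # same frame without a box: no bond
  fr$box <- NULL
  expect_equal(nrow(detect_hbonds(fr)), 0)
})

test_that("classification assigns the named pairs by topology", {
  fib <- default_fibril()
  inst <- enumerate_pair_instances(fib$structure, fib$topology)
  a <- fib$structure$atoms
  expect_setequal(unique(inst$pair), named_pairs())

  # intra-chain O3'H-O5: donor hydroxyl on residue i+1, acceptor O5 on i
  ic <- inst[inst$pair == "O3'H-O5", ]
  expect_true(all(a$chain[ic$donor] == a$chain[ic$acceptor]))
  expect_true(all(a$resid[ic$donor] == a$resid[ic$acceptor] + 1))
  expect_true(all(a$name[ic$donor] == "O3" & a$name[ic$acceptor] == "O5"))

  # intra-sheet N'H-O6: adjacent chains of the same sheet
  is_ <- inst[inst$pair == "N'H-O6", ]
  topo <- fib$topology
  expect_true(all(topo$chain_to_sheet[a$chain[is_$donor]] ==
                    topo$chain_to_sheet[a$chain[is_$acceptor]]))
  expect_true(all(abs(topo$chain_pos[a$chain[is_$donor]] -
                        topo$chain_pos[a$chain[is_$acceptor]]) == 1))

  # inter-sheet N'H-O4: adjacent sheets
  xs <- inst[inst$pair == "N'H-O4", ]
  expect_true(all(abs(topo$chain_to_sheet[a$chain[xs$donor]] -
                        topo$chain_to_sheet[a$chain[xs$acceptor]]) == 1))
  expect_true(all(a$name[xs$donor] == "N" & a$name[xs$acceptor] == "O4"))

  # unknown chain errors
  fr <- toy_structure(c("O6", "HO6", "O5"), rep("GCS", 3), c("Q", "Q", "Q"),
                      c(1, 1, 2),
                      rbind(c(0, 0, 0), c(1, 0, 0), c(2.8, 0, 0)))
  expect_error(detect_hbonds(fr, topology = toy_topology()), "topology")
})

test_that("partition property: every chitosan-chitosan event has one category", {
  crit <- hbond_criteria()
  for (seed in 1:3) {
    tf <- random_toy_frame(seed + 20, n_waters = 10)
    ev <- detect_hbonds(tf$frame, crit, tf$topology)
    if (nrow(ev) == 0) next
    expect_true(all(ev$category %in% c("intra_chain", "intra_sheet",
                                       "inter_sheet", "chitosan_water",
                                       "water_water")))
    cc <- ev$category %in% c("intra_chain", "intra_sheet", "inter_sheet")
    a <- tf$frame$atoms
    both_chit <- a$resname[ev$donor] != "HOH" & a$resname[ev$acceptor] != "HOH"
    expect_identical(cc, both_chit)
  }
})

test_that("monotonicity: relaxing criteria never removes an event", {
  for (seed in 4:6) {
    tf <- random_toy_frame(seed + 40, n_waters = 15)
    tight <- detect_hbonds(tf$frame, hbond_criteria(3.2, 145))
    loose <- detect_hbonds(tf$frame, hbond_criteria(3.8, 120))
    expect_true(all(event_key(tight) %in% event_key(loose)))
  }
})

test_that("occupancy counts frames directly and flags unknown pairs", {
  fib <- small_fibril()
  topo <- fib$topology
  s0 <- fib$structure
  inst <- enumerate_pair_instances(s0, topo, pairs = "O3'H-O5")
  one <- inst[1, ]
  xyz <- coords(s0)
  bond_on <- function(m) {
    d <- m[one$donor, ]; ac <- m[one$acceptor, ]
    nv <- (ac - d) / sqrt(sum((ac - d)^2))
    m[one$hydrogen, ] <- d + nv
    m
  }
  frames <- list(bond_on(xyz), bond_on(xyz), xyz, bond_on(xyz))
  traj <- new_trajectory(s0$atoms, frames)
  occ <- hbond_occupancy(traj, topo, pairs = "O3'H-O5", instances = one)
  expect_equal(occ$table$occupancy, 0.75)

  # a pair never formed has occupancy exactly 0
  occ0 <- hbond_occupancy(new_trajectory(s0$atoms, list(xyz, xyz)), topo,
                          pairs = "O6H-O3'")
  expect_equal(occ0$table$occupancy, 0)

  expect_error(hbond_occupancy(traj, topo, pairs = "bogus"), "unknown pair")
})

test_that("occupancy is invariant under relabeling equivalent chains", {
  fib <- small_fibril()
  cfg <- synthetic_config(seed = 5, n_frames = 30,
                          planted_occupancy = c("O3'H-O5" = 0.6))
  g <- generate_trajectory(fib, cfg)
  occ1 <- hbond_occupancy(g$trajectory, fib$topology,
                          instances = g$truth$instances)
  # relabel: swap the two chains of sheet 1 (equivalent by symmetry)
  topo2 <- fib$topology
  perm <- topo2$chain_ids
  i1 <- which(topo2$chain_to_sheet == 1)
  perm[i1] <- rev(perm[i1])
  atoms2 <- g$trajectory$atoms
  map <- setNames(perm, topo2$chain_ids)
  atoms2$chain <- ifelse(atoms2$chain == "W", "W", map[atoms2$chain])
  traj2 <- new_trajectory(atoms2, g$trajectory$frames, g$trajectory$box)
  occ2 <- hbond_occupancy(traj2, fib$topology,
                          reference = get_frame(traj2, 1))
  expect_equal(occ2$table$occupancy[occ2$table$pair == "O3'H-O5"],
               occ1$table$occupancy[occ1$table$pair == "O3'H-O5"],
               tolerance = 1e-12)
})

test_that("fraction_of_max normalises against the reference structure", {
  fib <- small_fibril()
  topo <- fib$topology
  # reference: all inter-chain pairs planted on
  cfg_on <- synthetic_config(seed = 9, n_frames = 1, jitter_sigma = 0,
                             planted_occupancy = c("N'H-O4" = 1))
  ref <- get_frame(generate_trajectory(fib, cfg_on)$trajectory, 1)

  traj_same <- new_trajectory(ref$atoms, list(coords(ref)))
  fm <- fraction_of_max(traj_same, topo, ref)
  expect_equal(fm$fraction, 1.0)

  # all inter-chain bonds broken -> 0
  base <- fib$structure
  traj_off <- new_trajectory(base$atoms, list(coords(base)))
  fm0 <- fraction_of_max(traj_off, topo, ref)
  expect_equal(fm0$fraction, 0.0)

  # zero reference count errors
  expect_error(fraction_of_max(traj_off, topo, base), "zero")
})

test_that("fraction_of_max recovers a planted 60% bond fraction", {
  fib <- small_fibril()
  topo <- fib$topology
  cfg_ref <- synthetic_config(seed = 2, n_frames = 1, jitter_sigma = 0,
                              planted_occupancy = c("N'H-O4" = 1, "N'H-O6" = 1))
  ref <- get_frame(generate_trajectory(fib, cfg_ref)$trajectory, 1)
  cfg <- synthetic_config(seed = 3, n_frames = 60,
                          planted_occupancy = c("N'H-O4" = 0.6, "N'H-O6" = 0.6))
  g <- generate_trajectory(fib, cfg)
  fm <- fraction_of_max(g$trajectory, topo, ref)
  n_ref <- attr(fm, "reference_count")
  # sampling error of the planted Bernoulli fraction
  se <- sqrt(0.6 * 0.4 / (n_ref * 60))
  expect_lt(abs(mean(fm$fraction) - 0.6), 4 * se + 0.01)
})

test_that("detector enforces donor hydrogen preconditions", {
  fr <- toy_structure(c("O6", "O5"), c("GCS", "GCS"), c("A", "B"), c(1, 1),
                      rbind(c(0, 0, 0), c(2.8, 0, 0)))
  expect_error(detect_hbonds(fr), "no covalently assigned hydrogen")
  expect_error(hbond_criteria(max_dist = -1))
  expect_error(hbond_criteria(min_angle = 200))
})
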