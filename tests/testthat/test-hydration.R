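test_that("water classes follow the 3.5 / 10 A shells", {
  fib <- quad_fibril()
  s0 <- fib$structure
  a <- s0$atoms
  # one water 2 A from a chitosan O6, one 15 A beyond every heavy atom
  o6 <- which(a$name == "O6")[1]
  near <- coords(s0)[o6, ] + c(0, 2, 0)
  far <- c(max(a$x) + 15, mean(a$y), mean(a$z))
  mid <- c(max(a$x) + 6, mean(a$y), mean(a$z))
  wat <- data.frame(
    name = rep(c("O", "H1", "H2"), 3), resname = "HOH", chain = "W",
    resid = rep(1:3, each = 3),
    x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  pos <- rbind(near, near + c(0.6, 0.6, 0), near + c(-0.6, 0.6, 0),
               far, far + c(0.6, 0.6, 0), far + c(-0.6, 0.6, 0),
               mid, mid + c(0.6, 0.6, 0), mid + c(-0.6, 0.6, 0))
  wat$x <- pos[, 1]; wat$y <- pos[, 2]; wat$z <- pos[, 3]
  a$element <- NULL
  fr <- new_structure(rbind(a, wat))
  wa <- assign_waters(fr, fib$topology)
  expect_equal(wa$class, c("bound", "bulk", "neither"))
  # bound and bulk can never overlap
  expect_equal(sum(wa$class == "bound" & wa$min_dist >= 3.5), 0)
  expect_error(assign_waters(fr, fib$topology, bound_cutoff = 11), "cutoff")
  expect_error(assign_waters(s0, fib$topology), "no waters")
})

test_that("water classes equal the exhaustive minimum-distance oracle", {
  for (seed in 1:3) {
    tf <- random_toy_frame(seed + 60, n_waters = 50)
    fr <- tf$frame
    wa <- assign_waters(fr, tf$topology)
    xyz <- coords(fr)
    chit <- which(!is_water(fr) & is_heavy(fr))
    for (k in seq_len(nrow(wa))) {
      dmin <- min(sqrt(rowSums(sweep(xyz[chit, , drop = FALSE], 2,
                                     xyz[wa$oxygen[k], ])^2)))
      expect_equal(wa$min_dist[k], dmin, tolerance = 1e-9)
      expected <- if (dmin < 3.5) "bound" else if (dmin >= 10) "bulk"
                  else "neither"
      expect_identical(wa$class[k], expected)
    }
  }
})

test_that("interior water count recovers planted placements exactly", {
  fib <- quad_fibril()
  # zero waters in the slab
  cfg0 <- synthetic_config(seed = 1, n_frames = 2, n_bulk_waters = 10)
  g0 <- generate_trajectory(fib, cfg0)
  iw0 <- interior_water_count(g0$trajectory, fib$topology)
  expect_equal(iw0$n_interior, c(0L, 0L))

  # planted k = 12 inside, 50 in the bulk
  cfg <- synthetic_config(seed = 2, n_frames = 3, n_interior_waters = 12,
                          n_bulk_waters = 50)
  g <- generate_trajectory(fib, cfg)
  iw <- interior_water_count(g$trajectory, fib$topology)
  expect_equal(iw$n_interior, rep(12L, 3))

  # planted decay schedule recovered exactly, frame by frame
  sched <- round(seq(30, 5, length.out = 8))
  cfgd <- synthetic_config(seed = 3, n_frames = 8,
                           n_interior_waters = sched, n_bulk_waters = 10)
  gd <- generate_trajectory(fib, cfgd)
  iwd <- interior_water_count(gd$trajectory, fib$topology)
  expect_equal(iwd$n_interior, gd$truth$per_frame$n_interior)
  expect_equal(iwd$n_interior, as.integer(sched))

  expect_error(interior_water_count(g$trajectory, small_fibril()$topology),
               "4 sheets")
})

test_that("water bridges: combinatorics and planted categories", {
  # water bonded to one chitosan atom only -> no bridge
  one <- toy_structure(
    c("O6", "HO6", "O", "H1", "H2"),
    c("GCS", "GCS", "HOH", "HOH", "HOH"),
    c("A", "A", "W", "W", "W"), c(1, 1, 1, 1, 1),
    rbind(c(0, 0, 0), c(-0.9, 0, 0), c(2.8, 0, 0), c(1.85, 0, 0),
          c(3.1, 0.9, 0)))
  br1 <- detect_water_bridges(one, topology = toy_topology())
  expect_equal(nrow(br1), 0)

  # water H-bonded to three chitosan atoms A, B, C -> exactly 3 bridges,
  # equal to the pair enumeration C(3,2)
  tri <- toy_structure(
    c("O6", "HO6", "O4", "O5", "O", "H1", "H2"),
    c(rep("GCS", 4), rep("HOH", 3)),
    c("A", "A", "B", "G", "W", "W", "W"), c(1, 1, 1, 1, 1, 1, 1),
    rbind(c(2.9, 0, 0), c(1.95, 0, 0),          # O6 donates to the water
          c(-2.9, 0, 0), c(0, 2.9, 0),          # two acceptors
          c(0, 0, 0), c(-0.96, 0, 0), c(0, 0.96, 0)))
  br3 <- detect_water_bridges(tri, topology = toy_topology())
  expect_equal(nrow(br3), 3)
  expect_equal(nrow(unique(br3[, c("atom1", "atom2")])), 3)
  # categories from the partner chains: A+B same sheet, G other sheet
  expect_setequal(br3$category, c("intra_sheet", "inter_sheet", "inter_sheet"))

  # every bridge implies two chitosan-water events in the same frame
  ev <- detect_hbonds(tri, topology = toy_topology())
  expect_gte(sum(ev$category == "chitosan_water"), 3)
})

test_that("planted bridge sites are recovered with survival statistics", {
  fib <- quad_fibril()
  cfg <- synthetic_config(seed = 8, n_frames = 40, n_bridge_sites = 5,
                          n_intra_bridge_sites = 3, bridge_survival_p = 0.7,
                          n_bulk_waters = 10)
  g <- generate_trajectory(fib, cfg)
  gt <- g$truth$per_frame
  got_inter <- got_intra <- integer(40)
  for (f in 1:40) {
    fr <- get_frame(g$trajectory, f)
    br <- detect_water_bridges(fr, topology = fib$topology)
    got_inter[f] <- sum(br$category == "inter_sheet")
    got_intra[f] <- sum(br$category == "intra_sheet")
  }
  expect_equal(got_inter, gt$n_bridges_inter)
  expect_equal(got_intra, gt$n_bridges_intra)
  # survival estimate within the 99.9% binomial band of p = 0.7
  phat <- sum(got_inter + got_intra) / (8 * 40)
  se <- sqrt(0.7 * 0.3 / (8 * 40))
  expect_lt(abs(phat - 0.7), 3.3 * se)
})

test_that("dry trajectories zero hydration but keep chitosan H-bonds", {
  fib <- quad_fibril()
  cfg <- synthetic_config(seed = 4, n_frames = 3,
                          planted_occupancy = c("O3'H-O5" = 0.8),
                          n_interior_waters = 10, n_bridge_sites = 3,
                          n_bulk_waters = 15)
  g <- generate_trajectory(fib, cfg)
  traj <- g$trajectory
  # strip all waters
  keep <- traj$atoms$resname != "HOH"
  dry <- new_trajectory(traj$atoms[keep, ],
                        lapply(traj$frames, function(m) m[keep, , drop = FALSE]),
                        traj$box)
  hyd <- hydration_summary(dry, fib$topology)
  expect_true(all(hyd$n_bound == 0 & hyd$n_bulk == 0 & hyd$n_interior == 0 &
                    hyd$n_bridges_inter == 0 & hyd$n_bridges_intra == 0))
  wet_counts <- hbond_counts(traj, fib$topology)
  dry_counts <- hbond_counts(dry, fib$topology)
  for (cat in c("intra_chain", "intra_sheet", "inter_sheet")) {
    expect_equal(dry_counts[[cat]], wet_counts[[cat]])
  }
  cw <- chitosan_water_table(dry, fib$topology)
  expect_true(all(cw$mean_count == 0))
})

test_that("chitosan-water table resolves roles on interior chains", {
  fib <- quad_fibril()
  s0 <- fib$structure
  a <- s0$atoms
  topo <- fib$topology
  interior <- topo$chain_ids[topo$chain_to_sheet %in% c(2, 3)]
  # single water accepting from an interior O3H only
  o3 <- which(a$name == "O3" & a$chain == interior[1])[2]
  ho3 <- which(a$name == "HO3" & a$chain == interior[1] &
                 a$resid == a$resid[o3])
  d <- coords(s0)[o3, ]
  # place the water along +y from the hydroxyl, hydrogen pointing at it
  owat <- d + c(0, 2.8, 0)
  xyz <- coords(s0)
  xyz[ho3, ] <- d + c(0, 1, 0)
  wat <- data.frame(name = c("O", "H1", "H2"), resname = "HOH", chain = "W",
                    resid = 1, x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  wpos <- rbind(owat, owat + c(0.75, 0.6, 0), owat + c(-0.75, 0.6, 0))
  wat$x <- wpos[, 1]; wat$y <- wpos[, 2]; wat$z <- wpos[, 3]
  a2 <- a; a2$element <- NULL
  a2$x <- xyz[, 1]; a2$y <- xyz[, 2]; a2$z <- xyz[, 3]
  fr <- new_structure(rbind(a2, wat))
  traj <- new_trajectory(fr$atoms, list(coords(fr)))
  tab <- chitosan_water_table(traj, topo)
  expect_equal(sum(tab$mean_count > 0), 1)
  expect_equal(tab$atom[tab$mean_count > 0], "O3")
  expect_equal(tab$role[tab$mean_count > 0], "donor")
  expect_equal(tab$mean_count[tab$mean_count > 0], 1)
  expect_error(chitosan_water_table(traj, small_fibril()$topology), "4 sheets")
})

test_that("planted chitosan-water rate is recovered on interior chains", {
  fib <- quad_fibril()
  # plant a known number of O3H-water bonds per frame by bridge-free
  # construction: use bridge sites' two bonds as the planted rate
  cfg <- synthetic_config(seed = 12, n_frames = 30, n_bridge_sites = 4,
                          bridge_survival_p = 1.0, n_bulk_waters = 5)
  g <- generate_trajectory(fib, cfg)
  tab <- chitosan_water_table(g$trajectory, fib$topology)
  # every surviving bridge contributes exactly two acceptor-role bonds
  # on interior chains (partners are interior acceptors by construction)
  expect_equal(sum(tab$mean_count[tab$role == "acceptor"]), 8,
               tolerance = 1e-9)
})
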