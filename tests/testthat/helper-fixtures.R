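# Shared fixtures: all built in code, nothing on disk.

# Full default fibril, built once per test run.
default_fibril <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_fibril()
    cache
  }
})

# Small fibril for fast trajectory round trips (2 sheets x 2 chains x 8).
small_fibril <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_fibril(fibril_spec(n_sheets = 2, chains_per_sheet = 2,
                                         dp = 8))
    }
    cache
  }
})

# Small 4-sheet fibril (hydration/stacking observables need 4 sheets).
quad_fibril <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_fibril(fibril_spec(n_sheets = 4, chains_per_sheet = 3,
                                         dp = 8))
    }
    cache
  }
})

# Single-row structure helper for hand-placed toy frames.
toy_structure <- function(names, resnames, chains, resids, xyz, box = NULL) {
  new_structure(data.frame(
    name = names, resname = resnames, chain = chains, resid = resids,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE),
    box = box)
}

# A free-standing topology for toy chitosan chains A, B (sheet 1) and
# G (sheet 2).
toy_topology <- function() {
  new_topology(c("A", "B", "G"), sheet = c(1L, 1L, 2L),
               direction = c(1L, 1L, -1L), pos = c(1L, 2L, 1L),
               spec = fibril_spec(n_sheets = 2, chains_per_sheet = 2,
                                  dp = 2, sugars_per_c_repeat = 1))
}

# Independent brute-force H-bond oracle: loops over every donor
# hydrogen and every acceptor, O(N^2), no shared code with the
# vectorised detector beyond the covalent H->parent naming rule.
brute_force_hbonds <- function(frame, criteria) {
  a <- frame$atoms
  box <- frame$box
  hmap <- c(HN = "N", HO3 = "O3", HO6 = "O6", H1 = "O", H2 = "O")
  xyz <- coords(frame)
  acc <- which((a$resname != "HOH" & a$name %in% c("N", "O3", "O4", "O5", "O6")) |
               (a$resname == "HOH" & a$name == "O"))
  res <- list()
  mic <- function(v) {
    if (!is.null(box)) v - box * round(v / box) else v
  }
  for (h in which(a$name %in% names(hmap))) {
    d <- which(a$chain == a$chain[h] & a$resid == a$resid[h] &
               a$name == hmap[[a$name[h]]])
    if (length(d) != 1) stop("oracle: bad donor mapping")
    for (ac in acc) {
      if (ac == d) next
      dv <- mic(xyz[ac, ] - xyz[d, ])
      if (sqrt(sum(dv^2)) >= criteria$max_dist) next
      u <- mic(xyz[d, ] - xyz[h, ])
      v <- mic(xyz[ac, ] - xyz[h, ])
      ang <- acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) *
        180 / pi
      if (ang > criteria$min_angle) {
        res[[length(res) + 1L]] <- c(d, h, ac)
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0)))
  }
  m <- do.call(rbind, res)
  data.frame(donor = m[, 1], hydrogen = m[, 2], acceptor = m[, 3])
}

# Random solvated toy frame: a few chitosan residues plus scattered
# waters, used for oracle-equivalence properties (<= 200 atoms).
random_toy_frame <- function(seed, n_waters = 20, box = NULL) {
  set.seed(seed)
  fib <- build_fibril(fibril_spec(n_sheets = 2, chains_per_sheet = 1, dp = 4))
  a <- fib$structure$atoms
  xyz <- coords(fib$structure) + matrix(rnorm(3 * nrow(a), 0, 0.6), ncol = 3)
  wrows <- data.frame(
    name = rep(c("O", "H1", "H2"), n_waters), resname = "HOH", chain = "W",
    resid = rep(seq_len(n_waters), each = 3), x = 0, y = 0, z = 0,
    stringsAsFactors = FALSE)
  lo <- apply(xyz, 2, min) - 3; hi <- apply(xyz, 2, max) + 3
  wxyz <- do.call(rbind, lapply(seq_len(n_waters), function(i) {
    o <- runif(3, lo, hi)
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    e <- rnorm(3); e <- e - sum(e * d) * d; e <- e / sqrt(sum(e^2))
    ha <- 104.52 / 2 * pi / 180
    rbind(o, o + 0.9572 * (cos(ha) * d + sin(ha) * e),
          o + 0.9572 * (cos(ha) * d - sin(ha) * e))
  }))
  a$element <- NULL
  at <- rbind(a, wrows)
  at$x <- c(xyz[, 1], wxyz[, 1])
  at$y <- c(xyz[, 2], wxyz[, 2])
  at$z <- c(xyz[, 3], wxyz[, 3])
  list(frame = new_structure(at, box = box), topology = fib$topology)
}

event_key <- function(ev) {
  sort(paste(ev$donor, ev$hydrogen, ev$acceptor, sep = ":"))
}
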