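#' Orthorhombic unit cell with symmetry operators
#'
#' @param a,b,c lattice lengths in Angstrom. Defaults are the anhydrous
#'   chitosan cell (a = 8.129, b = 8.347, c = 10.311 A).
#' @param ops list of symmetry operators, each `list(R = 3x3 matrix with
#'   entries in \{-1,0,1\}, t = fractional translation)`. Defaults to the
#'   four operators of space group P2(1)2(1)2(1).
#' @return An object of class `cf_cell`.
#' @export
unit_cell <- function(a = 8.129, b = 8.347, c = 10.311, ops = p212121_ops()) {
  stopifnot(a > 0, b > 0, c > 0, length(ops) >= 1)
  for (op in ops) {
    stopifnot(is.matrix(op$R), all(dim(op$R) == c(3, 3)),
              all(op$R %in% c(-1, 0, 1)), length(op$t) == 3)
  }
  check_ops_closed(ops)
  structure(list(a = a, b = b, c = c, ops = ops), class = "cf_cell")
}

#' Symmetry operators of space group P2(1)2(1)2(1)
#'
#' Three mutually perpendicular two-fold screw axes:
#' (x,y,z); (x+1/2, -y+1/2, -z); (-x, y+1/2, -z+1/2); (-x+1/2, -y, z+1/2).
#'
#' @return List of four affine operators.
#' @export
p212121_ops <- function() {
  R1 <- diag(3)
  R2 <- diag(c(1, -1, -1))
  R3 <- diag(c(-1, 1, -1))
  R4 <- diag(c(-1, -1, 1))
  list(
    list(R = R1, t = c(0, 0, 0)),
    list(R = R2, t = c(0.5, 0.5, 0)),
    list(R = R3, t = c(0, 0.5, 0.5)),
    list(R = R4, t = c(0.5, 0, 0.5))
  )
}

# Operator set must be closed under composition modulo unit translations.
check_ops_closed <- function(ops) {
  key <- function(R, t) {
    t <- t - floor(t + 1e-9)
    paste(c(round(R), round(t * 1e6)), collapse = ",")
  }
  have <- vapply(ops, function(o) key(o$R, o$t), character(1))
  if (!key(diag(3), c(0, 0, 0)) %in% have) stop("identity operator missing")
  for (i in seq_along(ops)) {
    for (j in seq_along(ops)) {
      R <- ops[[i]]$R %*% ops[[j]]$R
      t <- ops[[i]]$R %*% ops[[j]]$t + ops[[i]]$t
      if (!key(R, t) %in% have) {
        stop("operator set not closed under composition (mod lattice translations)")
      }
    }
  }
  invisible(TRUE)
}

#' Asymmetric unit in fractional coordinates
#'
#' @param atoms data.frame with columns `name`, `resid`, `fx`, `fy`, `fz`
#'   (fractional coordinates); optional `resname` (default "GCS").
#' @return An object of class `cf_asym`.
#' @export
asymmetric_unit <- function(atoms) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  req <- c("name", "resid", "fx", "fy", "fz")
  if (!all(req %in% names(atoms))) {
    stop("asymmetric unit needs columns: ", paste(req, collapse = ", "))
  }
  if (!all(is.finite(atoms$fx) & is.finite(atoms$fy) & is.finite(atoms$fz))) {
    stop("non-finite fractional coordinates")
  }
  dup <- duplicated(atoms[, c("resid", "name")])
  if (any(dup)) stop("duplicate atom names within a residue")
  if (is.null(atoms$resname)) atoms$resname <- "GCS"
  structure(list(atoms = atoms), class = "cf_asym")
}

#' Expand an asymmetric unit by the cell's symmetry operators
#'
#' Applies every operator to the fractional coordinates and converts to
#' Cartesian Angstrom via `diag(a, b, c)`. Copies are labelled by operator
#' index through the chain id (`S1`, `S2`, ...). If any two atoms of
#' different copies fall closer than `clash` Angstrom a warning is emitted.
#'
#' @param asym a `cf_asym`.
#' @param cell a `cf_cell`.
#' @param clash clash-warning distance in Angstrom (default 1.0).
#' @return A `cf_structure` holding all symmetry copies.
#' @export
apply_symmetry <- function(asym, cell, clash = 1.0) {
  stopifnot(inherits(asym, "cf_asym"), inherits(cell, "cf_cell"))
  if (nrow(asym$atoms) == 0) stop("empty asymmetric unit")
  f <- as.matrix(asym$atoms[, c("fx", "fy", "fz")])
  out <- vector("list", length(cell$ops))
  for (i in seq_along(cell$ops)) {
    op <- cell$ops[[i]]
    fi <- t(op$R %*% t(f) + op$t)
    cart <- fi %*% diag(c(cell$a, cell$b, cell$c))
    out[[i]] <- data.frame(
      name = asym$atoms$name,
      resname = asym$atoms$resname,
      chain = paste0("S", i),
      resid = asym$atoms$resid,
      x = cart[, 1], y = cart[, 2], z = cart[, 3],
      stringsAsFactors = FALSE
    )
  }
  atoms <- do.call(rbind, out)
  s <- new_structure(atoms)
  if (length(cell$ops) > 1) {
    xyz <- coords(s)
    grp <- rep(seq_along(cell$ops), each = nrow(asym$atoms))
    dmin <- min_cross_distance(xyz, grp)
    if (is.finite(dmin) && dmin < clash) {
      warning(sprintf("symmetry copies approach within %.2f A (< %.2f A clash threshold)",
                      dmin, clash))
    }
  }
  s
}

# Minimum distance between points belonging to different groups.
min_cross_distance <- function(xyz, grp) {
  n <- nrow(xyz)
  if (n < 2) return(Inf)
  d2 <- as.matrix(stats::dist(xyz))^2
  same <- outer(grp, grp, "==")
  d2[same] <- Inf
  sqrt(min(d2))
}

#' Fibril build specification
#'
#' @param n_sheets number of stacked sheets (default 4).
#' @param chains_per_sheet chains in each sheet (default 6).
#' @param dp degree of polymerization, glucosamine units per chain
#'   (default 20).
#' @param sugars_per_c_repeat sugars in one c-repeat of the chain
#'   (default 2; `dp` must then be even).
#' @return An object of class `cf_fibril_spec`.
#' @export
fibril_spec <- function(n_sheets = 4, chains_per_sheet = 6, dp = 20,
                        sugars_per_c_repeat = 2) {
  stopifnot(n_sheets >= 1, chains_per_sheet >= 1, dp >= 1,
            sugars_per_c_repeat >= 1)
  if (dp %% sugars_per_c_repeat != 0) {
    stop("dp must be a multiple of sugars_per_c_repeat")
  }
  structure(list(n_sheets = n_sheets, chains_per_sheet = chains_per_sheet,
                 dp = dp, sugars_per_c_repeat = sugars_per_c_repeat),
            class = "cf_fibril_spec")
}

# Atoms a glucosamine residue template must provide.
required_template_atoms <- c("N", "O3", "O4", "O5", "O6",
                             "C1", "C2", "C3", "C4", "C5", "C6",
                             "HN", "HO3", "HO6")

#' Idealized glucosamine residue template (synthetic)
#'
#' A fixed, idealized coordinate set for one glucosamine unit, used to
#' build fibrils when no crystallographic asymmetric unit is supplied.
#' It is a *synthetic* lattice fixture, not the published crystal
#' coordinates: atom positions are chosen so that on the assembled
#' lattice every named hydrogen-bond pair type (O3'H-O5, O6H-O3',
#' N'H-O6, N'H-O4) has a donor-acceptor heavy-atom distance between
#' 2.5 and 3.2 Angstrom.
#'
#' @return data.frame with columns `name`, `x`, `y`, `z` (local
#'   coordinates in Angstrom, ring centre at the origin, chain axis z).
#' @export
glucosamine_template <- function() {
  heavy <- data.frame(
    name = c("C1", "C2", "C3", "C4", "C5", "O5",
             "N", "O3", "O4", "O6", "C6"),
    x = c(-0.75, -1.45, -0.75, 0.75, 1.45, 0.75,
          -2.85, -1.90, -0.70, 2.60, 2.50),
    y = c(0, 0, 0, 0, 0, 0,
          0.80, 0.50, 1.10, 0.30, 0.70),
    z = c(1.25, 0, -1.25, -1.25, 0, 1.25,
          0.30, -1.75, -2.30, 0.90, -0.20),
    stringsAsFactors = FALSE
  )
  # Resting donor hydrogens point inward along the heteroatom -> carbon
  # bond, so no unplanted donor can satisfy the angle criterion with any
  # acceptor (acceptors all lie outward of the donor).
  hpos <- function(hname, from, towards) {
    a <- unlist(heavy[heavy$name == from, c("x", "y", "z")])
    b <- unlist(heavy[heavy$name == towards, c("x", "y", "z")])
    u <- (b - a) / sqrt(sum((b - a)^2))
    data.frame(name = hname, x = a[1] + u[1], y = a[2] + u[2],
               z = a[3] + u[3], stringsAsFactors = FALSE)
  }
  out <- rbind(heavy,
               hpos("HN", "N", "C2"),
               hpos("HO3", "O3", "C3"),
               hpos("HO6", "O6", "C6"))
  rownames(out) <- NULL
  out
}

# Antiparallel sheets are built by a 180-degree rotation about y
# (x -> -x, z -> zc - z). This z-registry constant fixes zc so that
# inter-sheet N'H...O4 donor and acceptor z-coordinates coincide
# exactly on the ideal lattice (builder convention).
SHEET_FLIP_Z_SHIFT <- -2.0

#' Build an oriented chitosan nanofibril with full topology
#'
#' Chains are elongated along z by stacking `dp / sugars_per_c_repeat`
#' c-translations of a two-sugar repeat (the second sugar is the 2(1)
#' screw image of the first). Chains within a sheet are offset by one
#' a-translation along x; sheets are stacked along y at b/2 spacing
#' (the unit cell holds two antiparallel sheets) with adjacent sheets
#' rotated 180 degrees about y and z-registry shifted.
#'
#' @param spec a [fibril_spec()].
#' @param cell a [unit_cell()].
#' @param template residue template data.frame (see
#'   [glucosamine_template()]), or a `cf_asym` whose first residue is
#'   used as the template (fractional coordinates converted with `cell`).
#' @return list with elements `structure` (a `cf_structure`) and
#'   `topology` (a `cf_topology`).
#' @export
build_fibril <- function(spec = fibril_spec(), cell = unit_cell(),
                         template = glucosamine_template()) {
  stopifnot(inherits(spec, "cf_fibril_spec"), inherits(cell, "cf_cell"))
  if (inherits(template, "cf_asym")) {
    a1 <- template$atoms[template$atoms$resid == template$atoms$resid[1], ]
    template <- data.frame(name = a1$name,
                           x = a1$fx * cell$a, y = a1$fy * cell$b,
                           z = a1$fz * cell$c, stringsAsFactors = FALSE)
    template$x <- template$x - mean(template$x)
    template$y <- template$y - mean(template$y)
    template$z <- template$z - mean(template$z)
  }
  miss <- setdiff(required_template_atoms, template$name)
  if (length(miss) > 0) {
    stop("template missing required named atoms: ", paste(miss, collapse = ", "))
  }

  n_chains <- spec$n_sheets * spec$chains_per_sheet
  if (n_chains > 26 * 27) stop("spec requests more chains than nameable")
  chain_ids <- chain_id_seq(n_chains)
  sper <- spec$sugars_per_c_repeat
  step <- cell$c / sper                     # z advance per sugar
  half_b <- cell$b / 2                      # sheet stacking spacing
  zc <- (spec$dp - 1) * step + SHEET_FLIP_Z_SHIFT

  # one chain in local coordinates: dp residues on the 2(1) screw
  res_idx <- seq_len(spec$dp)
  per_res <- nrow(template)
  chain_local <- do.call(rbind, lapply(res_idx, function(k) {
    sgn <- if ((k - 1) %% 2 == 0) 1 else -1   # screw alternation of x,y
    data.frame(name = template$name,
               resid = k,
               x = sgn * template$x,
               y = sgn * template$y,
               z = template$z + (k - 1) * step,
               stringsAsFactors = FALSE)
  }))

  rows <- vector("list", n_chains)
  chain_sheet <- integer(n_chains)
  chain_dirn <- integer(n_chains)
  chain_pos <- integer(n_chains)
  idx <- 0L
  for (s in seq_len(spec$n_sheets)) {
    flip <- (s %% 2 == 0)                   # sheets 2, 4, ... antiparallel
    for (p in seq_len(spec$chains_per_sheet)) {
      idx <- idx + 1L
      ch <- chain_local
      if (flip) {
        ch$x <- -ch$x
        ch$z <- zc - ch$z
      }
      ch$x <- ch$x + (p - 1) * cell$a
      ch$y <- ch$y + (s - 1) * half_b
      rows[[idx]] <- data.frame(name = ch$name, resname = "GCS",
                                chain = chain_ids[idx], resid = ch$resid,
                                x = ch$x, y = ch$y, z = ch$z,
                                stringsAsFactors = FALSE)
      chain_sheet[idx] <- s
      chain_dirn[idx] <- if (flip) -1L else 1L
      chain_pos[idx] <- p
    }
  }
  atoms <- do.call(rbind, rows)
  st <- new_structure(atoms)
  topo <- new_topology(chain_ids, chain_sheet, chain_dirn, chain_pos, spec)
  list(structure = st, topology = topo)
}

# Chain id sequence: A..Z then AA, AB, ... (default fibril uses A..X).
chain_id_seq <- function(n) {
  if (n <= 26) return(LETTERS[seq_len(n)])
  extra <- as.vector(t(outer(LETTERS, LETTERS, paste0)))
  c(LETTERS, extra)[seq_len(n)]
}

#' Fibril topology map
#'
#' @param chain_ids character chain ids in build order.
#' @param sheet integer sheet index per chain (1-based, along +y).
#' @param direction +1/-1 chain direction along the fibril axis.
#' @param pos position of the chain within its sheet (1-based, along +x).
#' @param spec the originating [fibril_spec()].
#' @return An object of class `cf_topology`.
#' @export
new_topology <- function(chain_ids, sheet, direction, pos, spec) {
  stopifnot(length(chain_ids) == length(sheet),
            length(sheet) == length(direction),
            length(direction) == length(pos),
            all(direction %in% c(-1L, 1L)))
  structure(list(
    chain_ids = chain_ids,
    chain_to_sheet = setNames(as.integer(sheet), chain_ids),
    chain_direction = setNames(as.integer(direction), chain_ids),
    chain_pos = setNames(as.integer(pos), chain_ids),
    n_sheets = spec$n_sheets,
    chains_per_sheet = spec$chains_per_sheet,
    dp = spec$dp
  ), class = "cf_topology")
}

#' @export
print.cf_topology <- function(x, ...) {
  cat("<cf_topology> ", length(x$chain_ids), " chains in ", x$n_sheets,
      " sheets x ", x$chains_per_sheet, " chains, dp ", x$dp, "\n", sep = "")
  invisible(x)
}

#' Orient a fibril onto its canonical axes
#'
#' Rigid-body transform placing the longest principal extent of the
#' heavy atoms along z (fibril elongation), the second along x (sheet
#' growth) and the shortest along y (sheet stacking). An
#' already-oriented fibril is returned unchanged to numerical tolerance.
#'
#' @param s a `cf_structure`.
#' @param t a `cf_topology` (used only to restrict to chitosan atoms).
#' @return The re-oriented `cf_structure`.
#' @export
orient_fibril <- function(s, t = NULL) {
  sel <- is_heavy(s) & !is_water(s)
  xyz <- coords(s, sel)
  ctr <- colMeans(xyz)
  cc <- sweep(xyz, 2, ctr)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  if (ev$values[2] < 1e-10 * max(ev$values[1], 1)) {
    stop("degenerate geometry: atoms are collinear")
  }
  # eigenvectors ordered by decreasing variance -> map to (z, x, y)
  axes <- ev$vectors[, c(2, 3, 1)]   # columns become new x, y, z
  # fix signs so the rotation is as close to identity as possible
  for (k in 1:3) if (axes[k, k] < 0) axes[, k] <- -axes[, k]
  if (det(axes) < 0) axes[, 2] <- -axes[, 2]
  all_xyz <- coords(s)
  rot <- sweep(all_xyz, 2, ctr) %*% axes
  set_coords(s, sweep(rot, 2, ctr, FUN = "+"))
}
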