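#' Create a molecular structure
#'
#' A `cf_structure` is the package's snapshot container: an atom table
#' (name, element, residue name, chain id, residue index, Cartesian
#' coordinates in Angstrom, optional partial charge in units of the
#' elementary charge) plus an optional orthorhombic box.
#'
#' @param atoms data.frame with columns `name`, `resname`, `chain`,
#'   `resid`, `x`, `y`, `z`; optional `element` (derived from `name` if
#'   absent) and `charge`.
#' @param box numeric length-3 vector of orthorhombic box edge lengths in
#'   Angstrom, or `NULL`.
#' @return An object of class `cf_structure`.
#' @export
new_structure <- function(atoms, box = NULL) {
  stopifnot(is.data.frame(atoms))
  req <- c("name", "resname", "chain", "resid", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0) {
    stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in atom table")
  }
  if (is.null(atoms$element)) {
    atoms$element <- guess_element(atoms$name)
  }
  if (!is.null(atoms$charge) && anyNA(atoms$charge)) {
    stop("charge column present but contains NA")
  }
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
      stop("box must be three positive edge lengths")
    }
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, box = box), class = "cf_structure")
}

# Element from PDB-style atom name: leading H -> hydrogen, else first letter.
guess_element <- function(name) {
  ifelse(grepl("^H", name), "H", substr(name, 1, 1))
}

#' @export
print.cf_structure <- function(x, ...) {
  a <- x$atoms
  cat("<cf_structure> ", nrow(a), " atoms, ",
      length(unique(a$chain)), " chains, ",
      sum(a$resname == "HOH") / 3, " waters",
      if (!is.null(x$box)) sprintf(", box %.1f x %.1f x %.1f A",
                                   x$box[1], x$box[2], x$box[3]) else "",
      "\n", sep = "")
  invisible(x)
}

#' Coordinate matrix of a structure
#'
#' @param s a `cf_structure`.
#' @param sel optional logical or integer atom selection.
#' @return n x 3 numeric matrix (Angstrom).
#' @export
coords <- function(s, sel = NULL) {
  m <- cbind(x = s$atoms$x, y = s$atoms$y, z = s$atoms$z)
  if (!is.null(sel)) m <- m[sel, , drop = FALSE]
  m
}

#' Replace the coordinates of a structure
#'
#' @param s a `cf_structure`.
#' @param m n x 3 matrix matching the atom count.
#' @return The modified structure.
#' @export
set_coords <- function(s, m) {
  stopifnot(is.matrix(m), nrow(m) == nrow(s$atoms), ncol(m) == 3)
  s$atoms$x <- m[, 1]
  s$atoms$y <- m[, 2]
  s$atoms$z <- m[, 3]
  s
}

#' Logical mask of water atoms
#' @param s a `cf_structure`.
#' @return logical vector over atoms (TRUE for water residues, resname `HOH`).
#' @export
is_water <- function(s) s$atoms$resname == "HOH"

#' Logical mask of heavy (non-hydrogen) atoms
#' @param s a `cf_structure`.
#' @return logical vector over atoms.
#' @export
is_heavy <- function(s) s$atoms$element != "H"

#' Create a trajectory
#'
#' A `cf_trajectory` holds one shared atom table and an ordered list of
#' coordinate matrices, one per frame, each with an orthorhombic box.
#'
#' @param atoms atom table as in [new_structure()] (coordinates ignored).
#' @param frames list of n x 3 coordinate matrices, all with the same
#'   atom count as `atoms`.
#' @param box either a length-3 vector (shared by all frames) or an
#'   F x 3 matrix of per-frame boxes; may be `NULL`.
#' @return An object of class `cf_trajectory`.
#' @export
new_trajectory <- function(atoms, frames, box = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1)
  n <- nrow(atoms)
  ok <- vapply(frames, function(m) is.matrix(m) && nrow(m) == n && ncol(m) == 3,
               logical(1))
  if (!all(ok)) stop("all frames must be n x 3 matrices matching the atom table")
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, nrow = length(frames), ncol = 3,
                                         byrow = TRUE)
    stopifnot(nrow(box) == length(frames), ncol(box) == 3, all(box > 0))
  }
  structure(list(atoms = atoms, frames = frames, box = box),
            class = "cf_trajectory")
}

#' @export
print.cf_trajectory <- function(x, ...) {
  cat("<cf_trajectory> ", length(x$frames), " frames x ",
      nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `cf_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Extract one frame of a trajectory as a structure
#'
#' @param traj a `cf_trajectory`.
#' @param i frame index (1-based).
#' @return A `cf_structure` for frame `i`.
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= length(traj$frames))
  a <- traj$atoms
  m <- traj$frames[[i]]
  a$x <- m[, 1]; a$y <- m[, 2]; a$z <- m[, 3]
  box <- if (!is.null(traj$box)) traj$box[i, ] else NULL
  new_structure(a, box = box)
}

# Minimum-image displacement for an orthorhombic box; box NULL -> plain
# difference. `a`, `b` are n x 3 matrices (or vectors recycled).
min_image <- function(a, b, box = NULL) {
  d <- a - b
  if (!is.null(box)) {
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  }
  d
}
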