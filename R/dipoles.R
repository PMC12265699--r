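# 1 e*Angstrom in Debye.
EA_TO_DEBYE <- 4.803

#' Read a plain-text partial-charge table
#'
#' Whitespace-separated columns `resname atom charge`; `#` starts a
#' comment. Charges are in elementary-charge units.
#'
#' @param path file path.
#' @param net_tol per-residue-type net charge must be within `net_tol`
#'   of an integer (default 1e-6).
#' @return data.frame with columns `resname`, `atom`, `charge`.
#' @export
read_charge_table <- function(path, net_tol = 1e-6) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("resname", "atom", "charge"),
                           stringsAsFactors = FALSE)
  for (rn in unique(tab$resname)) {
    q <- sum(tab$charge[tab$resname == rn])
    if (abs(q - round(q)) > net_tol) {
      stop(sprintf("residue %s net charge %.6f is not near-integer", rn, q))
    }
  }
  tab
}

#' Packaged toy charge table (synthetic)
#'
#' Neutral idealized glucosamine residue plus a 3-site water. These are
#' *not* force-field charges; they exist so dipole machinery is testable
#' without external input.
#'
#' @return data.frame as from [read_charge_table()].
#' @export
toy_charge_table <- function() {
  read_charge_table(system.file("extdata", "toy_charges.tsv",
                                package = "chitofib", mustWork = TRUE))
}

#' Attach partial charges to a structure
#'
#' @param s a `cf_structure`.
#' @param charges a charge table (see [read_charge_table()]).
#' @return The structure with a `charge` atom column.
#' @export
assign_charges <- function(s, charges) {
  key <- paste(charges$resname, charges$atom)
  idx <- match(paste(s$atoms$resname, s$atoms$name), key)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("no charge for atom ", s$atoms$name[bad], " of residue ",
         s$atoms$resname[bad])
  }
  s$atoms$charge <- charges$charge[idx]
  s
}

#' Dipole vector of a charged atom set
#'
#' mu = sum(q_i r_i) about the set's centre of geometry. The result is
#' origin-independent iff the set is neutral; by default a non-neutral
#' set is an error.
#'
#' @param s a `cf_structure` with charges (see [assign_charges()]).
#' @param sel optional logical/integer atom selection.
#' @param require_neutral error when |sum q| exceeds `tol` (default TRUE).
#' @param tol neutrality tolerance in elementary charges (default 1e-6).
#' @return numeric length-3 dipole vector in e*Angstrom, with attributes
#'   `magnitude` (e*Angstrom) and `debye` (the same magnitude in Debye,
#'   1 e*Angstrom = 4.803 D).
#' @export
dipole_vector <- function(s, sel = NULL, require_neutral = TRUE, tol = 1e-6) {
  if (is.null(s$atoms$charge)) stop("structure has no charges; see assign_charges()")
  a <- s$atoms
  if (!is.null(sel)) a <- a[sel, , drop = FALSE]
  q <- a$charge
  if (require_neutral && abs(sum(q)) > tol) {
    stop(sprintf("atom set is not neutral (sum q = %.4g e)", sum(q)))
  }
  r <- cbind(a$x, a$y, a$z)
  r0 <- colMeans(r)
  mu <- colSums(q * sweep(r, 2, r0))
  attr(mu, "magnitude") <- sqrt(sum(mu^2))
  attr(mu, "debye") <- sqrt(sum(mu^2)) * EA_TO_DEBYE
  mu
}

# Angle in degrees between two 3-vectors.
vec_angle <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Chain dipole orientation relative to the chain vector
#'
#' The chain vector runs from the centre of mass of sugar unit 2 to that
#' of unit 19 (for a 20-mer; generally units 2 and dp-1). Returns the
#' angle between each chain's dipole and its chain vector.
#'
#' @param frame a `cf_structure` with charges.
#' @param topology a `cf_topology` (chains need >= 19 residues).
#' @param chains chain ids (default: all chitosan chains).
#' @return data.frame with columns `chain`, `mu_x`, `mu_y`, `mu_z`
#'   (e*Angstrom), `magnitude`, `theta` (degrees vs chain vector).
#' @export
chain_dipole_angles <- function(frame, topology, chains = topology$chain_ids) {
  if (topology$dp < 19) stop("chain too short: chain vector needs >= 19 residues")
  a <- frame$atoms
  out <- lapply(chains, function(ch) {
    sel <- a$chain == ch
    mu <- dipole_vector(frame, sel)
    r2 <- sel & a$resid == 2
    r19 <- sel & a$resid == (topology$dp - 1)
    v <- c(mean(a$x[r19]) - mean(a$x[r2]),
           mean(a$y[r19]) - mean(a$y[r2]),
           mean(a$z[r19]) - mean(a$z[r2]))
    data.frame(chain = ch, mu_x = mu[1], mu_y = mu[2], mu_z = mu[3],
               magnitude = attr(mu, "magnitude"),
               theta = vec_angle(mu, v))
  })
  do.call(rbind, out)
}

#' Net dipole of the fibril
#'
#' Vector sum of the per-chain dipoles. For an even number of identical
#' antiparallel sheets the net dipole cancels to zero.
#'
#' @param frame a `cf_structure` with charges.
#' @param topology a `cf_topology`.
#' @return length-3 vector in e*Angstrom with `magnitude` and `debye`
#'   attributes.
#' @export
net_fibril_dipole <- function(frame, topology) {
  mus <- vapply(topology$chain_ids, function(ch) {
    dipole_vector(frame, frame$atoms$chain == ch)
  }, numeric(3))
  mu <- rowSums(mus)
  attr(mu, "magnitude") <- sqrt(sum(mu^2))
  attr(mu, "debye") <- sqrt(sum(mu^2)) * EA_TO_DEBYE
  mu
}

#' Water dipole orientation angles
#'
#' Angle between each water's dipole (along the H-O-H bisector for
#' symmetric H charges) and a reference axis, for a chosen water class.
#' With an applied field the field direction is the natural reference;
#' without one, z is used.
#'
#' @param traj a `cf_trajectory` (or `cf_structure`) with water charges
#'   assignable from `charges`.
#' @param topology a `cf_topology`.
#' @param class `"bulk"`, `"bound"`, `"interior_bound"` (bound and
#'   inside the interior slab) or `"all"`.
#' @param axis reference axis: `"x"`, `"y"`, `"z"` or a length-3 vector.
#' @param charges charge table (default [toy_charge_table()]).
#' @return data.frame with columns `frame`, `water`, `theta` (degrees in
#'   \[0, 180\]).
#' @export
water_dipole_angles <- function(traj, topology, class = "bulk", axis = "z",
                                charges = toy_charge_table()) {
  if (inherits(traj, "cf_structure")) {
    traj <- new_trajectory(traj$atoms, list(coords(traj)), traj$box)
  }
  ax <- if (is.character(axis)) {
    switch(axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1),
           stop("unknown axis: ", axis))
  } else as.numeric(axis)
  qh <- charges$charge[charges$resname == "HOH" & charges$atom %in%
                         c("H1", "H2")]
  if (length(qh) == 2 && abs(qh[1] - qh[2]) > 1e-9) {
    stop("water H charges must be equal for a well-defined dipole")
  }
  out <- lapply(seq_len(n_frames(traj)), function(f) {
    fr <- assign_charges(get_frame(traj, f), charges)
    wa <- assign_waters(fr, topology)
    keep <- switch(class,
                   all = rep(TRUE, nrow(wa)),
                   bulk = wa$class == "bulk",
                   bound = wa$class == "bound",
                   interior_bound = wa$class == "bound" &
                     !is.na(wa$interior) & wa$interior,
                   stop("unknown water class: ", class))
    wid <- wa$water[keep]
    if (length(wid) == 0) return(NULL)
    a <- fr$atoms
    th <- vapply(wid, function(w) {
      sel <- a$resname == "HOH" & a$resid == w
      mu <- dipole_vector(fr, sel)
      vec_angle(mu, ax)
    }, numeric(1))
    data.frame(frame = f, water = wid, theta = th)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) stop("no waters in class '", class, "'")
  out
}

#' Angular density of orientation angles
#'
#' Histogram density of theta with optional sin(theta) correction (the
#' isotropic solid-angle weight), for comparing against a flat
#' field-free expectation.
#'
#' @param theta angles in degrees.
#' @param bin bin width in degrees (default 2).
#' @param sin_correct divide densities by sin(theta) at bin centres.
#' @return data.frame with columns `theta` (bin centre), `density`,
#'   and `density_sin_corrected` when requested.
#' @export
angle_density <- function(theta, bin = 2, sin_correct = TRUE) {
  br <- seq(0, 180, by = bin)
  h <- graphics::hist(theta, breaks = br, plot = FALSE)
  out <- data.frame(theta = h$mids, density = h$density)
  if (sin_correct) {
    w <- sin(h$mids * pi / 180)
    out$density_sin_corrected <- ifelse(w > 0, h$density / w, NA)
  }
  out
}

#' Maximum-likelihood concentration of an axial Boltzmann distribution
#'
#' Fits kappa in the density P(theta) proportional to
#' sin(theta) exp(kappa cos(theta)) by inverting the Langevin function
#' L(kappa) = coth(kappa) - 1/kappa = mean(cos theta). kappa = 0 is the
#' isotropic limit.
#'
#' @param theta angles in degrees.
#' @return list with `kappa` (the MLE, >= 0) and `mean_cos`.
#' @export
fit_axial_concentration <- function(theta) {
  m <- mean(cos(theta * pi / 180))
  if (m <= 0) return(list(kappa = 0, mean_cos = m))
  langevin <- function(k) 1 / tanh(k) - 1 / k
  if (m >= langevin(700)) return(list(kappa = 700, mean_cos = m))
  k <- uniroot(function(k) langevin(k) - m, c(1e-8, 700), tol = 1e-10)$root
  list(kappa = k, mean_cos = m)
}
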