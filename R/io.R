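#' Write a structure or trajectory as (multi-model) PDB
#'
#' Writes standard fixed-width ATOM/HETATM records; waters become HETATM
#' `HOH`. A box is emitted as a CRYST1 record (orthorhombic, 90-degree
#' angles). Trajectories are written as MODEL/ENDMDL blocks.
#'
#' @param x a `cf_structure` or `cf_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (inherits(x, "cf_structure")) {
    atoms_list <- list(coords(x))
    a <- x$atoms
    box <- if (!is.null(x$box)) matrix(x$box, 1) else NULL
    multi <- FALSE
  } else {
    atoms_list <- x$frames
    a <- x$atoms
    box <- x$box
    multi <- TRUE
  }
  if (!is.null(box)) {
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      box[1, 1], box[1, 2], box[1, 3], 90, 90, 90), con)
  }
  het <- a$resname == "HOH"
  rec <- ifelse(het, "HETATM", "ATOM  ")
  # PDB atom-name column convention: pad short names into columns 13-16
  nm <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
  nm <- formatC(nm, width = -4)
  ch <- substr(a$chain, 1, 1)
  serial <- seq_len(nrow(a)) %% 100000L
  resid <- a$resid %% 10000L
  for (f in seq_along(atoms_list)) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    m <- atoms_list[[f]]
    lines <- sprintf(
      "%s%5d %s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, serial, nm, a$resname, ch, resid,
      m[, 1], m[, 2], m[, 3], 1, 0, a$element)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM records (fixed columns) and the CRYST1 box.
#' Multi-model files return a `cf_trajectory`; single-model files a
#' `cf_structure`.
#'
#' @param path PDB file.
#' @return A `cf_structure` or `cf_trajectory`.
#' @export
read_pdb <- function(path) {
  ln <- readLines(path)
  if (length(ln) == 0) stop("empty PDB file: ", path)
  is_atom <- grepl("^(ATOM  |HETATM)", ln)
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  box <- NULL
  cr <- grep("^CRYST1", ln, value = TRUE)
  if (length(cr) > 0) {
    box <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                        substr(cr[1], 25, 33)))
    if (anyNA(box) || any(box <= 0)) box <- NULL
  }
  model_starts <- grep("^MODEL", ln)
  parse_block <- function(rows) {
    s <- ln[rows]
    x <- suppressWarnings(as.numeric(substr(s, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(s, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(s, 47, 54)))
    bad <- which(is.na(x) | is.na(y) | is.na(z))
    if (length(bad) > 0) {
      stop("malformed coordinate field at line ", rows[bad[1]], " of ", path)
    }
    data.frame(
      name = trimws(substr(s, 13, 16)),
      resname = trimws(substr(s, 18, 20)),
      chain = trimws(substr(s, 22, 22)),
      resid = as.integer(substr(s, 23, 26)),
      x = x, y = y, z = z, stringsAsFactors = FALSE)
  }
  if (length(model_starts) <= 1) {
    at <- parse_block(which(is_atom))
    return(new_structure(at, box = box))
  }
  ends <- grep("^ENDMDL", ln)
  if (length(ends) != length(model_starts)) stop("unbalanced MODEL/ENDMDL in ", path)
  blocks <- lapply(seq_along(model_starts), function(i) {
    rows <- intersect(which(is_atom),
                      seq(model_starts[i] + 1L, ends[i] - 1L))
    parse_block(rows)
  })
  n <- vapply(blocks, nrow, integer(1))
  if (length(unique(n)) != 1) stop("models differ in atom count in ", path)
  atoms <- blocks[[1]]
  frames <- lapply(blocks, function(b) cbind(b$x, b$y, b$z))
  new_trajectory(atoms, frames,
                 box = if (!is.null(box)) box else NULL)
}

#' Read atoms from an mmCIF file
#'
#' Minimal `_atom_site` loop reader: atom name, residue name, chain
#' (auth or label asym id), residue number and Cartesian coordinates.
#'
#' @param path mmCIF file.
#' @return A `cf_structure`.
#' @export
read_mmcif <- function(path) {
  ln <- readLines(path)
  hdr <- grep("^_atom_site\\.", ln)
  if (length(hdr) == 0) stop("no _atom_site loop in ", path)
  fields <- sub("^_atom_site\\.", "", trimws(ln[hdr]))
  body_start <- max(hdr) + 1L
  body <- character(0)
  for (i in body_start:length(ln)) {
    s <- trimws(ln[i])
    if (s == "" || startsWith(s, "#") || startsWith(s, "loop_") ||
        startsWith(s, "_")) break
    body <- c(body, s)
  }
  if (length(body) == 0) stop("empty _atom_site loop in ", path)
  tok <- strsplit(body, "\\s+")
  nf <- length(fields)
  bad <- which(vapply(tok, length, integer(1)) != nf)
  if (length(bad) > 0) {
    stop("malformed _atom_site row at line ", body_start + bad[1] - 1L,
         " of ", path)
  }
  m <- do.call(rbind, tok)
  colnames(m) <- fields
  get <- function(opts) {
    for (o in opts) if (o %in% fields) return(m[, o])
    stop("mmCIF lacks required field: ", paste(opts, collapse = "/"))
  }
  atoms <- data.frame(
    name = gsub('"', "", get(c("auth_atom_id", "label_atom_id"))),
    resname = get(c("auth_comp_id", "label_comp_id")),
    chain = get(c("auth_asym_id", "label_asym_id")),
    resid = as.integer(get(c("auth_seq_id", "label_seq_id"))),
    x = as.numeric(get("Cartn_x")),
    y = as.numeric(get("Cartn_y")),
    z = as.numeric(get("Cartn_z")),
    stringsAsFactors = FALSE)
  new_structure(atoms)
}

#' Write a trajectory in DCD format
#'
#' CHARMM/NAMD-style binary DCD with a unit-cell block per frame
#' (orthorhombic; angles written as 90 degrees) and single-precision
#' coordinates.
#'
#' @param traj a `cf_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dcd <- function(traj, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  natom <- nrow(traj$atoms)
  nf <- length(traj$frames)
  has_box <- !is.null(traj$box)
  wrec <- function(writer) {
    tmp <- raw(0)
    tcon <- rawConnection(tmp, open = "wb")
    writer(tcon)
    payload <- rawConnectionValue(tcon)
    close(tcon)
    writeBin(length(payload), con, size = 4L)
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4L)
  }
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  icntrl[11] <- if (has_box) 1L else 0L
  icntrl[20] <- 24L   # CHARMM version stamp
  wrec(function(c2) {
    writeChar("CORD", c2, nchars = 4, eos = NULL)
    writeBin(icntrl, c2, size = 4L)
  })
  wrec(function(c2) {
    writeBin(1L, c2, size = 4L)
    writeChar(formatC("generated by chitofib", width = -80), c2,
              nchars = 80, eos = NULL)
  })
  wrec(function(c2) writeBin(natom, c2, size = 4L))
  for (f in seq_len(nf)) {
    if (has_box) {
      b <- traj$box[f, ]
      wrec(function(c2) writeBin(as.double(c(b[1], 90, b[2], 90, 90, b[3])),
                                 c2, size = 8L))
    }
    m <- traj$frames[[f]]
    for (k in 1:3) {
      wrec(function(c2) writeBin(as.double(m[, k]), c2, size = 4L))
    }
  }
  invisible(path)
}

#' Read a DCD trajectory
#'
#' Reads CHARMM/NAMD-style DCD. With a `callback`, frames are streamed
#' one at a time (constant memory) and the function returns the frame
#' count; otherwise a `cf_trajectory` is assembled.
#'
#' @param atoms atom table matching the file (e.g. from [read_pdb()] of
#'   the companion structure); atom counts must agree.
#' @param path DCD file.
#' @param callback optional `function(frame_matrix, box, frame_index)`
#'   called per frame.
#' @return A `cf_trajectory`, or (with `callback`) the frame count.
#' @export
read_dcd <- function(atoms, path, callback = NULL) {
  if (inherits(atoms, "cf_structure")) atoms <- atoms$atoms
  con <- file(path, open = "rb")
  on.exit(close(con))
  rrec <- function() {
    n <- readBin(con, integer(), n = 1, size = 4)
    if (length(n) == 0) return(NULL)
    payload <- readBin(con, raw(), n = n)
    n2 <- readBin(con, integer(), n = 1, size = 4)
    if (length(n2) == 0 || n2 != n) stop("corrupt DCD record in ", path)
    payload
  }
  hdr <- rrec()
  if (is.null(hdr) || length(hdr) < 84 ||
      rawToChar(hdr[1:4]) != "CORD") stop("not a DCD file: ", path)
  icntrl <- readBin(hdr[5:84], integer(), n = 20, size = 4)
  nf <- icntrl[1]
  has_box <- icntrl[11] == 1L
  rrec() # title
  natom_rec <- rrec()
  natom <- readBin(natom_rec, integer(), n = 1, size = 4)
  if (natom != nrow(atoms)) {
    stop("DCD atom count ", natom, " does not match atom table ", nrow(atoms))
  }
  frames <- if (is.null(callback)) vector("list", nf) else NULL
  boxes <- if (has_box) matrix(NA_real_, nf, 3) else NULL
  for (f in seq_len(nf)) {
    b <- NULL
    if (has_box) {
      cell <- readBin(rrec(), double(), n = 6, size = 8)
      b <- cell[c(1, 3, 6)]
      boxes[f, ] <- b
    }
    m <- matrix(0, natom, 3)
    for (k in 1:3) {
      v <- readBin(rrec(), double(), n = natom, size = 4)
      if (length(v) != natom) stop("truncated DCD frame ", f, " in ", path)
      m[, k] <- v
    }
    if (is.null(callback)) frames[[f]] <- m else callback(m, b, f)
  }
  if (!is.null(callback)) return(nf)
  new_trajectory(atoms, frames, box = boxes)
}

#' Write the fibril topology sidecar as JSON
#'
#' Schema: `{chain_id: {sheet, direction, residues}}` plus a `_meta`
#' entry with the sheet/chain counts.
#'
#' @param topology a `cf_topology`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_topology_json <- function(topology, path) {
  obj <- setNames(lapply(topology$chain_ids, function(ch) {
    list(sheet = unname(topology$chain_to_sheet[ch]),
         direction = unname(topology$chain_direction[ch]),
         position = unname(topology$chain_pos[ch]),
         residues = topology$dp)
  }), topology$chain_ids)
  obj[["_meta"]] <- list(n_sheets = topology$n_sheets,
                         chains_per_sheet = topology$chains_per_sheet,
                         dp = topology$dp)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a fibril topology sidecar
#'
#' @param path JSON file written by [write_topology_json()].
#' @return A `cf_topology`.
#' @export
read_topology_json <- function(path) {
  obj <- jsonlite::read_json(path)
  meta <- obj[["_meta"]]
  obj[["_meta"]] <- NULL
  ids <- names(obj)
  new_topology(
    ids,
    sheet = vapply(obj, function(o) as.integer(o$sheet), integer(1)),
    direction = vapply(obj, function(o) as.integer(o$direction), integer(1)),
    pos = vapply(obj, function(o) as.integer(o$position), integer(1)),
    spec = fibril_spec(n_sheets = meta$n_sheets,
                       chains_per_sheet = meta$chains_per_sheet,
                       dp = meta$dp,
                       sugars_per_c_repeat = 1))
}
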