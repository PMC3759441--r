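# Structure and ensemble I/O: multi-model PDB in, one in-memory
# representation out.  Frames are data.frame-backed so every downstream
# module (scoring, PCA, pocket analysis) consumes the same columns.

#' Standard amino-acid residue names
#'
#' Three-letter codes treated as protein residues when selecting main-chain
#' or C-alpha atoms.
#' @keywords internal
STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE", "HID", "HIE", "HIP", "CYX", "ASH", "GLH", "LYN"
)

atom_columns <- c(
  "serial", "name", "altloc", "resname", "chain", "resno",
  "x", "y", "z", "occupancy", "bfactor", "element", "record",
  "role", "atom_type"
)

#' Construct a frame
#'
#' A frame is one snapshot of a structure: an ordered table of atoms plus a
#' frame index and a simulation time in picoseconds.
#'
#' @param atoms data.frame with (at least) columns `serial`, `name`,
#'   `element`, `resname`, `resno`, `chain`, `x`, `y`, `z`.  Missing
#'   bookkeeping columns (`altloc`, `occupancy`, `bfactor`, `record`,
#'   `role`, `atom_type`) are filled with defaults.
#' @param index integer frame index, 0-based.
#' @param time_ps simulation time of the snapshot, picoseconds.
#' @return an object of class `rmr_frame`.
#' @export
new_frame <- function(atoms, index = 0L, time_ps = 0) {
  stopifnot(is.data.frame(atoms))
  need <- c("serial", "name", "element", "resname", "resno", "chain",
            "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0L) {
    stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (!("altloc" %in% names(atoms))) atoms$altloc <- ""
  if (!("occupancy" %in% names(atoms))) atoms$occupancy <- 1
  if (!("bfactor" %in% names(atoms))) atoms$bfactor <- 0
  if (!("record" %in% names(atoms))) {
    atoms$record <- ifelse(atoms$resname %in% STANDARD_AA, "ATOM", "HETATM")
  }
  if (!("role" %in% names(atoms))) atoms$role <- "receptor"
  if (!("atom_type" %in% names(atoms))) atoms$atom_type <- ""
  atoms <- atoms[, atom_columns]
  fr <- structure(
    list(index = as.integer(index), time_ps = as.numeric(time_ps),
         atoms = atoms),
    class = "rmr_frame"
  )
  validate_frame(fr)
  fr
}

validate_frame <- function(frame) {
  a <- frame$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("frame has non-finite coordinates")
  if (anyDuplicated(a$serial)) stop("duplicate atom serials within a frame")
  if (any(a$serial < 1L)) stop("atom serials must be >= 1")
  invisible(frame)
}

#' @export
print.rmr_frame <- function(x, ...) {
  cat(sprintf("<rmr_frame> index %d, t = %g ps, %d atoms (%d residues)\n",
              x$index, x$time_ps, nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain", "resno")]))))
  invisible(x)
}

#' Coordinates of a frame as an n x 3 matrix
#' @param frame an `rmr_frame`.
#' @return numeric matrix with columns x, y, z.
#' @export
frame_coords <- function(frame) {
  m <- as.matrix(frame$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Replace the coordinates of a frame
#' @param frame an `rmr_frame`.
#' @param xyz n x 3 numeric matrix.
#' @return the modified frame.
#' @export
set_frame_coords <- function(frame, xyz) {
  stopifnot(nrow(xyz) == nrow(frame$atoms), ncol(xyz) == 3)
  frame$atoms$x <- xyz[, 1]
  frame$atoms$y <- xyz[, 2]
  frame$atoms$z <- xyz[, 3]
  frame
}

# Topology identity: everything that defines atom ordering and labelling,
# deliberately excluding coordinates so rigid motion or drift cannot change
# the hash.
topology_hash_of <- function(atoms) {
  # hash a flat string: immune to ALTREP/serialization representation
  # differences between freshly built and file-parsed vectors
  rlang::hash(paste(atoms$serial, atoms$name, atoms$resname,
                    atoms$resno, atoms$chain, sep = "|", collapse = "\n"))
}

#' Construct an ensemble from a list of frames
#'
#' All frames must share the same topology (atom count, ordering, names,
#' residue numbering); times must be strictly increasing.
#'
#' @param frames list of `rmr_frame` objects.
#' @return an object of class `rmr_ensemble` with fields `frames` and
#'   `topology_hash`.
#' @export
new_ensemble <- function(frames) {
  if (length(frames) < 1L) stop("an ensemble needs at least one frame")
  hashes <- vapply(frames, function(f) topology_hash_of(f$atoms), "")
  if (length(unique(hashes)) != 1L) {
    stop("topology error: frames do not share one atom topology")
  }
  times <- vapply(frames, function(f) f$time_ps, 0)
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  structure(list(frames = frames, topology_hash = hashes[[1L]]),
            class = "rmr_ensemble")
}

#' @export
print.rmr_ensemble <- function(x, ...) {
  tt <- ensemble_times(x)
  cat(sprintf("<rmr_ensemble> %d frames, %d atoms, t = [%g, %g] ps\n",
              length(x$frames), nrow(x$frames[[1L]]$atoms),
              min(tt), max(tt)))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble an `rmr_ensemble`.
#' @export
n_frames <- function(ensemble) length(ensemble$frames)

#' Frame times of an ensemble (ps)
#' @param ensemble an `rmr_ensemble`.
#' @export
ensemble_times <- function(ensemble) {
  vapply(ensemble$frames, function(f) f$time_ps, 0)
}

parse_pdb_atom_lines <- function(lines, lineno) {
  n <- length(lines)
  short <- nchar(lines) < 54L
  if (any(short)) {
    stop(sprintf("parse error at line %d: ATOM/HETATM record shorter than 54 columns",
                 lineno[which(short)[1L]]))
  }
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(lines, from, to)))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L) {
      stop(sprintf("parse error at line %d: cannot parse %s field",
                   lineno[bad[1L]], what))
    }
    v
  }
  element <- trimws(substr(lines, 77, 78))
  name <- trimws(substr(lines, 13, 16))
  # fall back to the atom-name element columns when 77-78 is absent
  guess <- trimws(substr(lines, 13, 14))
  guess <- toupper(gsub("[0-9' ]", "", guess))
  two_letter <- c("FE", "CL", "BR", "ZN", "MG", "MN", "CU", "NA", "SE", "NI")
  guess <- ifelse(guess %in% two_letter, guess, substr(gsub("^[0-9]*", "", name), 1, 1))
  element <- ifelse(element == "", guess, element)
  data.frame(
    serial = as.integer(num(7, 11, "serial")),
    name = name,
    altloc = trimws(substr(lines, 17, 17)),
    resname = trimws(substr(lines, 18, 21)),
    chain = trimws(substr(lines, 22, 22)),
    resno = as.integer(num(23, 26, "residue number")),
    x = num(31, 38, "x"),
    y = num(39, 46, "y"),
    z = num(47, 54, "z"),
    occupancy = {
      o <- suppressWarnings(as.numeric(substr(lines, 55, 60)))
      ifelse(is.finite(o), o, 1)
    },
    bfactor = {
      b <- suppressWarnings(as.numeric(substr(lines, 61, 66)))
      ifelse(is.finite(b), b, 0)
    },
    element = element,
    record = trimws(substr(lines, 1, 6)),
    stringsAsFactors = FALSE
  )
}

#' Read a (multi-model) PDB file into an ensemble
#'
#' MODEL/ENDMDL blocks become frames in file order; a file with no MODEL
#' records yields a one-frame ensemble.  HETATM records are kept.  Alternate
#' locations other than blank or "A" are dropped.  Frame times are taken
#' from `REMARK 250 TIME_PS` records written by [write_ensemble()]; files
#' without them get `index * dt_ps`.
#'
#' @param path PDB file path.
#' @param format `"pdb"` or `"multi_model_pdb"` (both accepted by the same
#'   parser; the distinction only documents intent).
#' @param ligand,cofactor residue names used to assign roles (see
#'   [assign_roles()]); `NULL` leaves every atom a receptor atom.
#' @param dt_ps frame spacing assumed when the file carries no time records.
#' @return an `rmr_ensemble`.
#' @export
read_ensemble <- function(path, format = c("multi_model_pdb", "pdb"),
                          ligand = NULL, cofactor = NULL, dt_ps = 10) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") | trimws(rec) %in% c("ATOM", "HETATM")
  is_model <- trimws(rec) == "MODEL"
  model_of <- cumsum(is_model)
  atom_idx <- which(is_atom)
  if (length(atom_idx) == 0L) stop("parse error: no ATOM/HETATM records in ", path)
  atoms_all <- parse_pdb_atom_lines(lines[atom_idx], atom_idx)
  atoms_all$model <- model_of[atom_idx]
  keep <- atoms_all$altloc %in% c("", "A")
  atoms_all <- atoms_all[keep, , drop = FALSE]

  # per-model times from REMARK records, matched to models in file order
  tm_idx <- grep("^REMARK.*TIME_PS", lines)
  times <- NULL
  if (length(tm_idx) > 0L) {
    times <- suppressWarnings(
      as.numeric(sub(".*TIME_PS[ =]*", "", lines[tm_idx]))
    )
    if (any(!is.finite(times))) times <- NULL
  }

  models <- unique(atoms_all$model)
  frames <- vector("list", length(models))
  for (i in seq_along(models)) {
    a <- atoms_all[atoms_all$model == models[[i]], , drop = FALSE]
    a$model <- NULL
    rownames(a) <- NULL
    t_i <- if (!is.null(times) && length(times) >= i) times[[i]] else (i - 1) * dt_ps
    frames[[i]] <- new_frame(a, index = i - 1L, time_ps = t_i)
  }
  counts <- vapply(frames, function(f) nrow(f$atoms), 0L)
  if (length(unique(counts)) != 1L) {
    stop(sprintf("topology error: models have inconsistent atom counts (%s)",
                 paste(unique(counts), collapse = ", ")))
  }
  ens <- new_ensemble(frames)
  if (!is.null(ligand) || !is.null(cofactor)) {
    ens <- assign_roles(ens, ligand = ligand, cofactor = cofactor)
  }
  ens
}

format_pdb_atom_line <- function(a) {
  name <- ifelse(nchar(a$name) >= 4L, a$name, sprintf(" %-3s", a$name))
  sprintf("%-6s%5d %-4s%1s%-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a$record, a$serial, name,
          ifelse(a$altloc == "", " ", a$altloc),
          a$resname, ifelse(a$chain == "", " ", a$chain), a$resno,
          a$x, a$y, a$z, a$occupancy, a$bfactor, a$element)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Coordinates are written with the fixed-width PDB `%8.3f` convention, so a
#' round trip preserves them to 1e-3 Angstrom.  Frame times are stored as
#' `REMARK 250 TIME_PS` records so [read_ensemble()] can recover them.
#'
#' @param ensemble an `rmr_ensemble`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  if (!inherits(ensemble, "rmr_ensemble")) stop("not an rmr_ensemble")
  if (length(ensemble$frames) < 1L) stop("empty ensemble")
  out <- character(0)
  for (i in seq_along(ensemble$frames)) {
    fr <- ensemble$frames[[i]]
    out <- c(out,
             sprintf("MODEL     %4d", i),
             sprintf("REMARK 250 TIME_PS %.6f", fr$time_ps),
             format_pdb_atom_line(fr$atoms),
             "ENDMDL")
  }
  out <- c(out, "END")
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("I/O error: cannot open ", path))
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Assign receptor / ligand / cofactor roles by residue name
#'
#' Role identities are fixed per system: the ligand and the cofactor (e.g.
#' the heme) are named residues and everything else is receptor.
#'
#' @param x an `rmr_frame` or `rmr_ensemble`.
#' @param ligand residue name(s) of the ligand, or `NULL`.
#' @param cofactor residue name(s) of the cofactor, or `NULL`.
#' @return the object with the `role` column populated.
#' @export
assign_roles <- function(x, ligand = NULL, cofactor = NULL) {
  if (inherits(x, "rmr_ensemble")) {
    x$frames <- lapply(x$frames, assign_roles, ligand = ligand,
                       cofactor = cofactor)
    return(x)
  }
  stopifnot(inherits(x, "rmr_frame"))
  role <- rep("receptor", nrow(x$atoms))
  if (!is.null(ligand)) role[x$atoms$resname %in% ligand] <- "ligand"
  if (!is.null(cofactor)) role[x$atoms$resname %in% cofactor] <- "cofactor"
  x$atoms$role <- role
  x
}

# heavy-atom neighbour lists under a covalent-distance heuristic
covalent_neighbours <- function(atoms, cutoff = 1.8) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  heavy <- which(toupper(atoms$element) != "H")
  nb <- vector("list", nrow(atoms))
  if (length(heavy) >= 2L) {
    hxyz <- xyz[heavy, , drop = FALSE]
    d2 <- outer(rowSums(hxyz^2), rowSums(hxyz^2), "+") - 2 * tcrossprod(hxyz)
    d2[d2 < 0] <- 0
    adj <- d2 <= cutoff^2
    diag(adj) <- FALSE
    for (k in seq_along(heavy)) nb[[heavy[[k]]]] <- heavy[adj[k, ]]
  }
  nb
}

#' Assign scoring atom types
#'
#' `scheme = "element"` copies the element symbol into `atom_type`.
#' `scheme = "element_context"` appends a chemical-context flag derived from
#' covalent-distance neighbour heuristics (no bond-order perception):
#' carbonyl O/C, amide N, aromatic-like C (three heavy neighbours), sp3
#' otherwise.  The typing granularity actually used with a
#' database-trained potential is a configuration choice; both schemes feed
#' the same scoring machinery.
#'
#' @param frame an `rmr_frame` with elements populated.
#' @param scheme `"element"` or `"element_context"`.
#' @return the frame with `atom_type` filled for every atom.
#' @export
assign_atom_types <- function(frame, scheme = c("element", "element_context")) {
  scheme <- match.arg(scheme)
  a <- frame$atoms
  el <- toupper(a$element)
  bad <- which(el == "" | is.na(el))
  if (length(bad) > 0L) {
    stop("typing error: atoms without an element symbol: serial ",
         paste(a$serial[bad], collapse = ", "))
  }
  if (scheme == "element") {
    frame$atoms$atom_type <- el
    return(frame)
  }
  nb <- covalent_neighbours(a)
  is_carbonyl_c <- function(i) {
    if (el[[i]] != "C") return(FALSE)
    nbs <- nb[[i]]
    has_o <- any(el[nbs] == "O")
    has_o && sum(el[nbs] %in% c("O", "N")) >= 2L
  }
  carbonyl_c <- vapply(seq_len(nrow(a)), is_carbonyl_c, TRUE)
  typ <- character(nrow(a))
  for (i in seq_len(nrow(a))) {
    nbs <- nb[[i]]
    typ[[i]] <- switch(
      el[[i]],
      "C" = if (carbonyl_c[[i]]) "C.carbonyl"
            else if (length(nbs) >= 3L) "C.aromatic" else "C.sp3",
      "O" = if (any(carbonyl_c[nbs])) "O.carbonyl" else "O.sp3",
      "N" = if (any(carbonyl_c[nbs])) "N.amide" else "N.sp3",
      el[[i]]
    )
  }
  frame$atoms$atom_type <- typ
  frame
}

#' Select atom indices of a frame
#'
#' @param frame an `rmr_frame`.
#' @param spec `"mainchain_CON"` (atoms literally named C, O or N in
#'   protein residues — note C-alpha is excluded), `"calpha"` (atoms named
#'   CA in protein residues) or `"custom"` with explicit `indices`.
#' @param indices integer row indices, used when `spec = "custom"`.
#' @return integer vector of atom row indices.
#' @export
select_atoms <- function(frame, spec = c("mainchain_CON", "calpha", "custom"),
                         indices = NULL) {
  spec <- match.arg(spec)
  a <- frame$atoms
  idx <- switch(
    spec,
    mainchain_CON = which(a$name %in% c("C", "O", "N") &
                            a$resname %in% STANDARD_AA),
    calpha = which(a$name == "CA" & a$resname %in% STANDARD_AA),
    custom = as.integer(indices)
  )
  if (length(idx) == 0L) stop("selection error: no atoms match '", spec, "'")
  idx
}
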