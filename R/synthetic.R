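# Seeded generators for every input the pipeline needs: contact databases
# with known truncated-normal distance laws, labelled pose ensembles whose
# ligand-pocket contact distances follow a favorable or decoy law, and
# trajectories with planted low-dimensional collective modes.  Nothing here
# pretends to be physics — only the statistical structure the scoring and
# PCA stages assume.

#' Derive a stream seed from a global seed
#'
#' Deterministic splitting of one global seed into independent per-stream
#' seeds, keyed by a stream label, so adding a new generator never perturbs
#' existing streams.  Multiplicative-congruential mixing mod 2^31 - 1.
#'
#' @param seed global integer seed.
#' @param stream character stream label.
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, stream) {
  M <- 2147483647
  h <- 0
  for (ch in utf8ToInt(as.character(stream))) h <- (h * 131 + ch) %% M
  s <- (abs(as.numeric(seed)) %% M)
  s <- (s * 48271) %% M
  s <- (s + h + 1) %% M
  s <- (s * 48271) %% M
  as.integer(if (s == 0) 1 else s)
}

# truncated-normal draws on (lo, hi] via inverse-CDF
rtrunc_normal <- function(n, mean, sd, lo = 0, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  if (phi - plo < 1e-12) {
    stop("spec error: truncation removes essentially all mass of the law")
  }
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Specification of a synthetic contact database
#'
#' @param pairs data.frame with columns `type_a`, `type_b`, `mean`, `sd`,
#'   `count`: one truncated-normal distance law per unordered type pair.
#' @param d_max_gen upper truncation of the generated distances, Angstrom.
#' @param seed integer seed.
#' @return validated list of class `rmr_contact_db_spec`.
#' @export
contact_db_spec <- function(pairs, d_max_gen = 8, seed = 1L) {
  need <- c("type_a", "type_b", "mean", "sd", "count")
  if (!all(need %in% names(pairs))) {
    stop("spec error: pairs needs columns ", paste(need, collapse = ", "))
  }
  if (any(pairs$sd <= 0)) stop("spec error: law sd must be positive")
  if (any(pairs$count < 1)) stop("spec error: counts must be >= 1")
  structure(list(pairs = pairs, d_max_gen = d_max_gen,
                 seed = as.integer(seed)),
            class = "rmr_contact_db_spec")
}

#' Generate a synthetic contact database
#'
#' Seeded, reproducible draws: each type pair gets its own derived stream
#' seed, distances come from that pair's truncated normal on
#' `(0, d_max_gen]`.  The spec is attached as the `spec` attribute.
#'
#' @param spec an `rmr_contact_db_spec`.
#' @return data.frame with `type_a`, `type_b`, `distance`.
#' @export
generate_contact_db <- function(spec) {
  stopifnot(inherits(spec, "rmr_contact_db_spec"))
  p <- spec$pairs
  chunks <- lapply(seq_len(nrow(p)), function(i) {
    key <- pair_key(as.character(p$type_a[[i]]), as.character(p$type_b[[i]]))
    set.seed(split_seed(spec$seed, paste0("contacts/", key)))
    data.frame(type_a = p$type_a[[i]], type_b = p$type_b[[i]],
               distance = rtrunc_normal(p$count[[i]], p$mean[[i]],
                                        p$sd[[i]], 0, spec$d_max_gen),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, chunks)
  rownames(out) <- NULL
  attr(out, "spec") <- spec
  out
}

#' Specification of a labelled pose ensemble
#'
#' Describes an ensemble in which a known fraction of frames is
#' "near-native": their ligand-pocket contact distances are drawn from the
#' favorable law, the rest from the decoy law, and the reactive pair sits
#' at a baseline distance plus per-frame jitter, with near-native frames
#' shifted nearer the probe.
#'
#' @param n_frames number of frames.
#' @param near_native_fraction fraction of frames labelled near-native.
#' @param n_contacts ligand-pocket contact pairs per frame (one pocket
#'   residue per contact).
#' @param favorable,decoy length-2 numeric `c(mean, sd)` distance laws,
#'   Angstrom.
#' @param reactive_baseline baseline probe-target distance, Angstrom.
#' @param reactive_jitter_sd per-frame jitter sd, Angstrom.
#' @param reactive_near_shift additive shift of the near-native reactive
#'   distance (negative = nearer the probe).
#' @param ligand_element,pocket_element elements (= scoring types under the
#'   element scheme) of the ligand and pocket contact atoms.
#' @param ligand_resname,cofactor_resname residue names written to the PDB.
#' @param d_max_gen upper truncation of contact laws.
#' @param seed integer seed.
#' @return validated list of class `rmr_pose_ensemble_spec`.
#' @export
pose_ensemble_spec <- function(n_frames = 400, near_native_fraction = 0.1,
                               n_contacts = 8,
                               favorable = c(3.0, 0.25),
                               decoy = c(4.5, 1.2),
                               reactive_baseline = 3.6,
                               reactive_jitter_sd = 0.05,
                               reactive_near_shift = -0.4,
                               ligand_element = "C", pocket_element = "O",
                               ligand_resname = "LIG",
                               cofactor_resname = "HEM",
                               d_max_gen = 8, seed = 1L) {
  stopifnot(n_frames >= 1, near_native_fraction >= 0,
            near_native_fraction <= 1, n_contacts >= 1,
            favorable[[2L]] > 0, decoy[[2L]] > 0, reactive_jitter_sd >= 0)
  if (abs(favorable[[1L]] - decoy[[1L]]) < 1e-9 &&
      abs(favorable[[2L]] - decoy[[2L]]) < 1e-9) {
    stop("spec error: favorable and decoy laws must be distinguishable")
  }
  structure(list(n_frames = as.integer(n_frames),
                 near_native_fraction = near_native_fraction,
                 n_contacts = as.integer(n_contacts),
                 favorable = favorable, decoy = decoy,
                 reactive_baseline = reactive_baseline,
                 reactive_jitter_sd = reactive_jitter_sd,
                 reactive_near_shift = reactive_near_shift,
                 ligand_element = ligand_element,
                 pocket_element = pocket_element,
                 ligand_resname = ligand_resname,
                 cofactor_resname = cofactor_resname,
                 d_max_gen = d_max_gen, seed = as.integer(seed)),
            class = "rmr_pose_ensemble_spec")
}

# Geometric layout: pocket residue i sits at (spacing*i, 0, 0) with one
# contact atom; ligand atom i sits directly above it at the drawn contact
# distance.  Residues are spaced far beyond the scoring range, so the only
# in-range pairs are the planted ones and the contact distances realised in
# the frame ARE the drawn law.  The cofactor (probe) and the reactive
# target atom live on their own far-away site.
POSE_SPACING <- 25

#' Generate a labelled pose ensemble
#'
#' @param spec an `rmr_pose_ensemble_spec`.
#' @return list with `ensemble` (typed, roles assigned) and `labels`
#'   (data.frame `frame_index`, `label` in \{"near_native", "decoy"\});
#'   labels are evaluation-only and are never written into the PDB.
#' @export
generate_pose_ensemble <- function(spec) {
  stopifnot(inherits(spec, "rmr_pose_ensemble_spec"))
  n <- spec$n_frames
  nc <- spec$n_contacts
  n_near <- round(spec$near_native_fraction * n)
  set.seed(split_seed(spec$seed, "poses/labels"))
  near_idx <- if (n_near > 0) sort(sample.int(n, n_near)) else integer(0)
  is_near <- seq_len(n) %in% near_idx

  probe_site <- c(-2 * POSE_SPACING, 0, 0)
  set.seed(split_seed(spec$seed, "poses/contacts"))
  frames <- vector("list", n)
  for (t in seq_len(n)) {
    law <- if (is_near[[t]]) spec$favorable else spec$decoy
    d <- rtrunc_normal(nc, law[[1L]], law[[2L]], 0.8, spec$d_max_gen)
    r <- spec$reactive_baseline +
      (if (is_near[[t]]) spec$reactive_near_shift else 0) +
      stats::rnorm(1L, 0, spec$reactive_jitter_sd)
    r <- max(r, 0.8)
    pocket <- data.frame(
      serial = seq_len(nc),
      name = paste0(spec$pocket_element, "X"),
      element = spec$pocket_element,
      resname = "POC", resno = seq_len(nc), chain = "A",
      x = POSE_SPACING * seq_len(nc), y = 0, z = 0,
      role = "receptor", stringsAsFactors = FALSE)
    lig <- data.frame(
      serial = nc + seq_len(nc + 1L),
      name = c(paste0("L", seq_len(nc)), "C7"),
      element = spec$ligand_element,
      resname = spec$ligand_resname, resno = 900L, chain = "L",
      x = c(POSE_SPACING * seq_len(nc), probe_site[[1L]]),
      y = 0,
      z = c(d, probe_site[[3L]] + r),
      role = "ligand", stringsAsFactors = FALSE)
    cof <- data.frame(
      serial = 2L * nc + 2L:3L,
      name = c("FE", "O1"),
      element = c("FE", "O"),
      resname = spec$cofactor_resname, resno = 950L, chain = "X",
      x = probe_site[[1L]], y = 0, z = c(-1.6, 0),
      role = "cofactor", stringsAsFactors = FALSE)
    atoms <- rbind(pocket, lig, cof)
    atoms$serial <- seq_len(nrow(atoms))
    fr <- new_frame(atoms, index = t - 1L, time_ps = 10 * t)
    frames[[t]] <- assign_atom_types(fr, "element")
  }
  labels <- data.frame(frame_index = 0:(n - 1L),
                       label = ifelse(is_near, "near_native", "decoy"),
                       stringsAsFactors = FALSE)
  ens <- new_ensemble(frames)
  attr(ens, "spec") <- spec
  list(ensemble = ens,
       labels = labels,
       reactive_pair = c(probe_serial = frames[[1L]]$atoms$serial[
                           frames[[1L]]$atoms$name == "O1"],
                         target_serial = frames[[1L]]$atoms$serial[
                           frames[[1L]]$atoms$name == "C7"]))
}

#' Specification of a trajectory with planted collective modes
#'
#' @param n_atoms number of C-alpha atoms.
#' @param n_frames number of frames.
#' @param amplitudes strictly decreasing positive sds (one per planted
#'   mode, at most 3).
#' @param noise_sd isotropic per-coordinate noise sd, Angstrom.
#' @param rigid_motion apply a random rigid rotation + translation to every
#'   frame (superposition must then remove it).
#' @param modes optional 3N x k orthonormal matrix of planted modes; `NULL`
#'   generates random modes orthogonal to the rigid-body subspace.
#' @param seed integer seed.
#' @return validated list of class `rmr_modal_trajectory_spec`.
#' @export
modal_trajectory_spec <- function(n_atoms = 20, n_frames = 200,
                                  amplitudes = c(1.0, 0.6, 0.3),
                                  noise_sd = 0.03, rigid_motion = FALSE,
                                  modes = NULL, seed = 1L) {
  stopifnot(n_atoms >= 4, n_frames >= 2, length(amplitudes) <= 3,
            all(amplitudes > 0), noise_sd >= 0)
  if (length(amplitudes) > 1L && any(diff(amplitudes) >= 0)) {
    stop("spec error: amplitudes must be strictly decreasing")
  }
  if (!is.null(modes)) {
    modes <- as.matrix(modes)
    if (nrow(modes) != 3L * n_atoms || ncol(modes) != length(amplitudes)) {
      stop("spec error: modes must be 3*n_atoms x length(amplitudes)")
    }
    G <- crossprod(modes)
    if (max(abs(G - diag(ncol(modes)))) > 1e-8) {
      stop("spec error: planted modes must be orthonormal")
    }
  }
  structure(list(n_atoms = as.integer(n_atoms),
                 n_frames = as.integer(n_frames),
                 amplitudes = amplitudes, noise_sd = noise_sd,
                 rigid_motion = isTRUE(rigid_motion), modes = modes,
                 seed = as.integer(seed)),
            class = "rmr_modal_trajectory_spec")
}

# idealised alpha-helix C-alpha trace: radius 2.3 A, rise 1.5 A, 100 deg
helix_reference <- function(n_atoms) {
  i <- seq_len(n_atoms) - 1L
  ang <- i * 100 * pi / 180
  cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
}

# orthonormal basis of the 6 rigid-body directions (3 translations +
# 3 linearised rotations about the centroid) at a reference geometry
rigid_body_basis <- function(ref) {
  n <- nrow(ref)
  ctr <- sweep(ref, 2, colMeans(ref))
  B <- matrix(0, nrow = 3L * n, ncol = 6L)
  for (k in 1:3) B[seq(k, 3L * n, by = 3L), k] <- 1
  axes <- diag(3)
  for (k in 1:3) {
    w <- t(vapply(seq_len(n), function(i) {
      c(axes[k, 2] * ctr[i, 3] - axes[k, 3] * ctr[i, 2],
        axes[k, 3] * ctr[i, 1] - axes[k, 1] * ctr[i, 3],
        axes[k, 1] * ctr[i, 2] - axes[k, 2] * ctr[i, 1])
    }, numeric(3)))
    B[, 3L + k] <- as.vector(t(w))
  }
  qr.Q(qr(B))[, seq_len(qr(B)$rank), drop = FALSE]
}

#' Random orthonormal internal modes
#'
#' Generates `k` random unit 3N vectors, projected out of the rigid-body
#' subspace of the reference geometry and mutually orthonormalised, for use
#' as planted collective modes.
#'
#' @param reference n x 3 reference coordinates.
#' @param k number of modes.
#' @param seed integer seed.
#' @return 3N x k orthonormal matrix.
#' @export
random_internal_modes <- function(reference, k, seed = 1L) {
  ref <- as.matrix(reference)
  n3 <- 3L * nrow(ref)
  RB <- rigid_body_basis(ref)
  set.seed(seed)
  raw <- matrix(stats::rnorm(n3 * k), nrow = n3)
  raw <- raw - RB %*% crossprod(RB, raw)
  qr.Q(qr(raw))[, seq_len(k), drop = FALSE]
}

random_rotation <- function() {
  A <- matrix(stats::rnorm(9), 3, 3)
  qrA <- qr(A)
  Q <- qr.Q(qrA)
  Q <- Q %*% diag(sign(diag(qr.R(qrA))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Generate a trajectory with planted collective modes
#'
#' Frame `t` coordinates are `reference + sum_k a_k(t) mode_k + noise` with
#' `a_k(t) ~ N(0, amplitude_k^2)` and isotropic per-coordinate Gaussian
#' noise; an optional random rigid motion is applied last, so recovering
#' the planted modes requires superposition.
#'
#' @param spec an `rmr_modal_trajectory_spec`.
#' @return an `rmr_ensemble` of C-alpha-only frames; the spec, reference
#'   coordinates, mode matrix and per-frame mode projections are attached
#'   as attributes `spec`, `reference`, `modes`, `projections`.
#' @export
generate_modal_trajectory <- function(spec) {
  stopifnot(inherits(spec, "rmr_modal_trajectory_spec"))
  n <- spec$n_atoms
  ref <- helix_reference(n)
  k <- length(spec$amplitudes)
  modes <- spec$modes
  if (is.null(modes)) {
    modes <- random_internal_modes(ref, k, split_seed(spec$seed, "modal/modes"))
  }
  set.seed(split_seed(spec$seed, "modal/amplitudes"))
  A <- matrix(stats::rnorm(spec$n_frames * k), ncol = k)
  A <- sweep(A, 2, spec$amplitudes, "*")
  set.seed(split_seed(spec$seed, "modal/noise"))
  noise <- matrix(stats::rnorm(spec$n_frames * 3L * n, 0, spec$noise_sd),
                  nrow = spec$n_frames)
  set.seed(split_seed(spec$seed, "modal/rigid"))
  frames <- vector("list", spec$n_frames)
  base_atoms <- data.frame(
    serial = seq_len(n), name = "CA", element = "C", resname = "ALA",
    resno = seq_len(n), chain = "A", x = 0, y = 0, z = 0,
    role = "receptor", stringsAsFactors = FALSE)
  for (t in seq_len(spec$n_frames)) {
    disp <- as.vector(modes %*% A[t, ]) + noise[t, ]
    xyz <- ref + matrix(disp, ncol = 3L, byrow = TRUE)
    if (spec$rigid_motion) {
      R <- random_rotation()
      tr <- stats::runif(3, -5, 5)
      xyz <- sweep(xyz %*% t(R), 2, tr, "+")
    }
    at <- base_atoms
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
    fr <- new_frame(at, index = t - 1L, time_ps = 10 * t)
    frames[[t]] <- assign_atom_types(fr, "element")
  }
  ens <- new_ensemble(frames)
  attr(ens, "spec") <- spec
  attr(ens, "reference") <- ref
  attr(ens, "modes") <- modes
  attr(ens, "projections") <- A
  ens
}

#' Write frame labels as TSV
#' @param labels data.frame with `frame_index`, `label`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
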