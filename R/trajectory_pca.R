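# Equilibration diagnostics and essential dynamics: Kabsch superposition,
# RMSD series, stable-window frame extraction, and PCA of the C-alpha
# coordinate covariance with porcupine-arrow export.

coords_of <- function(x) {
  if (inherits(x, "rmr_frame")) frame_coords(x) else as.matrix(x)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares optimal rotation + translation mapping `mobile` onto
#' `reference` over the selected atoms; reflections are excluded, so the
#' rotation is proper (`det = +1`).
#'
#' @param mobile,reference n x 3 coordinate matrices or `rmr_frame`s
#'   sharing atom indexing.
#' @param selection integer atom indices used for the fit (default: all).
#' @return list of class `rmr_superposition` with `rotation` (3 x 3),
#'   `translation` (length 3), `rmsd` (over the selection, after the fit)
#'   and `transform(xyz)`, a function applying the fit to any n x 3 matrix.
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  M <- coords_of(mobile)
  R <- coords_of(reference)
  stopifnot(nrow(M) == nrow(R), ncol(M) == 3, ncol(R) == 3)
  sel <- if (is.null(selection)) seq_len(nrow(M)) else as.integer(selection)
  if (length(sel) < 3L) stop("rank error: need at least 3 atoms to superpose")
  Ms <- M[sel, , drop = FALSE]
  Rs <- R[sel, , drop = FALSE]
  cm <- colMeans(Ms)
  cr <- colMeans(Rs)
  A <- sweep(Ms, 2, cm)
  B <- sweep(Rs, 2, cr)
  sv_chk <- svd(A, nu = 0, nv = 0)$d
  if (sv_chk[2] <= 1e-8 * max(sv_chk[1], 1)) {
    stop("rank error: selection is collinear or degenerate")
  }
  H <- crossprod(A, B)          # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  rot <- sv$v %*% D %*% t(sv$u) # maps centred mobile onto centred reference
  fitted <- sweep(A %*% t(rot), 2, cr, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Rs)^2)))
  trans <- as.numeric(cr - rot %*% cm)
  structure(
    list(rotation = rot, translation = trans, rmsd = rmsd,
         transform = function(xyz) {
           sweep(as.matrix(xyz) %*% t(rot), 2, trans, "+")
         }),
    class = "rmr_superposition")
}

#' @export
print.rmr_superposition <- function(x, ...) {
  cat(sprintf("<rmr_superposition> rmsd = %.4f A, det(R) = %.6f\n",
              x$rmsd, det(x$rotation)))
  invisible(x)
}

#' Root-mean-square deviation between two coordinate sets
#' @param a,b n x 3 matrices or frames with identical indexing.
#' @param selection optional integer atom indices.
#' @export
rmsd <- function(a, b, selection = NULL) {
  A <- coords_of(a)
  B <- coords_of(b)
  if (!is.null(selection)) {
    A <- A[selection, , drop = FALSE]
    B <- B[selection, , drop = FALSE]
  }
  sqrt(mean(rowSums((A - B)^2)))
}

#' RMSD time series of an ensemble against a reference frame
#'
#' Each frame is (optionally) superposed on the reference over the
#' selection before the RMSD is recorded.  The default selection is the
#' main-chain C, O and N atoms (C-alpha deliberately excluded; use
#' `"calpha"` or a custom selection for the conventional backbone set).
#'
#' @param ensemble an `rmr_ensemble`.
#' @param reference an `rmr_frame` sharing the ensemble topology.
#' @param selection_spec `"mainchain_CON"`, `"calpha"` or `"custom"`.
#' @param indices custom atom indices when `selection_spec = "custom"`.
#' @param fit superpose before measuring (default `TRUE`); set `FALSE` for
#'   pre-aligned fixtures.
#' @return data.frame with columns `time_ps`, `rmsd`.
#' @export
rmsd_series <- function(ensemble, reference,
                        selection_spec = c("mainchain_CON", "calpha", "custom"),
                        indices = NULL, fit = TRUE) {
  selection_spec <- match.arg(selection_spec)
  sel <- select_atoms(reference, selection_spec, indices)
  ref_xyz <- frame_coords(reference)
  vals <- vapply(ensemble$frames, function(fr) {
    if (fit) {
      kabsch_superpose(frame_coords(fr), ref_xyz, sel)$rmsd
    } else {
      rmsd(frame_coords(fr), ref_xyz, sel)
    }
  }, 0)
  data.frame(time_ps = ensemble_times(ensemble), rmsd = vals)
}

#' Extract the trailing stable window of a trajectory
#'
#' Keeps frames with time in the half-open window `(T_end - window, T_end]`
#' sampled every `interval_ps`, anchored at the final frame.  With a
#' 25 000 ps trajectory at 10 ps spacing, `window_ns = 4` and
#' `interval_ps = 10` yield exactly 400 frames.
#'
#' @param ensemble an `rmr_ensemble` with (approximately) uniform spacing.
#' @param window_ns window length, nanoseconds.
#' @param interval_ps sampling interval, picoseconds; must be a multiple of
#'   the frame spacing.
#' @return the sub-ensemble, frame order preserved.
#' @export
extract_window <- function(ensemble, window_ns, interval_ps) {
  tt <- ensemble_times(ensemble)
  if (length(tt) < 2L) stop("range error: need at least 2 frames")
  sp <- diff(tt)
  spacing <- sp[[1L]]
  if (any(abs(sp - spacing) > 1e-6)) {
    stop("range error: frame spacing is not uniform")
  }
  ratio <- interval_ps / spacing
  if (abs(ratio - round(ratio)) > 1e-9 || ratio < 1) {
    stop("range error: interval_ps must be a positive multiple of the frame spacing")
  }
  window_ps <- 1000 * window_ns
  t_end <- tt[[length(tt)]]
  span <- t_end - tt[[1L]]
  if (window_ps > span + spacing + 1e-9) {
    stop("range error: window longer than the trajectory")
  }
  off <- (t_end - tt) / interval_ps
  keep <- tt > t_end - window_ps + 1e-9 & abs(off - round(off)) < 1e-9
  new_ensemble(ensemble$frames[keep])
}

#' Principal component analysis of C-alpha coordinate covariance
#'
#' Every frame is superposed on the reference over the C-alpha atoms to
#' remove global translation and rotation; the 3N C-alpha coordinate
#' vectors are mean-centred and the covariance `(1/(F-1)) X'X` is
#' diagonalised (via SVD of the centred coordinate matrix).  Modes are
#' sorted by decreasing eigenvalue; each eigenvector's sign is fixed so its
#' largest-magnitude component is positive.
#'
#' @param ensemble an `rmr_ensemble` with at least 2 frames.
#' @param reference fit reference frame (default: first frame of the
#'   ensemble; pass the crystal structure when one is available).
#' @param selection_spec,indices atom selection (default C-alpha).
#' @param fit superpose before the PCA (default `TRUE`).
#' @return object of class `rmr_modes`: `eigenvalues` (A^2, decreasing),
#'   `vectors` (3N x k, orthonormal columns), `variance_fraction`,
#'   `atom_indices`, `n_atoms`.
#' @export
compute_pca <- function(ensemble, reference = NULL,
                        selection_spec = c("calpha", "mainchain_CON", "custom"),
                        indices = NULL, fit = TRUE) {
  selection_spec <- match.arg(selection_spec)
  if (length(ensemble$frames) < 2L) stop("data error: PCA needs >= 2 frames")
  if (is.null(reference)) reference <- ensemble$frames[[1L]]
  sel <- select_atoms(reference, selection_spec, indices)
  ref_xyz <- frame_coords(reference)
  F_ <- length(ensemble$frames)
  X <- matrix(0, nrow = F_, ncol = 3L * length(sel))
  for (i in seq_len(F_)) {
    xyz <- frame_coords(ensemble$frames[[i]])
    if (fit) {
      fitres <- kabsch_superpose(xyz, ref_xyz, sel)
      xyz <- fitres$transform(xyz)
    }
    X[i, ] <- as.vector(t(xyz[sel, , drop = FALSE]))
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc, nu = 0)
  lambda <- sv$d^2 / (F_ - 1)
  k <- min(F_ - 1L, ncol(Xc))
  lambda <- lambda[seq_len(k)]
  V <- sv$v[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-magnitude component positive
  for (j in seq_len(k)) {
    m <- which.max(abs(V[, j]))
    if (V[m, j] < 0) V[, j] <- -V[, j]
  }
  tot <- sum(lambda)
  structure(
    list(eigenvalues = lambda, vectors = V,
         variance_fraction = if (tot > 0) lambda / tot else rep(0, k),
         atom_indices = sel, n_atoms = length(sel)),
    class = "rmr_modes")
}

#' @export
print.rmr_modes <- function(x, ...) {
  k <- min(3L, length(x$eigenvalues))
  cat(sprintf("<rmr_modes> %d modes over %d atoms; top eigenvalues: %s\n",
              length(x$eigenvalues), x$n_atoms,
              paste(sprintf("%.4g (%.1f%%)", x$eigenvalues[seq_len(k)],
                            100 * x$variance_fraction[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}

#' Extract one mode as a standalone record
#'
#' @param modes an `rmr_modes` object.
#' @param index 1-based mode index (1 = largest eigenvalue).
#' @return list with `index`, `eigenvalue`, `vector` (unit 3N vector),
#'   `variance_fraction`.
#' @export
get_mode <- function(modes, index = 1L) {
  stopifnot(index >= 1L, index <= length(modes$eigenvalues))
  list(index = as.integer(index),
       eigenvalue = modes$eigenvalues[[index]],
       vector = modes$vectors[, index],
       variance_fraction = modes$variance_fraction[[index]])
}

#' Porcupine arrows for one eigenvector
#'
#' One arrow per selected atom: the start is the reference coordinate, the
#' end adds the atom's three eigenvector components multiplied by a common
#' arbitrary scale factor, so relative arrow lengths are scale-independent.
#'
#' @param reference an `rmr_frame` holding the reference coordinates.
#' @param mode a mode record from [get_mode()] (or any list with a `vector`
#'   field of length `3 * length(atom_indices)`).
#' @param scale common scale factor applied to every atom.
#' @param atom_indices atom rows the mode components refer to; defaults to
#'   the C-alpha selection of `reference`.
#' @return data.frame with `atom_index`, `x0,y0,z0`, `x1,y1,z1`, `length`.
#' @export
porcupine_arrows <- function(reference, mode, scale = 1,
                             atom_indices = NULL) {
  if (is.null(atom_indices)) atom_indices <- select_atoms(reference, "calpha")
  v <- mode$vector
  if (length(v) != 3L * length(atom_indices)) {
    stop("shape error: mode vector length ", length(v),
         " does not match 3 x ", length(atom_indices), " selected atoms")
  }
  start <- frame_coords(reference)[atom_indices, , drop = FALSE]
  comp <- matrix(v, ncol = 3L, byrow = TRUE)
  end <- start + scale * comp
  data.frame(atom_index = atom_indices,
             x0 = start[, 1], y0 = start[, 2], z0 = start[, 3],
             x1 = end[, 1], y1 = end[, 2], z1 = end[, 3],
             length = sqrt(rowSums((end - start)^2)))
}
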