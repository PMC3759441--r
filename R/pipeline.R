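# Per-variant analysis orchestration: pocket selection on a reference
# frame, frame-by-frame scoring, native-like representative selection,
# reactive-distance feasibility, SRS-classified per-residue tables,
# hydrogen-bond networks and cross-variant comparison.

#' Select the binding pocket around the ligand
#'
#' Receptor residues with at least one atom within `cutoff` of any ligand
#' atom in the given frame.  The pocket is typically defined once on a
#' reference frame and held fixed across the ensemble so per-residue score
#' trajectories stay comparable.
#'
#' @param frame an `rmr_frame` with roles assigned.
#' @param cutoff heavy-atom contact cutoff, Angstrom (default 5).
#' @param include_cofactor also score the cofactor residue(s) (default
#'   `TRUE`; the heme is part of the paper-style pocket).
#' @return object of class `rmr_pocket` with `residues` (data.frame:
#'   chain, resno, resname), `cutoff`, `include_cofactor`.
#' @export
select_pocket <- function(frame, cutoff = 5, include_cofactor = TRUE) {
  a <- frame$atoms
  lig <- which(a$role == "ligand")
  if (length(lig) == 0L) stop("role error: frame has no ligand atoms")
  rec <- which(a$role == "receptor")
  residues <- data.frame(chain = character(0), resno = integer(0),
                         resname = character(0), stringsAsFactors = FALSE)
  if (length(rec) > 0L) {
    lx <- as.matrix(a[lig, c("x", "y", "z")])
    rx <- as.matrix(a[rec, c("x", "y", "z")])
    d2 <- outer(rowSums(rx^2), rowSums(lx^2), "+") - 2 * tcrossprod(rx, lx)
    near <- apply(d2, 1L, min) <= cutoff^2 + 1e-12
    hit <- rec[near]
    if (length(hit) > 0L) {
      residues <- unique(data.frame(chain = a$chain[hit],
                                    resno = a$resno[hit],
                                    resname = a$resname[hit],
                                    stringsAsFactors = FALSE))
      residues <- residues[order(residues$chain, residues$resno), ,
                           drop = FALSE]
      rownames(residues) <- NULL
    }
  }
  structure(list(residues = residues, cutoff = cutoff,
                 include_cofactor = include_cofactor),
            class = "rmr_pocket")
}

#' @export
print.rmr_pocket <- function(x, ...) {
  cat(sprintf("<rmr_pocket> %d residues within %g A%s\n",
              nrow(x$residues), x$cutoff,
              if (x$include_cofactor) " (+ cofactor)" else ""))
  invisible(x)
}

#' Reactive-pair distance and catalytic feasibility
#'
#' Euclidean distance between two atoms (e.g. the ferryl oxygen and the
#' ligand's hydroxylation carbon) with a feasibility annotation: distances
#' at or above `min_allowed` (default 2.9 Angstrom, the proposed minimum
#' between a substrate hydroxylation site and the heme center) are flagged
#' feasible.  The threshold annotates — it never filters frames.
#'
#' @param frame an `rmr_frame`.
#' @param probe_serial,target_serial atom serial numbers.
#' @param min_allowed feasibility threshold, Angstrom.
#' @return list with `distance` and `feasible`.
#' @export
reactive_distance <- function(frame, probe_serial, target_serial,
                              min_allowed = 2.9) {
  a <- frame$atoms
  ia <- match(probe_serial, a$serial)
  ib <- match(target_serial, a$serial)
  if (is.na(ia) || is.na(ib)) {
    stop("lookup error: serial(s) ",
         paste(c(probe_serial, target_serial)[c(is.na(ia), is.na(ib))],
               collapse = ", "), " not in frame")
  }
  d <- sqrt((a$x[ia] - a$x[ib])^2 + (a$y[ia] - a$y[ib])^2 +
              (a$z[ia] - a$z[ib])^2)
  list(distance = d, feasible = d >= min_allowed)
}

#' Score every frame of an ensemble
#'
#' @param ensemble a typed `rmr_ensemble` with roles assigned.
#' @param potential an `rmr_potential`.
#' @param pocket an `rmr_pocket`.
#' @param reactive_pair optional `c(probe_serial, target_serial)`.
#' @return list of `rmr_score_report`, one per frame, frame order
#'   preserved.
#' @export
score_ensemble <- function(ensemble, potential, pocket,
                           reactive_pair = NULL) {
  lapply(seq_along(ensemble$frames), function(i) {
    tryCatch(
      score_complex(potential, ensemble$frames[[i]], pocket, reactive_pair),
      error = function(e) {
        stop("frame ", i - 1L, ": ", conditionMessage(e), call. = FALSE)
      })
  })
}

#' Pick the most native-like frame
#'
#' The snapshot with the lowest total score is taken to exhibit the most
#' native-like biomolecular interaction; ties break to the earliest frame.
#'
#' @param reports list of `rmr_score_report`.
#' @return 0-based frame index of the minimum total.
#' @export
select_representative <- function(reports) {
  if (length(reports) < 1L) stop("data error: no score reports")
  totals <- vapply(reports, function(r) r$total, 0)
  reports[[which.min(totals)]]$frame_index
}

#' Build an SRS map
#'
#' Named residue ranges (substrate recognition sites SRS-1..SRS-6) used to
#' classify pocket residues; ranges must not overlap within a chain.
#'
#' @param ranges data.frame with columns `label`, `chain`, `start`, `end`.
#' @return validated data.frame of class `rmr_srs_map`.
#' @export
srs_map <- function(ranges) {
  need <- c("label", "chain", "start", "end")
  if (!all(need %in% names(ranges))) {
    stop("config error: SRS map needs columns label, chain, start, end")
  }
  if (any(ranges$end < ranges$start)) {
    stop("config error: SRS range with end < start")
  }
  for (ch in unique(ranges$chain)) {
    rr <- ranges[ranges$chain == ch, , drop = FALSE]
    rr <- rr[order(rr$start), , drop = FALSE]
    if (nrow(rr) > 1L && any(rr$start[-1L] <= rr$end[-nrow(rr)])) {
      stop("config error: overlapping SRS ranges in chain '", ch, "'")
    }
  }
  class(ranges) <- c("rmr_srs_map", "data.frame")
  ranges
}

#' Read an SRS map from TSV
#' @param path TSV with header `label`, `chain`, `start`, `end`.
#' @return an `rmr_srs_map`.
#' @export
read_srs_map <- function(path) {
  srs_map(utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE))
}

#' Per-residue score table classified by SRS
#'
#' Labels every per-residue entry of a score report by its SRS range (or
#' `"non-SRS"`); the cofactor is reported on its own `"cofactor"` row so
#' protein and heme contributions stay separable.  Row scores re-sum to the
#' report total.
#'
#' @param report an `rmr_score_report`.
#' @param map an `rmr_srs_map` (see [srs_map()]).
#' @return data.frame with `chain`, `resno`, `resname`, `srs`, `score`,
#'   sorted by residue number.
#' @export
per_residue_table <- function(report, map) {
  map <- srs_map(as.data.frame(map))  # re-validate
  pr <- report$per_residue
  lab <- character(nrow(pr))
  for (i in seq_len(nrow(pr))) {
    if (pr$role[[i]] == "cofactor") {
      lab[[i]] <- "cofactor"
      next
    }
    hit <- map$chain == pr$chain[[i]] &
      map$start <= pr$resno[[i]] & pr$resno[[i]] <= map$end
    lab[[i]] <- if (any(hit)) map$label[which(hit)[1L]] else "non-SRS"
  }
  out <- data.frame(chain = pr$chain, resno = pr$resno,
                    resname = pr$resname, srs = lab, score = pr$score,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chain, out$resno), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean pocket score over frames for a residue subset
#'
#' Mean over frames of the per-frame sum of the subset's per-residue
#' scores (the "cumulative score averaged across the stable window").
#'
#' @param reports list of `rmr_score_report`.
#' @param residues data.frame with `chain`, `resno` (and optionally
#'   `resname`) naming the subset; must be a subset of the reports'
#'   per-residue keys.
#' @return numeric mean.
#' @export
mean_pocket_score <- function(reports, residues) {
  stopifnot(length(reports) >= 1L)
  want <- paste(residues$chain, residues$resno, sep = ":")
  per_frame <- vapply(reports, function(r) {
    have <- paste(r$per_residue$chain, r$per_residue$resno, sep = ":")
    idx <- match(want, have)
    if (any(is.na(idx))) {
      stop("key error: residue(s) not in report: ",
           paste(want[is.na(idx)], collapse = ", "))
    }
    sum(r$per_residue$score[idx])
  }, 0)
  mean(per_frame)
}

#' Geometric hydrogen-bond detection
#'
#' Donor atoms are N/O heavy atoms of the donor residues; acceptors are O
#' atoms of the acceptor residues.  A bond is reported when the heavy-atom
#' donor-acceptor distance is at most `max_da` and, when the donor carries
#' a hydrogen (within 1.2 Angstrom) and `min_angle` is set, the D-H...A
#' angle at the hydrogen is at least `min_angle` for some such hydrogen.
#' Frames without hydrogens (crystal-derived fixtures) are judged on the
#' distance criterion alone.  Intra-residue pairs are skipped.
#'
#' @param frame an `rmr_frame`.
#' @param donor_residues,acceptor_residues residue numbers (vector) or
#'   data.frame with `chain`, `resno`.
#' @param max_da heavy-atom distance cutoff, Angstrom (default 3.5).
#' @param min_angle minimum D-H...A angle in degrees, or `NULL` to skip the
#'   angle criterion.
#' @return data.frame, one row per hydrogen bond.
#' @export
find_hydrogen_bonds <- function(frame, donor_residues, acceptor_residues,
                                max_da = 3.5, min_angle = NULL) {
  a <- frame$atoms
  res_idx <- function(sel) {
    if (is.data.frame(sel)) {
      which(paste(a$chain, a$resno) %in% paste(sel$chain, sel$resno))
    } else {
      which(a$resno %in% sel)
    }
  }
  don_at <- intersect(res_idx(donor_residues),
                      which(toupper(a$element) %in% c("N", "O")))
  acc_at <- intersect(res_idx(acceptor_residues),
                      which(toupper(a$element) == "O"))
  if (length(don_at) == 0L || length(acc_at) == 0L) {
    stop("selection error: empty donor or acceptor atom selection")
  }
  xyz <- as.matrix(a[, c("x", "y", "z")])
  hyd <- which(toupper(a$element) == "H")
  out <- list()
  for (d in don_at) {
    dh <- integer(0)
    if (length(hyd) > 0L) {
      hd <- sqrt(rowSums(sweep(xyz[hyd, , drop = FALSE], 2, xyz[d, ])^2))
      dh <- hyd[hd <= 1.2]
    }
    for (acc in acc_at) {
      if (a$chain[d] == a$chain[acc] && a$resno[d] == a$resno[acc]) next
      if (d == acc) next
      dd <- sqrt(sum((xyz[d, ] - xyz[acc, ])^2))
      if (dd > max_da) next
      ang <- NA_real_
      if (length(dh) > 0L) {
        angles <- vapply(dh, function(h) {
          v1 <- xyz[d, ] - xyz[h, ]
          v2 <- xyz[acc, ] - xyz[h, ]
          cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
          acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        }, 0)
        ang <- max(angles)
        if (!is.null(min_angle) && ang < min_angle) next
      }
      out[[length(out) + 1L]] <- data.frame(
        donor_chain = a$chain[d], donor_resno = a$resno[d],
        donor_resname = a$resname[d], donor_atom = a$name[d],
        acceptor_chain = a$chain[acc], acceptor_resno = a$resno[acc],
        acceptor_resname = a$resname[acc], acceptor_atom = a$name[acc],
        distance = dd, angle = ang, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(donor_chain = character(0), donor_resno = integer(0),
                      donor_resname = character(0), donor_atom = character(0),
                      acceptor_chain = character(0),
                      acceptor_resno = integer(0),
                      acceptor_resname = character(0),
                      acceptor_atom = character(0),
                      distance = numeric(0), angle = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Compare variants by their representative frames
#'
#' For each named report set: the representative (lowest-total) frame, its
#' total score, reactive-pair score, reactive distance and catalytic
#' feasibility.  Variants are ranked by reactive-pair score ascending
#' (most favourable first); ties break by reactive distance ascending,
#' then input order.
#'
#' @param report_sets named list; each element a list of
#'   `rmr_score_report` carrying reactive-pair information.
#' @param min_allowed feasibility threshold, Angstrom (default 2.9).
#' @return data.frame of class `rmr_variant_comparison`, one row per
#'   variant in rank order, with a `rank` column.
#' @export
compare_variants <- function(report_sets, min_allowed = 2.9) {
  if (length(report_sets) < 2L) stop("need at least 2 variants to compare")
  if (is.null(names(report_sets)) || any(names(report_sets) == "")) {
    stop("config error: report sets must be named")
  }
  rows <- lapply(names(report_sets), function(nm) {
    reports <- report_sets[[nm]]
    rep_idx <- select_representative(reports)
    rep_report <- reports[[which(vapply(reports, function(r) r$frame_index,
                                        0L) == rep_idx)[1L]]]
    if (is.null(rep_report$reactive_pair)) {
      stop("config error: variant '", nm,
           "' was scored without a reactive pair")
    }
    data.frame(variant = nm, representative_frame = rep_idx,
               total = rep_report$total,
               reactive_score = rep_report$reactive_pair$score,
               reactive_distance = rep_report$reactive_distance,
               feasible = rep_report$reactive_distance >= min_allowed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(out$reactive_score, out$reactive_distance,
               seq_len(nrow(out)))
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("rmr_variant_comparison", "data.frame")
  out
}
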