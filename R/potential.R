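# Distance-binned knowledge-based pair potential with a mean reference
# state.  A pair score is the negative log ratio of a type pair's binned
# distance probability to the type-pooled ("mean") distribution, so
# negative values mark contacts that are more frequent than average in the
# training database — the favourable direction.

#' Define a half-open distance binning
#'
#' Bins are `[d_min + k*width, d_min + (k+1)*width)`; the right edge
#' `d_max` is excluded.  `(d_max - d_min) / width` must be a whole number.
#'
#' @param d_min,d_max bin range in Angstrom, `0 <= d_min < d_max`.
#' @param width bin width in Angstrom.
#' @return an object of class `rmr_binning`.
#' @export
distance_binning <- function(d_min = 0, d_max = 6, width = 0.2) {
  d_min <- as.numeric(d_min)
  d_max <- as.numeric(d_max)
  width <- as.numeric(width)
  stopifnot(d_min >= 0, d_max > d_min, width > 0)
  n <- (d_max - d_min) / width
  if (abs(n - round(n)) > 1e-9) {
    stop("(d_max - d_min) must be an integer multiple of width")
  }
  structure(list(d_min = d_min, d_max = d_max, width = width,
                 n_bins = as.integer(round(n))),
            class = "rmr_binning")
}

#' Map a distance to its bin index
#'
#' @param distance positive distance(s), Angstrom.
#' @param binning an `rmr_binning`.
#' @return 0-based integer bin index, or `NA` for distances outside
#'   `[d_min, d_max)` (half-open: the right edge maps to `NA`).
#' @export
bin_index <- function(distance, binning) {
  if (any(distance <= 0)) stop("domain error: distances must be positive")
  k <- floor((distance - binning$d_min) / binning$width)
  k <- pmin(k, binning$n_bins - 1L)  # float guard at the right edge
  out <- as.integer(k)
  out[distance < binning$d_min | distance >= binning$d_max] <- NA_integer_
  out
}

pair_key <- function(type_a, type_b) {
  paste(pmin(type_a, type_b), pmax(type_a, type_b), sep = "|")
}

#' Build the statistical potential from contact observations
#'
#' For each unordered type pair, bin counts `c_k` over `[d_min, d_max)` are
#' smoothed with a pseudocount and normalised:
#' `P_pair(k) = (c_k + alpha) / sum_j (c_j + alpha)`.  The mean reference
#' state pools the same observations over all type pairs and applies the
#' identical rule.  Contacts outside the binning range are ignored but
#' counted in the provenance record.
#'
#' @param contacts data.frame with columns `type_a`, `type_b`, `distance`
#'   (Angstrom); pair identity is unordered.
#' @param binning an `rmr_binning`.
#' @param pseudocount smoothing pseudocount `alpha > 0` added to every bin
#'   (Laplace by default); guarantees finite log ratios.
#' @param provenance optional free-text/list metadata stored verbatim.
#' @return an object of class `rmr_potential`.
#' @export
build_potential <- function(contacts, binning, pseudocount = 1,
                            provenance = NULL) {
  stopifnot(inherits(binning, "rmr_binning"), pseudocount > 0)
  need <- c("type_a", "type_b", "distance")
  if (!all(need %in% names(contacts))) {
    stop("contacts must have columns type_a, type_b, distance")
  }
  d <- contacts$distance
  if (any(d <= 0)) stop("domain error: contact distances must be positive")
  bins <- suppressWarnings(bin_index(d, binning))
  inside <- !is.na(bins)
  if (!any(inside)) {
    stop("empty-potential error: no contacts fall inside the binning range")
  }
  keys <- pair_key(as.character(contacts$type_a),
                   as.character(contacts$type_b))[inside]
  b <- bins[inside]
  ukeys <- sort(unique(keys))
  nb <- binning$n_bins
  counts <- matrix(0, nrow = length(ukeys), ncol = nb,
                   dimnames = list(ukeys, NULL))
  tab <- table(factor(keys, levels = ukeys), factor(b, levels = 0:(nb - 1L)))
  counts[,] <- as.numeric(tab)
  norm <- function(cnt) (cnt + pseudocount) / sum(cnt + pseudocount)
  pair_tables <- t(apply(counts, 1L, norm))
  dimnames(pair_tables) <- list(ukeys, NULL)
  ref_counts <- colSums(counts)
  structure(
    list(
      binning = binning,
      pair_tables = pair_tables,
      pair_counts = counts,
      reference_table = norm(ref_counts),
      reference_counts = ref_counts,
      pseudocount = pseudocount,
      provenance = c(list(n_observations = nrow(contacts),
                          n_used = sum(inside),
                          n_out_of_range = sum(!inside)),
                     provenance)
    ),
    class = "rmr_potential"
  )
}

#' @export
print.rmr_potential <- function(x, ...) {
  b <- x$binning
  cat(sprintf(paste0("<rmr_potential> %d type pairs, %d bins of %g A over ",
                     "[%g, %g), alpha = %g, %d contacts used\n"),
              nrow(x$pair_tables), b$n_bins, b$width, b$d_min, b$d_max,
              x$pseudocount, x$provenance$n_used))
  invisible(x)
}

#' Score one atom pair at a given distance
#'
#' Returns exactly 0 for any distance outside `[d_min, d_max)` — a pair
#' beyond the potential's contact range has no interaction.  For in-range
#' distances the score is `-ln(P_pair(bin) / P_ref(bin))`; type pairs never
#' observed in the training contacts fall back to the reference table and
#' therefore also score 0.  Negative scores are favourable.
#'
#' @param potential an `rmr_potential`.
#' @param type_a,type_b atom type labels (order irrelevant).
#' @param distance distance(s) in Angstrom, `> 0`; vectorised.
#' @return numeric score(s).
#' @export
pair_score <- function(potential, type_a, type_b, distance) {
  stopifnot(inherits(potential, "rmr_potential"))
  bins <- bin_index(distance, potential$binning)
  out <- numeric(length(distance))
  inside <- !is.na(bins)
  if (!any(inside)) return(out)
  key <- pair_key(as.character(type_a), as.character(type_b))
  row <- match(key, rownames(potential$pair_tables))
  if (is.na(row)) return(out)  # unseen pair: reference vs reference
  pp <- potential$pair_tables[row, bins[inside] + 1L]
  pr <- potential$reference_table[bins[inside] + 1L]
  out[inside] <- -log(pp / pr)
  out
}

# vectorised lookup used by score_complex: keys and bins of equal length
pair_score_bulk <- function(potential, keys, bins) {
  out <- numeric(length(keys))
  inside <- !is.na(bins)
  if (!any(inside)) return(out)
  rows <- match(keys[inside], rownames(potential$pair_tables))
  known <- !is.na(rows)
  idx <- which(inside)[known]
  if (length(idx) == 0L) return(out)
  b1 <- bins[idx] + 1L
  pp <- potential$pair_tables[cbind(rows[known], b1)]
  pr <- potential$reference_table[b1]
  out[idx] <- -log(pp / pr)
  out
}

residue_key <- function(chain, resno, resname) {
  paste(chain, resno, resname, sep = ":")
}

#' Score a ligand-bound frame against the potential
#'
#' Enumerates every (ligand atom, pocket-residue-or-cofactor atom) pair,
#' scores each with [pair_score()] semantics and aggregates: `total` is the
#' sum over pairs, `per_residue` sums pair scores by the receptor/cofactor
#' residue.  When `reactive_pair` is given, that atom pair (e.g. the ferryl
#' oxygen and the ligand's hydroxylation carbon) is additionally reported
#' with its Euclidean distance — its score is part of the total whenever
#' the partner atom belongs to a scored residue.
#'
#' @param potential an `rmr_potential`.
#' @param frame a typed `rmr_frame` with roles assigned.
#' @param pocket an `rmr_pocket` from [select_pocket()].
#' @param reactive_pair integer pair `c(probe_serial, target_serial)` or
#'   `NULL`.
#' @return an object of class `rmr_score_report` with fields `frame_index`,
#'   `time_ps`, `total`, `per_pair`, `per_residue`, `reactive_pair`,
#'   `reactive_distance`.
#' @export
score_complex <- function(potential, frame, pocket, reactive_pair = NULL) {
  a <- frame$atoms
  if (any(a$atom_type == "")) {
    stop("frame is not typed; call assign_atom_types() first")
  }
  lig <- which(a$role == "ligand")
  if (length(lig) == 0L) stop("role error: frame has no ligand atoms")

  rk <- residue_key(a$chain, a$resno, a$resname)
  pocket_keys <- residue_key(pocket$residues$chain, pocket$residues$resno,
                             pocket$residues$resname)
  if (!all(pocket_keys %in% rk)) {
    stop("pocket residues absent from frame: ",
         paste(setdiff(pocket_keys, rk), collapse = ", "))
  }
  part <- which(rk %in% pocket_keys & a$role == "receptor")
  if (isTRUE(pocket$include_cofactor)) {
    part <- c(part, which(a$role == "cofactor"))
  }

  # residue table rows are fixed by the pocket, not by which pairs happen
  # to fall in range, so per-frame reports are directly comparable
  res_rows <- unique(data.frame(
    chain = a$chain[part], resno = a$resno[part], resname = a$resname[part],
    role = a$role[part], stringsAsFactors = FALSE))
  res_rows <- res_rows[order(res_rows$chain, res_rows$resno), , drop = FALSE]
  rownames(res_rows) <- NULL

  if (length(part) > 0L) {
    lx <- as.matrix(a[lig, c("x", "y", "z")])
    px <- as.matrix(a[part, c("x", "y", "z")])
    d2 <- outer(rowSums(lx^2), rowSums(px^2), "+") - 2 * tcrossprod(lx, px)
    d2[d2 < 0] <- 0
    dist <- sqrt(d2)  # ligand x partner
    li <- rep(lig, times = length(part))
    pi_ <- rep(part, each = length(lig))
    dv <- as.vector(dist)
    keys <- pair_key(a$atom_type[li], a$atom_type[pi_])
    bins <- suppressWarnings(bin_index(pmax(dv, 1e-12), potential$binning))
    sc <- pair_score_bulk(potential, keys, bins)
    per_pair <- data.frame(
      ligand_serial = a$serial[li], partner_serial = a$serial[pi_],
      type_a = a$atom_type[li], type_b = a$atom_type[pi_],
      partner_residue = rk[pi_],
      distance = dv, bin = bins, score = sc, stringsAsFactors = FALSE)
    per_pair <- per_pair[order(per_pair$ligand_serial,
                               per_pair$partner_serial), , drop = FALSE]
    rownames(per_pair) <- NULL
    res_score <- tapply(per_pair$score,
                        factor(per_pair$partner_residue,
                               levels = residue_key(res_rows$chain,
                                                    res_rows$resno,
                                                    res_rows$resname)),
                        sum, default = 0)
    res_rows$score <- as.numeric(res_score)
  } else {
    per_pair <- data.frame(ligand_serial = integer(0),
                           partner_serial = integer(0),
                           type_a = character(0), type_b = character(0),
                           partner_residue = character(0),
                           distance = numeric(0), bin = integer(0),
                           score = numeric(0), stringsAsFactors = FALSE)
    res_rows$score <- numeric(0)
  }

  reactive <- NULL
  reactive_dist <- NULL
  if (!is.null(reactive_pair)) {
    stopifnot(length(reactive_pair) == 2L)
    ia <- match(reactive_pair[[1L]], a$serial)
    ib <- match(reactive_pair[[2L]], a$serial)
    if (is.na(ia) || is.na(ib)) {
      stop("lookup error: reactive pair serials ",
           paste(reactive_pair, collapse = ", "), " not all present")
    }
    dd <- sqrt(sum((c(a$x[ia], a$y[ia], a$z[ia]) -
                      c(a$x[ib], a$y[ib], a$z[ib]))^2))
    reactive <- list(
      atom_a = a$serial[ia], atom_b = a$serial[ib], distance = dd,
      bin = if (dd > 0) bin_index(dd, potential$binning) else NA_integer_,
      score = if (dd > 0)
        pair_score(potential, a$atom_type[ia], a$atom_type[ib], dd) else 0)
    reactive_dist <- dd
  }

  structure(
    list(frame_index = frame$index, time_ps = frame$time_ps,
         total = sum(per_pair$score), per_pair = per_pair,
         per_residue = res_rows, reactive_pair = reactive,
         reactive_distance = reactive_dist),
    class = "rmr_score_report")
}

#' @export
print.rmr_score_report <- function(x, ...) {
  cat(sprintf("<rmr_score_report> frame %d (t = %g ps): total %.4f over %d pairs, %d residues\n",
              x$frame_index, x$time_ps, x$total, nrow(x$per_pair),
              nrow(x$per_residue)))
  if (!is.null(x$reactive_pair)) {
    cat(sprintf("  reactive pair %d-%d: %.3f A, score %.4f\n",
                x$reactive_pair$atom_a, x$reactive_pair$atom_b,
                x$reactive_pair$distance, x$reactive_pair$score))
  }
  invisible(x)
}

POTENTIAL_FORMAT <- "rmr_potential/1"

#' Save a potential to JSON
#'
#' Lossless: probabilities are written at full double precision, so a
#' reload reproduces every table bitwise.
#'
#' @param potential an `rmr_potential`.
#' @param path output path (JSON).
#' @return `path`, invisibly.
#' @export
save_potential <- function(potential, path) {
  stopifnot(inherits(potential, "rmr_potential"))
  obj <- list(
    format = POTENTIAL_FORMAT,
    binning = unclass(potential$binning),
    pseudocount = potential$pseudocount,
    pairs = lapply(seq_len(nrow(potential$pair_tables)), function(i) {
      list(key = rownames(potential$pair_tables)[[i]],
           probabilities = unname(potential$pair_tables[i, ]),
           counts = unname(potential$pair_counts[i, ]))
    }),
    reference = list(probabilities = unname(potential$reference_table),
                     counts = unname(potential$reference_counts)),
    provenance = potential$provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a potential saved by [save_potential()]
#'
#' @param path JSON path.
#' @return an `rmr_potential`.
#' @export
load_potential <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("format error: cannot parse potential file ", path,
                         " (", conditionMessage(e), ")")
                  })
  if (is.null(obj$format) || !identical(obj$format, POTENTIAL_FORMAT)) {
    stop("format error: not a ", POTENTIAL_FORMAT, " file: ", path)
  }
  binning <- distance_binning(obj$binning$d_min, obj$binning$d_max,
                              obj$binning$width)
  nb <- binning$n_bins
  keys <- vapply(obj$pairs, function(p) p$key, "")
  as_num <- function(x) vapply(x, as.numeric, 0)
  pc <- do.call(rbind, lapply(obj$pairs, function(p) as_num(p$counts)))
  dimnames(pc) <- list(keys, NULL)
  if (ncol(pc) != nb) stop("format error: table width does not match binning")
  alpha <- as.numeric(obj$pseudocount)
  # probabilities are recomputed from the (exactly representable) counts
  # with the same arithmetic as build_potential, so a round trip
  # reproduces every table bitwise regardless of JSON float formatting
  norm <- function(cnt) (cnt + alpha) / sum(cnt + alpha)
  pt <- t(apply(pc, 1L, norm))
  dimnames(pt) <- list(keys, NULL)
  ref_counts <- as_num(obj$reference$counts)
  structure(
    list(binning = binning, pair_tables = pt, pair_counts = pc,
         reference_table = norm(ref_counts),
         reference_counts = ref_counts,
         pseudocount = alpha,
         provenance = obj$provenance),
    class = "rmr_potential")
}

#' Read a contact database from TSV/CSV
#'
#' @param path file with header columns `type_a`, `type_b`, `distance`.
#' @param sep field separator (tab by default).
#' @return data.frame of contact observations.
#' @export
read_contacts <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("type_a", "type_b", "distance")
  if (!all(need %in% names(df))) {
    stop("contact table must have columns type_a, type_b, distance")
  }
  df
}

#' Write a contact database as TSV
#' @param contacts data.frame with `type_a`, `type_b`, `distance`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(contacts, path) {
  utils::write.table(contacts[, c("type_a", "type_b", "distance")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
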