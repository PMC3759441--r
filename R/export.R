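# Plain-text artifact writers.  All numeric formatting is deterministic
# (fixed %.*g) and no writer embeds timestamps, so identical inputs give
# byte-identical files.

fmt_num <- function(x) sprintf("%.12g", x)

write_tsv_det <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an RMSD series as TSV
#' @param series data.frame from [rmsd_series()].
#' @param path output path.
#' @export
write_rmsd_series <- function(series, path) {
  write_tsv_det(data.frame(time_ps = series$time_ps,
                           rmsd_A = series$rmsd), path)
}

#' Write eigenmodes as JSON
#' @param modes an `rmr_modes` object.
#' @param path output path.
#' @export
write_modes <- function(modes, path) {
  obj <- list(
    format = "rmr_modes/1",
    n_atoms = modes$n_atoms,
    atom_indices = modes$atom_indices,
    modes = lapply(seq_along(modes$eigenvalues), function(i) {
      list(index = i, eigenvalue = modes$eigenvalues[[i]],
           variance_fraction = modes$variance_fraction[[i]],
           vector = modes$vectors[, i])
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write porcupine arrows as CSV
#' @param arrows data.frame from [porcupine_arrows()].
#' @param path output path.
#' @export
write_arrows <- function(arrows, path) {
  df <- arrows
  for (j in c("x0", "y0", "z0", "x1", "y1", "z1", "length")) {
    df[[j]] <- fmt_num(df[[j]])
  }
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write score reports as TSV
#'
#' One row per atom pair, followed by one summary row per residue and one
#' total row per frame (`row_type` distinguishes them).
#'
#' @param reports a single `rmr_score_report` or a list of them.
#' @param path output path.
#' @export
write_score_reports <- function(reports, path) {
  if (inherits(reports, "rmr_score_report")) reports <- list(reports)
  rows <- lapply(reports, function(r) {
    pair <- data.frame(
      frame = r$frame_index, row_type = "pair",
      ligand_serial = r$per_pair$ligand_serial,
      partner_serial = r$per_pair$partner_serial,
      residue = r$per_pair$partner_residue,
      distance = fmt_num(r$per_pair$distance),
      score = fmt_num(r$per_pair$score), stringsAsFactors = FALSE)
    res <- data.frame(
      frame = r$frame_index, row_type = "residue",
      ligand_serial = NA_integer_, partner_serial = NA_integer_,
      residue = residue_key(r$per_residue$chain, r$per_residue$resno,
                            r$per_residue$resname),
      distance = "", score = fmt_num(r$per_residue$score),
      stringsAsFactors = FALSE)
    tot <- data.frame(
      frame = r$frame_index, row_type = "total",
      ligand_serial = NA_integer_, partner_serial = NA_integer_,
      residue = "", distance = "", score = fmt_num(r$total),
      stringsAsFactors = FALSE)
    rbind(pair, res, tot)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a per-frame score summary as JSON
#'
#' Compact per-ensemble record used by the variant-comparison CLI: totals,
#' reactive score/distance per frame, plus the representative frame.
#'
#' @param reports list of `rmr_score_report`.
#' @param path output path.
#' @param name variant name embedded in the file.
#' @export
write_score_summary <- function(reports, path, name = "variant") {
  has_reactive <- !is.null(reports[[1L]]$reactive_pair)
  obj <- list(
    format = "rmr_score_summary/1",
    name = name,
    representative_frame = select_representative(reports),
    frames = lapply(reports, function(r) {
      rec <- list(frame = r$frame_index, time_ps = r$time_ps,
                  total = r$total)
      if (has_reactive) {
        rec$reactive_score <- r$reactive_pair$score
        rec$reactive_distance <- r$reactive_distance
      }
      rec
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a variant comparison as TSV
#' @param comparison an `rmr_variant_comparison`.
#' @param path output path.
#' @export
write_comparison <- function(comparison, path) {
  write_tsv_det(as.data.frame(comparison), path)
}

#' Write an SRS-classified per-residue table as TSV
#' @param table data.frame from [per_residue_table()].
#' @param path output path.
#' @export
write_residue_table <- function(table, path) {
  write_tsv_det(table, path)
}
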