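# Fixtures built in code and independent oracles used across test files.

topology_hash_of <- rmrscore:::topology_hash_of

# ---- frames -----------------------------------------------------------

# minimal protein + ligand + cofactor frame with real-ish geometry:
# two amino acids (backbone only), a two-atom ligand, a one-atom cofactor
toy_complex_frame <- function() {
  atoms <- data.frame(
    serial = 1:9,
    name = c("N", "CA", "C", "O", "N", "CA", "C", "C1", "FE"),
    element = c("N", "C", "C", "O", "N", "C", "C", "C", "FE"),
    resname = c(rep("ALA", 4), rep("GLY", 3), "LIG", "HEM"),
    resno = c(rep(10L, 4), rep(11L, 3), 900L, 950L),
    chain = c(rep("A", 7), "L", "X"),
    x = c(-1.20, 0.00, 1.20, 1.80, 1.60, 2.90, 3.50, 0.50, 3.00),
    y = c(0.80, 0.00, 0.70, 1.80, -0.30, -0.10, 1.20, 3.00, 4.00),
    z = c(0.00, 0.00, 0.00, 0.00, 0.00, 0.50, 1.00, 0.50, 2.00),
    stringsAsFactors = FALSE)
  fr <- new_frame(atoms)
  fr <- assign_roles(fr, ligand = "LIG", cofactor = "HEM")
  assign_atom_types(fr, "element")
}

# frame of n CA atoms at given coordinates
ca_frame <- function(xyz, index = 0L, time_ps = 0) {
  n <- nrow(xyz)
  new_frame(data.frame(
    serial = 1:n, name = "CA", element = "C", resname = "ALA",
    resno = 1:n, chain = "A", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    role = "receptor", atom_type = "C", stringsAsFactors = FALSE),
    index = index, time_ps = time_ps)
}

# hand-written multi-model PDB text (valid fixed-width records)
pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          record = "ATOM", element = substr(name, 1, 1)) {
  nm <- if (nchar(name) >= 4) name else sprintf(" %-3s", name)
  sprintf("%-6s%5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, resname, chain, resno, x, y, z, 1, 0, element)
}

two_model_pdb_text <- function() {
  mk <- function(dz) c(
    pdb_atom_line(1, "N", "ALA", "A", 1, 1.0, 2.0, 0.0 + dz),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 2.0, 2.5, 0.5 + dz),
    pdb_atom_line(3, "C", "ALA", "A", 1, 3.2, 1.8, 0.2 + dz),
    pdb_atom_line(4, "O", "ALA", "A", 1, 3.9, 2.1, -0.7 + dz),
    pdb_atom_line(5, "C1", "LIG", "L", 9, 5.0, 5.0, 1.0 + dz,
                  record = "HETATM", element = "C"))
  c("MODEL        1", mk(0), "ENDMDL",
    "MODEL        2", mk(0.25), "ENDMDL", "END")
}

# ---- statistical-potential oracle ------------------------------------
# from-scratch recount: cut() histograms + explicit log-ratio, sharing no
# code with build_potential/pair_score

oracle_potential <- function(contacts, d_min, d_max, width, alpha) {
  breaks <- seq(d_min, d_max, by = width)
  nb <- length(breaks) - 1L
  keep <- contacts$distance >= d_min & contacts$distance < d_max
  cc <- contacts[keep, , drop = FALSE]
  key <- paste(pmin(cc$type_a, cc$type_b), pmax(cc$type_a, cc$type_b),
               sep = "|")
  tables <- list()
  for (k in unique(key)) {
    d <- cc$distance[key == k]
    cnt <- as.numeric(table(cut(d, breaks, right = FALSE,
                                include.lowest = FALSE)))
    tables[[k]] <- (cnt + alpha) / sum(cnt + alpha)
  }
  cnt_all <- as.numeric(table(cut(cc$distance, breaks, right = FALSE,
                                  include.lowest = FALSE)))
  list(tables = tables,
       reference = (cnt_all + alpha) / sum(cnt_all + alpha),
       breaks = breaks, nb = nb)
}

oracle_pair_score <- function(op, type_a, type_b, d) {
  if (d < op$breaks[1] || d >= op$breaks[length(op$breaks)]) return(0)
  bin <- findInterval(d, op$breaks, rightmost.closed = FALSE)
  key <- paste(min(type_a, type_b), max(type_a, type_b), sep = "|")
  p_pair <- if (key %in% names(op$tables)) op$tables[[key]][bin]
            else op$reference[bin]
  -log(p_pair / op$reference[bin])
}

random_contact_db <- function(seed, max_n = 1000, max_types = 4) {
  set.seed(seed)
  types <- LETTERS[seq_len(sample(2:max_types, 1))]
  n <- sample(50:max_n, 1)
  data.frame(type_a = sample(types, n, replace = TRUE),
             type_b = sample(types, n, replace = TRUE),
             distance = runif(n, 0.2, 8), stringsAsFactors = FALSE)
}

# ---- Kabsch oracle: coarse-to-fine search over SO(3) ------------------

euler_rot <- function(a, b, c) {
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                             0, 0, 1), 3, 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                             sin(t), 0, cos(t)), 3, 3)
  Rz(a) %*% Ry(b) %*% Rz(c)
}

grid_min_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  f <- function(ang) {
    R <- euler_rot(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  best <- c(0, 0, 0)
  bestv <- Inf
  g1 <- seq(0, 2 * pi, by = pi / 12)
  g2 <- seq(0, pi, by = pi / 12)
  for (a in g1) for (b in g2) for (cc in g1) {
    v <- f(c(a, b, cc))
    if (v < bestv) { bestv <- v; best <- c(a, b, cc) }
  }
  step <- pi / 12
  for (it in 1:7) {
    step <- step / 4
    for (da in -3:3) for (db in -3:3) for (dc in -3:3) {
      ang <- best + step * c(da, db, dc)
      v <- f(ang)
      if (v < bestv) { bestv <- v; best <- ang }
    }
  }
  bestv
}

random_rotation_matrix <- function() {
  A <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(A))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# reference frame of a modal trajectory as an rmr_frame
modal_reference_frame <- function(traj) {
  ca_frame(attr(traj, "reference"))
}

abs_cosine <- function(u, v) abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
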