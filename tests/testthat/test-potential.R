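test_that("bin_index implements the half-open convention", {
  b <- distance_binning(0, 6, 0.2)
  expect_identical(bin_index(0.05, b), 0L)
  expect_identical(bin_index(6.0, b), NA_integer_)
  expect_identical(bin_index(3.12, b), 15L)
  expect_identical(bin_index(c(0.05, 3.12, 7.5), b), c(0L, 15L, NA))
  expect_error(bin_index(0, b), "domain error")
  expect_error(bin_index(-1, b), "domain error")
  expect_error(distance_binning(0, 6, 0.7), "integer multiple")
})

test_that("build_potential matches closed-form pseudocount arithmetic", {
  b2 <- distance_binning(0, 2, 1)
  # pair X-Y with counts (2,2), alpha = 1 -> (3/6, 3/6)
  contacts <- data.frame(type_a = "X", type_b = "Y",
                         distance = c(0.5, 0.6, 1.5, 1.6))
  pot <- build_potential(contacts, b2, pseudocount = 1)
  expect_equal(unname(pot$pair_tables["X|Y", ]), c(0.5, 0.5))
  # two pairs with disjoint single-bin supports, 4 obs each -> pooled
  # reference (4+1)/(8+2) per bin
  contacts <- data.frame(
    type_a = c(rep("A", 4), rep("C", 4)),
    type_b = c(rep("B", 4), rep("D", 4)),
    distance = c(rep(0.5, 4), rep(1.5, 4)))
  pot <- build_potential(contacts, b2, pseudocount = 1)
  expect_equal(unname(pot$reference_table), c(0.5, 0.5))
  expect_equal(unname(pot$pair_tables["A|B", ]), c(5 / 6, 1 / 6))
  # alpha -> 0 limit: single pair in one bin is an indicator, and the
  # reference equals it
  contacts <- data.frame(type_a = "A", type_b = "B", distance = rep(0.3, 10))
  pot <- build_potential(contacts, b2, pseudocount = 1e-12)
  expect_equal(unname(pot$pair_tables["A|B", ]), c(1, 0), tolerance = 1e-9)
  expect_equal(unname(pot$pair_tables["A|B", ]),
               unname(pot$reference_table))
  # degenerate inputs
  expect_error(build_potential(
    data.frame(type_a = "A", type_b = "B", distance = 9), b2),
    "empty-potential")
  expect_error(build_potential(
    data.frame(type_a = "A", type_b = "B", distance = -1), b2),
    "domain error")
})

test_that("tables are probability distributions and provenance counts range drops", {
  db <- random_contact_db(42)
  pot <- build_potential(db, distance_binning(0, 6, 0.2))
  expect_true(all(abs(rowSums(pot$pair_tables) - 1) < 1e-12))
  expect_equal(sum(pot$reference_table), 1, tolerance = 1e-12)
  expect_true(all(pot$pair_tables > 0))
  expect_equal(pot$provenance$n_used + pot$provenance$n_out_of_range,
               nrow(db))
})

test_that("pair_score: zero outside range, log-ratio inside, symmetric", {
  b2 <- distance_binning(0, 2, 1)
  # pair table (0.5, 0.5); reference (0.25, 0.75) is impossible from one
  # pair, so use two pairs: A-A in bin 0 only, A-B half and half
  contacts <- data.frame(
    type_a = c(rep("A", 4), "A", "A"),
    type_b = c(rep("A", 4), "B", "B"),
    distance = c(rep(0.5, 4), 0.5, 1.5))
  pot <- build_potential(contacts, b2, pseudocount = 1)
  # A|B: counts (1,1) -> (0.5, 0.5); reference counts (5,1) -> (0.75, 0.25)
  expect_equal(pair_score(pot, "A", "B", 1.5), -log(0.5 / 0.25))
  expect_identical(pair_score(pot, "A", "B", 10.0), 0)
  expect_identical(pair_score(pot, "A", "B", 2.0), 0)  # right edge
  expect_equal(pair_score(pot, "B", "A", 0.5),
               pair_score(pot, "A", "B", 0.5))
  # P_pair == P_ref -> exactly 0
  one <- build_potential(
    data.frame(type_a = "A", type_b = "B", distance = c(0.5, 1.5)), b2)
  expect_identical(pair_score(one, "A", "B", 0.5), 0)
  # unseen type pair falls back to the reference: 0 at any distance
  expect_identical(pair_score(pot, "Q", "Z", 1.0), 0)
  expect_error(pair_score(pot, "A", "B", 0), "domain error")
})

test_that("random databases agree with the from-scratch oracle", {
  b <- distance_binning(0, 6, 0.2)
  for (seed in 1:5) {
    db <- random_contact_db(seed)
    pot <- build_potential(db, b, pseudocount = 1)
    op <- oracle_potential(db, 0, 6, 0.2, 1)
    for (k in rownames(pot$pair_tables)) {
      expect_equal(unname(pot$pair_tables[k, ]), op$tables[[k]],
                   tolerance = 1e-12)
    }
    expect_equal(unname(pot$reference_table), op$reference,
                 tolerance = 1e-12)
    set.seed(seed + 1000)
    ds <- runif(20, 0.1, 7)
    tps <- matrix(sample(unique(c(db$type_a, db$type_b)), 40,
                         replace = TRUE), ncol = 2)
    for (i in 1:20) {
      expect_equal(pair_score(pot, tps[i, 1], tps[i, 2], ds[i]),
                   oracle_pair_score(op, tps[i, 1], tps[i, 2], ds[i]),
                   tolerance = 1e-12)
    }
  }
})

test_that("enriching a bin lowers that pair's score against a broad pool", {
  # the mean reference state pools all pairs, so the monotonicity holds
  # when the enriched pair is a minor contributor to the pooled bin (the
  # regime of a many-type contact database); a pair that IS the pool in a
  # bin dilutes itself instead
  b <- distance_binning(0, 4, 0.5)
  centers <- seq(0.25, 3.75, by = 0.5)
  base <- rbind(
    data.frame(type_a = "A", type_b = "B",
               distance = c(centers, 0.3, 0.8)),
    data.frame(type_a = "C", type_b = "D",
               distance = rep(centers, each = 60)))
  pot0 <- build_potential(base, b)
  s0 <- pair_score(pot0, "A", "B", 1.1)
  for (k in c(2, 5, 10)) {
    enriched <- rbind(base, data.frame(type_a = "A", type_b = "B",
                                       distance = rep(1.1, k)))
    s1 <- pair_score(build_potential(enriched, b), "A", "B", 1.1)
    expect_lt(s1, s0)
    s0 <- s1  # and monotone in the enrichment size
  }
})

test_that("score_complex decomposes additively and matches a double loop", {
  spec <- contact_db_spec(data.frame(
    type_a = c("C", "C", "O"), type_b = c("O", "N", "O"),
    mean = c(3.0, 4.0, 3.5), sd = c(0.4, 0.8, 0.5),
    count = c(500, 500, 500)), seed = 21)
  pot <- build_potential(generate_contact_db(spec), distance_binning(0, 6, 0.2))
  fr <- toy_complex_frame()
  pocket <- select_pocket(fr, cutoff = 6)
  rep_ <- score_complex(pot, fr, pocket, reactive_pair = c(9L, 8L))
  # additivity of the decomposition
  expect_equal(rep_$total, sum(rep_$per_pair$score), tolerance = 1e-12)
  expect_equal(rep_$total, sum(rep_$per_residue$score), tolerance = 1e-12)
  # independent double-loop recomputation
  a <- fr$atoms
  lig <- which(a$role == "ligand")
  part <- which(a$role != "ligand" &
                  (paste(a$chain, a$resno) %in%
                     paste(pocket$residues$chain, pocket$residues$resno) |
                     a$role == "cofactor"))
  tot <- 0
  for (i in lig) for (j in part) {
    d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) -
                     c(a$x[j], a$y[j], a$z[j]))^2))
    tot <- tot + pair_score(pot, a$atom_type[i], a$atom_type[j], d)
  }
  expect_equal(rep_$total, tot, tolerance = 1e-12)
  # reactive pair: distance is plain Euclidean
  d98 <- sqrt(sum((c(a$x[9], a$y[9], a$z[9]) -
                     c(a$x[8], a$y[8], a$z[8]))^2))
  expect_equal(rep_$reactive_distance, d98)
  expect_error(score_complex(pot, fr, pocket, reactive_pair = c(9L, 99L)),
               "lookup error")
  # ligand far away from everything -> all zeros
  far <- fr
  far$atoms$x[far$atoms$role == "ligand"] <- 500
  rep0 <- score_complex(pot, far, pocket)
  expect_identical(rep0$total, 0)
  expect_true(all(rep0$per_residue$score == 0))
})

test_that("potential serialization is lossless and deterministic", {
  db <- random_contact_db(7)
  pot <- build_potential(db, distance_binning(0, 6, 0.2),
                         provenance = list(note = "unit test"))
  f <- withr::local_tempfile(fileext = ".json")
  save_potential(pot, f)
  back <- load_potential(f)
  expect_identical(back$pair_tables, pot$pair_tables)
  expect_identical(back$reference_table, unname(pot$reference_table))
  expect_identical(back$pseudocount, pot$pseudocount)
  expect_identical(unclass(back$binning), unclass(pot$binning))
  for (d in c(0.7, 3.33, 5.99)) {
    expect_identical(pair_score(back, "A", "B", d),
                     pair_score(pot, "A", "B", d))
  }
  # corruption and version mismatch are format errors
  writeLines(substr(paste(readLines(f), collapse = ""), 1, 50), f)
  expect_error(load_potential(f), "format error")
  jsonlite::write_json(list(format = "other/9"), f, auto_unbox = TRUE)
  expect_error(load_potential(f), "format error")
})
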