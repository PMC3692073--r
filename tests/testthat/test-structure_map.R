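two_gly <- function() {
  write_pdb_text(data.frame(
    name = c("CA", "CA"), resname = "GLY", resnum = 1:2,
    x = c(0, 3), y = 0, z = 0, element = "C"
  ))
}

test_that("PDB parsing: residues, chains, first model only", {
  p <- generate_toy_pdb(5, "line", spacing = 3.8)
  s <- read_structure(p)
  expect_s3_class(s, "structure_model")
  expect_equal(nrow(s$residues), 5)
  expect_equal(s$chain_id, "A")
  expect_error(read_structure(p, chain = "B"), "available: A")

  # multi-model: only model 1 is read
  body <- readLines(p)
  atoms <- body[startsWith(body, "ATOM")]
  multi <- tempfile(fileext = ".pdb")
  shifted <- sub("^(.{30})", "\\1 ", atoms)  # model 2 would differ
  writeLines(c("MODEL        1", atoms, "ENDMDL",
               "MODEL        2", atoms[1:2], "ENDMDL", "END"), multi)
  sm <- read_structure(multi)
  expect_equal(nrow(sm$residues), 5)

  empty <- tempfile(fileext = ".pdb")
  writeLines(c("HEADER    NOTHING", "END"), empty)
  expect_error(read_structure(empty), "no ATOM records")
})

test_that("altloc keeps the highest-occupancy conformer", {
  at <- data.frame(
    name = c("CA", "CA", "CA"), resname = "ALA", resnum = c(1, 1, 2),
    x = c(0, 10, 3), y = 0, z = 0, element = "C",
    occ = c(0.3, 0.7, 1)
  )
  p <- write_pdb_text(at)
  # make the two residue-1 CA records altloc A/B
  lines <- readLines(p)
  substr(lines[1], 17, 17) <- "A"
  substr(lines[2], 17, 17) <- "B"
  writeLines(lines, p)
  s <- read_structure(p)
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$x[s$atoms$res == 1], 10)  # occupancy 0.7 wins
})

test_that("minimum distances exclude hydrogens and match the oracle", {
  s <- read_structure(two_gly())
  d <- min_distances(s)
  expect_equal(d[1, 2], 3.0)
  expect_equal(diag(d), c(`1` = 0, `2` = 0))

  # an H atom 1 A from residue 1, between the two: still 3.0
  withH <- write_pdb_text(data.frame(
    name = c("CA", "HA", "CA"), resname = "GLY", resnum = c(1, 1, 2),
    x = c(0, 1, 3), y = 0, z = 0, element = c("C", "H", "C")
  ))
  dh <- min_distances(read_structure(withH))
  expect_equal(dh[1, 2], 3.0)

  for (seed in c(13, 14)) {
    rs <- random_structure(6, seed)
    expect_equal(unname(min_distances(rs)), oracle_min_distances(rs),
                 tolerance = 1e-9)
  }
})

test_that("distances are invariant under rigid motion", {
  rs <- random_structure(5, 17)
  d0 <- min_distances(rs)
  # rotate 40 degrees about z and translate
  th <- 40 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(rs$atoms[, c("x", "y", "z")]) %*% t(R)
  rs2 <- rs
  rs2$atoms$x <- xyz[, 1] + 5
  rs2$atoms$y <- xyz[, 2] - 2
  rs2$atoms$z <- xyz[, 3] + 11
  expect_equal(min_distances(rs2), d0, tolerance = 1e-9)
})

test_that("hydrogen-only residues yield missing rows", {
  p <- write_pdb_text(data.frame(
    name = c("CA", "HA", "CA"), resname = "GLY", resnum = 1:3,
    x = c(0, 1, 3), y = 0, z = 0, element = c("C", "H", "C")
  ))
  d <- min_distances(read_structure(p))
  expect_true(all(is.na(d[2, ])))
  expect_true(all(is.na(d[, 2])))
  expect_equal(d[1, 3], 3.0)
})

test_that("Smith-Waterman mapping: identity, insertion, monotonicity", {
  a <- random_alignment(4, 20, seed = 23)
  m <- mask_columns(a, 0.5)
  ref <- a$seq[1]
  p <- generate_toy_pdb(20, "line", sequence = ref)
  s <- read_structure(p)
  map <- map_alignment_to_structure(a, m, s)
  expect_equal(map$coverage, 1)
  expect_equal(map$pairs$ref_pos, map$pairs$res_index)  # identity map

  # reference with a 2-residue insertion relative to the structure
  ins_ref <- paste0(substr(ref, 1, 10), "WW", substr(ref, 11, 20))
  b <- new_alignment(c("ref", a$id[-1]),
                     c(ins_ref, paste0(substr(a$seq[-1], 1, 10), "--",
                                       substr(a$seq[-1], 11, 20))))
  mb <- mask_columns(b, 0.5)
  map2 <- map_alignment_to_structure(b, mb, s)
  expect_false(any(c(11, 12) %in% map2$pairs$ref_pos))  # insertion unmapped
  expect_equal(setdiff(1:22, map2$pairs$ref_pos), c(11, 12))
  expect_true(all(diff(map2$pairs$res_index) > 0))  # order-preserving

  # mostly-unrelated sequence: the low-coverage warning path
  weak <- paste0(substr(ref, 1, 4), strrep("W", 16))
  un <- new_alignment(c("u1", "u2"), c(weak, weak))
  mu <- mask_columns(un, 0.5)
  expect_warning(map_alignment_to_structure(un, mu, s),
                 "low structure coverage")
})

test_that("distance network uses a strict cutoff", {
  p <- generate_toy_pdb(6, "line", spacing = 3.8)
  d <- min_distances(read_structure(p))
  net <- distance_network(d, cutoff = 5)
  expect_equal(nrow(net$edges), 5)  # consecutive residues only
  expect_true(all(abs(net$edges$distance - 3.8) < 1e-9))

  expect_equal(nrow(distance_network(d, cutoff = 0.1)$edges), 0)
  # boundary with exact arithmetic: two CAs exactly 3.0 A apart are NOT an
  # edge at cutoff 3.0 (strict "<")
  dg <- min_distances(read_structure(two_gly()))
  expect_equal(nrow(distance_network(dg, cutoff = 3.0)$edges), 0)
  expect_equal(nrow(distance_network(dg, cutoff = 3.0 + 1e-9)$edges), 1)

  rs <- random_structure(7, 29)
  dr <- min_distances(rs)
  nr <- distance_network(dr, 8)
  brute <- which(upper.tri(dr) & dr < 8, arr.ind = TRUE)
  expect_equal(nrow(nr$edges), nrow(brute))
  expect_equal(cbind(nr$edges$i, nr$edges$j), unname(brute))
})
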