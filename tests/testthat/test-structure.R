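test_that("the distance rule is boundary-inclusive at the threshold", {
  # residue 1 at 1.4 A from the ligand atom, residue 2 at 1.6 A
  sm <- make_structure(prot_xyz = rbind(c(0, 1.4, 0), c(10, 1.6, 0)),
                       lig_xyz = rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_identical(contact_residues(sm, "GDP", 1.5)$residues, 1L)
  # exactly at the boundary counts as contact
  sm2 <- make_structure(prot_xyz = rbind(c(0, 1.5, 0)),
                        lig_xyz = rbind(c(0, 0, 0)))
  expect_identical(contact_residues(sm2, "GDP", 1.5)$residues, 1L)
  expect_error(contact_residues(sm, "GDP", 0), "positive")
  expect_error(contact_residues(sm, "ATP", 1.5), "ligand absent")
})

test_that("PDB reading resolves altlocs by occupancy and rejects ligand-free files", {
  p <- withr::local_tempfile(fileext = ".pdb")
  write_altloc_pdb(p)
  sm <- read_structure(p)
  a <- sm$atoms
  expect_identical(nrow(a), 3L)  # 4 records, one altloc pair resolved
  kept <- a[!a$het & a$resno == 1, ]
  expect_equal(kept$x, 14)       # occupancy 0.60 beats 0.40
  # waters are not ligands
  wp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      10.000   0.000   0.000  1.00 10.00           C",
    "HETATM    2  O   HOH A   9      11.000   0.000   0.000  1.00 10.00           O",
    "END"), wp)
  expect_error(read_structure(wp), "ligand absent")
  expect_error(read_structure(withr::local_tempfile(fileext = ".pdb")),
               "not found")
})

test_that("generator-declared contact sets are recovered exactly", {
  st <- simulate_structure(10, c(3, 4, 7), threshold = 2.0, seed = 11)
  reg <- contact_residues(read_structure(st$path), "GDP", 2.0)
  expect_identical(reg$residues, c(3L, 4L, 7L))
  st0 <- simulate_structure(10, integer(0), threshold = 2.0, seed = 11)
  expect_identical(
    length(contact_residues(read_structure(st0$path), "GDP", 2.0)$residues),
    0L)
})

test_that("contact sets shrink monotonically with the threshold", {
  st <- simulate_structure(20, c(2, 5, 9, 13, 18), threshold = 2.5, seed = 3)
  sm <- read_structure(st$path)
  prev <- contact_residues(sm, "GDP", 3.5)$residues
  for (thr in c(3.0, 2.5, 2.0, 1.5, 1.0)) {
    cur <- contact_residues(sm, "GDP", thr)$residues
    expect_true(all(cur %in% prev), label = sprintf("threshold %.1f", thr))
    prev <- cur
  }
})

test_that("contact sets are invariant under rigid motions", {
  st <- simulate_structure(15, c(1, 6, 12), threshold = 2.0, seed = 5)
  sm <- read_structure(st$path)
  base <- contact_residues(sm, "GDP", 2.0)$residues
  for (seed in 1:5) {
    moved <- apply_rigid_motion(sm, seed = seed)
    expect_identical(contact_residues(moved, "GDP", 2.0)$residues, base)
  }
})

test_that("the numbering offset shifts annotated residues into sequence coordinates", {
  st <- simulate_structure(10, c(3, 7), threshold = 2.0, seed = 2)
  sm <- read_structure(st$path)
  reg <- contact_residues(sm, "GDP", 2.0, offset = 10, protein_length = 30)
  expect_identical(reg$residues, c(13L, 17L))
  expect_identical(reg$protein_length, 30L)
})

test_that("region fraction reports one-decimal percent of the protein", {
  expect_equal(region_fraction(region_annotation(1:24, 206)), 11.7)
  expect_equal(region_fraction(region_annotation(integer(0), 206)), 0)
  expect_equal(region_fraction(region_annotation(1:206, 206)), 100)
})

test_that("region export covers residue lists and 0-based half-open BED", {
  reg <- region_annotation(c(3, 4, 7), 10)
  iv <- region_intervals(reg)
  expect_identical(iv$start0, c(2L, 6L))
  expect_identical(iv$end, c(4L, 7L))
  expect_identical(region_intervals(region_annotation(25, 206)),
                   data.frame(start0 = 24L, end = 25L))
  expect_identical(region_intervals(region_annotation(1:206, 206)),
                   data.frame(start0 = 0L, end = 206L))
  bp <- withr::local_tempfile(fileext = ".bed")
  write_region(reg, bp, format = "bed", name = "RALA")
  expect_identical(readLines(bp), c("RALA\t2\t4", "RALA\t6\t7"))
  rp <- withr::local_tempfile(fileext = ".txt")
  write_region(reg, rp, format = "residues")
  expect_identical(read_region(rp, 10)$residues, reg$residues)
  expect_error(region_annotation(c(0, 5), 10), "outside")
})
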