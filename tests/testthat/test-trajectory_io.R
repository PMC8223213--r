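# Format boundaries: GRO/PDB input, the native fixture format and the
# tabular writers.

sp_map <- c(CM15 = "CM15", SUR = "SUR", DOPC = "DOPC")

test_that("GRO files round-trip within format precision", {
  topo <- make_topo(1, 1)
  fr <- frame(1, 0, c(5, 5, 5),
              matrix(c(1.2345, 2.3456, 3.4567, 4.1111, 0.2222, 1.3333),
                     ncol = 3, byrow = TRUE))
  bun <- bundle(list(fr), topo)
  f <- withr::local_tempfile(fileext = ".gro")
  write_gro(bun, f)
  back <- load_trajectory(f, species_map = sp_map)
  expect_lt(max(abs(back$frames[[1]]$coords - fr$coords)), 1e-3)
  expect_equal(back$frames[[1]]$box, c(5, 5, 5))
  expect_equal(nrow(back$topology$particles), 2)
})

test_that("PDB coordinates are converted from Angstrom to nm", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   50.000   50.000   50.000  90.00  90.00  90.00 P 1",
    "ATOM      1  CA  CM15A   1      12.000  24.000  36.000  1.00  0.00",
    "ATOM      2  CA  SUR A   2       6.000   8.000  10.000  1.00  0.00",
    "END"), f)
  bun <- load_trajectory(f, species_map = sp_map)
  expect_equal(bun$frames[[1]]$coords,
               matrix(c(1.2, 2.4, 3.6, 0.6, 0.8, 1.0), ncol = 3,
                      byrow = TRUE))
  expect_equal(bun$frames[[1]]$box, c(5, 5, 5))
})

test_that("structure/coordinate mismatches and unknown residues are hard errors", {
  f1 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   50.000   50.000   50.000  90.00  90.00  90.00 P 1",
    "ATOM      1  CA  CM15A   1      12.000  24.000  36.000  1.00  0.00",
    "ATOM      2  CA  CM15A   2       6.000   8.000  10.000  1.00  0.00",
    "END"), f1)
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   50.000   50.000   50.000  90.00  90.00  90.00 P 1",
    "MODEL     1",
    "ATOM      1  CA  CM15A   1      12.000  24.000  36.000  1.00  0.00",
    "ENDMDL",
    "END"), f2)
  expect_error(load_trajectory(f1, f2, species_map = sp_map),
               "particle-count mismatch")
  # unknown residue name is reported by name
  f3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   50.000   50.000   50.000  90.00  90.00  90.00 P 1",
    "ATOM      1  CA  XYZ A   1      12.000  24.000  36.000  1.00  0.00",
    "END"), f3)
  expect_error(load_trajectory(f3, species_map = sp_map), "XYZ")
  # binary trajectory formats are refused with guidance
  expect_error(load_trajectory(f1, "traj.xtc", species_map = sp_map),
               "not supported")
})

test_that("triclinic boxes are refused", {
  f <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("box test", "    1",
               "    1CM15    B1    1   1.000   1.000   1.000",
               "   5.0 5.0 5.0 0.0 0.0 1.2 0.0 0.0 0.0"), f)
  expect_error(load_trajectory(f, species_map = sp_map), "triclinic")
})

test_that("the native fixture format round-trips bit-identically", {
  bun <- generate_planted_trajectory(synthetic_preset("demo", seed = 7))
  f1 <- withr::local_tempfile(fileext = ".traj")
  f2 <- withr::local_tempfile(fileext = ".traj")
  write_fixture(bun, f1)
  back <- load_fixture(f1)
  write_fixture(back, f2)
  expect_identical(readBin(f1, "raw", 1e7), readBin(f2, "raw", 1e7))
  expect_identical(lapply(bun$frames, unclass), lapply(back$frames, unclass))
  expect_identical(bun$topology, back$topology)
  expect_identical(bun$ground_truth$labels, back$ground_truth$labels)

  # without the sidecar the bundle has no ground truth
  file.remove(paste0(f1, ".truth.json"))
  expect_null(load_fixture(f1)$ground_truth)
})

test_that("malformed fixtures fail with line numbers, never silently", {
  bun <- generate_planted_trajectory(synthetic_preset("demo", seed = 7))
  f <- withr::local_tempfile(fileext = ".traj")
  write_fixture(bun, f)
  lines <- readLines(f)
  # truncated final frame: drop the last 3 coordinate lines
  writeLines(lines[1:(length(lines) - 3)], f)
  expect_error(load_fixture(f), "truncated frame block at line")
  # corrupt header
  writeLines(c(lines[1], "{not json", lines[-(1:2)]), f)
  expect_error(load_fixture(f), "line 2")
  # wrong magic
  writeLines(c("#something-else", lines[-1]), f)
  expect_error(load_fixture(f), "magic")
})

test_that("metric CSVs are stable, ordered and full precision", {
  m <- data.frame(frame = 1:3, time_ns = c(0, 10, 20),
                  complex_ratio = c(1 / 3, 2 / 3, 1))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_metrics(m, f1)
  write_metrics(m, f2)
  expect_identical(readBin(f1, "raw", 1e6), readBin(f2, "raw", 1e6))
  back <- read.csv(f1)
  expect_identical(back$complex_ratio, m$complex_ratio)  # exact reparse
  expect_equal(names(back), names(m))
  expect_false(is.unsorted(back$time_ns))

  # empty series: header-only CSV
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_metrics(m[0, ], f3)
  expect_equal(readLines(f3), "frame,time_ns,complex_ratio")
})

test_that("molecule identity follows residue numbering with merge rules", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   50.000   50.000   50.000  90.00  90.00  90.00 P 1",
    "ATOM      1  C1  SUR A   1      10.000  10.000  10.000  1.00  0.00",
    "ATOM      2  C2  SUR A   2      12.000  10.000  10.000  1.00  0.00",
    "ATOM      3  CA  CM15A   3      20.000  10.000  10.000  1.00  0.00",
    "END"), f)
  # without a merge rule the two SUR residues are two molecules
  plain <- load_trajectory(f, species_map = sp_map)
  expect_equal(length(unique(plain$topology$particles$molecule)), 3)
  # with SUR declared multi-residue they merge into one molecule
  merged <- load_trajectory(f, species_map = sp_map, merge_species = "SUR")
  expect_equal(length(unique(merged$topology$particles$molecule)), 2)
  expect_equal(merged$topology$particles$molecule[1:2], c(1L, 1L))
})
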