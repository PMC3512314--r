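test_that("reader parses comments, directives and data rows", {
  path <- withr::local_tempfile(fileext = ".xvg")
  writeLines(c(
    "# a comment",
    "# spring_k: 400",
    "# units: reduced",
    "@    title \"Pull force\"",
    "@ s0 legend \"F_x\"",
    "@ s1 legend \"F_y\"",
    "@ s2 legend \"F_z\"",
    "0.0 1 2 3",
    "0.5 4 5 6",
    "1.0 7 8 9",
    "1.5 1 1 1",
    "2.0 2 2 2"
  ), path)
  tab <- read_pull_xvg(path, "force")
  expect_identical(dim(tab), c(5L, 4L))
  expect_identical(names(tab), c("time", "F_x", "F_y", "F_z"))
  expect_identical(attr(tab, "metadata")$spring_k, 400)
  expect_identical(attr(tab, "metadata")$units, "reduced")
})

test_that("duplicate time stamps keep the first occurrence with a warning", {
  path <- withr::local_tempfile(fileext = ".xvg")
  writeLines(c("0 1", "1 2", "1 99", "2 3"), path)
  expect_warning(tab <- read_pull_xvg(path, "force"), "duplicate")
  expect_identical(nrow(tab), 3L)
  expect_identical(tab[[2]], c(1, 2, 3))
})

test_that("ragged rows, comma decimals and empty files are rejected", {
  path <- withr::local_tempfile(fileext = ".xvg")
  writeLines(c("0 1 2", "1 2"), path)
  expect_error(read_pull_xvg(path, "force"), "ragged row at line 2")
  writeLines(c("0 1", "1 2,5"), path)
  expect_error(read_pull_xvg(path, "force"), "comma")
  writeLines(c("# only comments here"), path)
  expect_error(read_pull_xvg(path, "force"), "empty data")
})

test_that("a minimal trajectory writes exactly its data lines", {
  tr <- make_traj(time = c(0, 1), z = c(0, 1), x = c(0, 0.9), f = c(0.5, 0.6))
  path <- withr::local_tempfile(fileext = ".xvg")
  write_pull_xvg(tr, path, "force")
  lines <- readLines(path)
  data_lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "@")]
  expect_identical(length(data_lines), 2L)
  expect_true(any(grepl("units: reduced", lines)))
})

test_that("write/read roundtrip is the identity in every unit system", {
  for (units in c("reduced", "gromacs", "si")) {
    cfg <- tiny_well_config(units = units, n_replicas = 2L)
    set0 <- simulate_replicas(cfg)
    dir <- withr::local_tempdir()
    write_replica_set(set0, dir)
    set1 <- read_replica_set(dir)
    expect_identical(length(set1), 2L)
    for (i in 1:2) {
      a <- set0$trajectories[[i]]; b <- set1$trajectories[[i]]
      expect_equal(b$time, a$time, tolerance = 1e-14)
      expect_equal(unname(b$position), unname(a$position), tolerance = 1e-14)
      expect_equal(unname(b$force), unname(a$force), tolerance = 1e-14)
      expect_equal(unname(b$spring_end), unname(a$spring_end),
                   tolerance = 1e-14)
      expect_identical(b$units, units)
      expect_equal(b$spring_k, a$spring_k, tolerance = 1e-14)
    }
  }
})

test_that("pairing aligns time grids within tolerance and rejects beyond it", {
  cfg <- tiny_well_config(n_replicas = 1L)
  tr <- simulate_pull(cfg, 1L)
  dir <- withr::local_tempdir()
  write_pull_xvg(tr, file.path(dir, "f.xvg"), "force")
  write_pull_xvg(tr, file.path(dir, "x.xvg"), "position")
  ft <- read_pull_xvg(file.path(dir, "f.xvg"), "force")
  pt <- read_pull_xvg(file.path(dir, "x.xvg"), "position")

  # identical grids: paired untouched
  rs <- pair_replicas(list(ft), list(pt), tolerance = 1e-6)
  expect_identical(length(rs), 1L)
  expect_equal(rs$trajectories[[1]]$force[, 1], tr$force[, 1],
               tolerance = 1e-14)

  # offset by tolerance/2: paired, offset reported
  ft2 <- ft; ft2$time <- ft2$time + 5e-7
  expect_message(pair_replicas(list(ft2), list(pt), tolerance = 1e-6),
                 "max time offset")

  # offset by 10x tolerance: alignment error naming the first offending time
  ft3 <- ft; ft3$time <- ft3$time + 1e-5
  expect_error(pair_replicas(list(ft3), list(pt), tolerance = 1e-6),
               "beyond tolerance")
  expect_error(pair_replicas(list(ft, ft), list(pt)), "equal numbers")
})

test_that("gromacs <-> SI conversion is involutive and reduced refuses", {
  expect_equal(convert_quantity(convert_quantity(3.5, "force", "gromacs", "si"),
                                "force", "si", "gromacs"),
               3.5, tolerance = 1e-12)
  # 1 kJ/mol/nm is 1.66054e-12 N
  expect_equal(convert_quantity(1, "force", "gromacs", "si"), 1.66054e-12,
               tolerance = 1e-5)
  expect_error(convert_quantity(1, "force", "reduced", "si"), "reduced")

  cfg <- tiny_well_config(units = "gromacs", n_replicas = 1L)
  tr <- simulate_pull(cfg, 3L)
  back <- convert_trajectory(convert_trajectory(tr, "si"), "gromacs")
  expect_equal(back$force, tr$force, tolerance = 1e-12)
  expect_equal(back$spring_k, tr$spring_k, tolerance = 1e-12)
  expect_equal(back$time, tr$time, tolerance = 1e-12)
})
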