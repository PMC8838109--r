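test_that("cell volumes match closed forms for cubic, monoclinic and the triclinic oracle", {
  expect_equal(cell_volume(unit_cell(10, 10, 10)), 1000)
  expect_equal(cell_volume(unit_cell(5, 6, 7, beta = 100)),
               5 * 6 * 7 * sin(100 * pi / 180), tolerance = 1e-10)
  expect_equal(cell_volume(unit_cell(5, 6, 7, beta = 100)), 206.81, tolerance = 1e-4)
  # triclinic formula against the cell-matrix determinant oracle
  cl <- unit_cell(6.3, 7.1, 9.4, 82, 103, 95)
  expect_equal(cell_volume(cl), det(cell_matrix(cl)), tolerance = 1e-10)
})

test_that("CIF output round-trips through the reader", {
  cell <- gen_toy_cell(c(10.5, 11, 12, 90, 95, 90),
                       data.frame(element = c("O", "C"), x = c(0.1, 0.4),
                                  y = c(0.2, 0.5), z = c(0.3, 0.6)))
  tmp <- tempfile(fileext = ".cif")
  write_cif(cell, tmp)
  back <- read_structure(tmp)
  expect_equal(back$a, 10.5, tolerance = 1e-6)
  expect_equal(cell_volume(back), cell_volume(cell), tolerance = 1e-6)
  expect_equal(nrow(back$sites), 2)
  expect_setequal(back$sites$element, c("O", "C"))
  expect_equal(sort(back$sites$x), c(0.1, 0.4), tolerance = 1e-6)
})

test_that("symmetry operators expand to P1 with duplicate merging", {
  lines <- c("data_x",
             "_cell_length_a 8", "_cell_length_b 9", "_cell_length_c 10",
             "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
             "loop_", "_symmetry_equiv_pos_as_xyz", "'x, y, z'", "'-x, -y, -z'",
             "loop_", "_atom_site_label", "_atom_site_type_symbol",
             "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
             "C1 C 0.1 0.2 0.3")
  tmp <- tempfile(fileext = ".cif")
  writeLines(lines, tmp)
  cell <- read_structure(tmp)
  expect_equal(nrow(cell$sites), 2)  # inversion generates the second site
  # an atom on the inversion centre is merged back to one site
  lines2 <- sub("C1 C 0.1 0.2 0.3", "C1 C 0.0 0.0 0.0", lines)
  writeLines(lines2, tmp)
  expect_equal(nrow(read_structure(tmp)$sites), 1)
})

test_that("PDB CRYST1 records define the cell and coordinates become fractional", {
  pdb <- c(sprintf("%-6s%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1", "CRYST1", 10, 12, 14, 90, 90, 90),
           "ATOM      1  O1  MOL A   1       1.000   2.400   7.000  1.00  0.00           O",
           "ATOM      2  C1  MOL A   1       5.000   6.000   7.000  1.00  0.00           C",
           "END")
  tmp <- tempfile(fileext = ".pdb")
  writeLines(pdb, tmp)
  cell <- read_structure(tmp)
  expect_equal(c(cell$a, cell$b, cell$c), c(10, 12, 14))
  o <- cell$sites[cell$sites$element == "O", ]
  expect_equal(c(o$x, o$y, o$z), c(0.1, 0.2, 0.5), tolerance = 1e-6)
})

test_that("contacts resolve periodic minimum images with their shifts", {
  cell <- gen_toy_cell(c(10, 10, 10),
                       data.frame(element = "O", x = c(0, 0.28), y = 0, z = 0))
  cl <- contacts(cell, "O", "O", 3.2)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$dist_A, 2.80, tolerance = 1e-10)
  # pair across the cell boundary: 0.4 A through image (-1, 0, 0)
  wrap <- gen_toy_cell(c(10, 20, 20),
                       data.frame(element = "O", x = c(0.02, 0.98), y = 0, z = 0))
  cw <- contacts(wrap, "O", "O", 3.2)
  expect_equal(cw$dist_A, 0.4, tolerance = 1e-10)
  expect_equal(c(cw$shift_a, cw$shift_b, cw$shift_c), c(-1, 0, 0))
  # cutoff below every distance: empty result
  expect_equal(nrow(contacts(cell, "O", "O", 1.0)), 0)
  expect_message(contacts(cell, "N", "O", 3.2), "absent")
})

test_that("contact distances agree with a brute-force all-images oracle", {
  set.seed(17)
  cell <- gen_toy_cell(c(7, 8, 9, 85, 95, 100),
                       data.frame(element = rep("O", 6),
                                  x = runif(6), y = runif(6), z = runif(6)))
  cl <- contacts(cell, "O", "O", 4.0)
  s <- cell$sites
  for (r in seq_len(nrow(cl))) {
    ia <- match(cl$label_a[r], s$label); ib <- match(cl$label_b[r], s$label)
    d_oracle <- brute_min_image(cell,
                                c(s$x[ia], s$y[ia], s$z[ia]),
                                c(s$x[ib], s$y[ib], s$z[ib]))
    expect_equal(cl$dist_A[r], d_oracle, tolerance = 1e-10)
  }
  # completeness: every pair below cutoff by the oracle is reported
  n_oracle <- 0
  for (i in 1:5) for (j in (i + 1):6) {
    if (brute_min_image(cell, c(s$x[i], s$y[i], s$z[i]),
                        c(s$x[j], s$y[j], s$z[j])) <= 4.0) n_oracle <- n_oracle + 1
  }
  expect_equal(nrow(cl), n_oracle)
})

test_that("void fractions match the analytic sphere volume on a single-atom cell", {
  empty <- gen_toy_cell(c(10, 10, 10))
  expect_equal(void_fraction(empty, 0.6, 0.2)$fraction, 100)
  one <- gen_toy_cell(c(10, 10, 10), data.frame(element = "C", x = .5, y = .5, z = .5))
  v <- void_fraction(one, 0.6, 0.2)
  analytic <- 100 * (1000 - 4 / 3 * pi * (1.70 + 0.6)^3) / 1000
  expect_equal(v$fraction, analytic, tolerance = 0.005)
  # saturation: probe so large the excluded spheres tile the cell
  small <- gen_toy_cell(c(4, 4, 4), data.frame(element = "C", x = .5, y = .5, z = .5))
  expect_equal(void_fraction(small, 2.0, 0.4)$fraction, 0)
  expect_error(void_fraction(one, 0.6, 0.5), "coarse")
})

test_that("void fraction decreases with probe radius and converges with the grid", {
  cell <- gen_toy_cell(c(8, 8, 8),
                       data.frame(element = c("C", "O"), x = c(0.3, 0.7),
                                  y = c(0.3, 0.7), z = c(0.5, 0.5)))
  fr <- sapply(c(0.4, 0.6, 0.8, 1.0), function(p) void_fraction(cell, p, 0.2)$fraction)
  expect_true(all(diff(fr) <= 0))
  f1 <- void_fraction(cell, 0.6, 0.2)$fraction
  f2 <- void_fraction(cell, 0.6, 0.1)$fraction
  expect_lt(abs(f1 - f2), 0.2)
  # swappable radii: larger radii leave less void
  big <- vdw_radii("bondi"); big[] <- big + 0.3
  f3 <- void_fraction(cell, 0.6, 0.2, radii_set = big)
  expect_lt(f3$fraction, f1)
})
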