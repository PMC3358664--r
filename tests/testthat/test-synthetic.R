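test_that("generated structures match spec arithmetic and are reproducible", {
  spec <- synth_spec(2, 5, 4, seed = 31)
  s <- generate_structure(spec)
  expect_equal(unname(s$counts), c(1L, 2L, 10L, 40L))
  s2 <- generate_structure(spec)
  expect_identical(s$atoms, s2$atoms)
  s3 <- generate_structure(synth_spec(2, 5, 4, seed = 32))
  expect_false(identical(s$atoms$x, s3$atoms$x))
})

test_that("charge laws deliver their stated distributions", {
  sn <- generate_structure(synth_spec(2, 8, 5, charge_law = "neutral_residues",
                                      seed = 41))
  per_res <- tapply(sn$atoms$charge, paste(sn$atoms$chain, sn$atoms$resno),
                    sum)
  expect_true(all(abs(per_res) < 1e-12))

  sd <- generate_structure(synth_spec(1, 6, 2, charge_law = "unit_dipole",
                                      seed = 42))
  expect_true(all(sd$atoms$charge %in% c(0.5, -0.5)))
  expect_equal(sum(sd$atoms$charge), 0)
  expect_error(synth_spec(1, 6, 3, charge_law = "unit_dipole"),
               "atoms_per_residue == 2")

  su <- generate_structure(synth_spec(1, 10, 5, seed = 43))
  expect_true(all(abs(su$atoms$charge) <= 0.5))
})

test_that("vertices lie on the bounding sphere with guaranteed clearance", {
  s <- generate_structure(synth_spec(2, 10, 4, seed = 51))
  ctr <- s$center
  r_max <- sqrt(max((s$atoms$x - ctr[1])^2 + (s$atoms$y - ctr[2])^2 +
                      (s$atoms$z - ctr[3])^2))
  offset <- 2.0

  v1 <- generate_vertices(s, 1, offset = offset, seed = 1)
  expect_equal(sqrt(sum((v1$points[1, ] - ctr)^2)), r_max + offset,
               tolerance = 1e-12)

  v100 <- generate_vertices(s, 100, offset = offset, seed = 1)
  radii <- sqrt(rowSums(sweep(v100$points, 2, ctr)^2))
  expect_true(all(abs(radii - (r_max + offset)) < 1e-9))
  expect_equal(v100$center, ctr)

  # clearance: no vertex closer than offset/2 (construction gives >= offset)
  d2 <- outer(rowSums(v100$points^2),
              s$atoms$x^2 + s$atoms$y^2 + s$atoms$z^2, `+`) -
    2 * v100$points %*% t(cbind(s$atoms$x, s$atoms$y, s$atoms$z))
  expect_gte(sqrt(min(d2)), offset / 2)
})

test_that("the Fibonacci lattice spreads points more sparsely at lower counts", {
  s <- generate_structure(synth_spec(1, 5, 3, seed = 61))
  min_angle <- function(P) {
    v <- generate_vertices(s, P, seed = 61)
    u <- sweep(v$points, 2, s$center)
    u <- u / sqrt(rowSums(u^2))
    cosines <- tcrossprod(u)
    diag(cosines) <- -1
    acos(min(max(cosines), 1))
  }
  expect_gt(min_angle(100), min_angle(1000))
})

test_that("generated structures satisfy the structural invariants", {
  ens <- synth_ensemble(n = 4, P = 1, base_seed = 700)
  for (e in ens) {
    s <- e$structure
    expect_equal(sort(s$flat$atom_id), seq_len(nrow(s$atoms)))
    expect_equal(s$root$n_atoms, nrow(s$atoms))
    expect_equal(s$center, c(mean(s$atoms$x), mean(s$atoms$y),
                             mean(s$atoms$z)))
    expect_equal(sum(vapply(s$root$children, function(c) c$n_atoms, 0)),
                 nrow(s$atoms))
  }
})

test_that("spec validation rejects impossible geometries and counts", {
  expect_error(synth_spec(0, 5, 4))
  expect_error(synth_spec(2, 5, 4, residue_spacing = 0))
  expect_error(synth_spec(2, 5, 4, residue_extent = -1))
  expect_error(synth_spec(63, 5, 4))
})
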