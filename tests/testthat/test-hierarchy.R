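test_that("hierarchy groups atoms by chain and residue in appearance order", {
  atoms <- make_atoms(x = seq_len(12), y = 0, z = 0,
                      charge = rep(c(0.2, -0.1), 6),
                      chain = rep(c("A", "B"), each = 6),
                      resno = rep(rep(1:3, each = 2), 2))
  s <- build_hierarchy(atoms)
  expect_equal(unname(s$counts), c(1L, 2L, 6L, 12L))
  expect_equal(s$root$level, "complex")
  expect_length(s$root$children, 2)
  expect_equal(vapply(s$root$children, function(c) length(c$children), 0L),
               c(3L, 3L))
  expect_equal(s$root$children[[1]]$chain, "A")
  # every atom in exactly one residue
  expect_equal(sort(s$flat$atom_id), 1:12)
})

test_that("single atom yields a degenerate but valid hierarchy", {
  s <- build_hierarchy(make_atoms(1, 2, 3, charge = 0.4))
  expect_equal(unname(s$counts), c(1L, 1L, 1L, 1L))
  res <- s$root$children[[1]]$children[[1]]
  expect_equal(res$center, c(1, 2, 3))
  expect_equal(res$bounding_radius, 0)
  expect_error(build_hierarchy(make_atoms(1, 2, 3, charge = 0.4)[0, ]),
               "non-empty")
})

test_that("generator parameters fix the hierarchy census exactly", {
  # nucleosome-like shape: 1 complex, 10 strands, 1270 residues
  s <- generate_structure(synth_spec(10, 127, 4, seed = 2))
  expect_equal(unname(s$counts), c(1L, 10L, 1270L, 5080L))
})

test_that("approximate charge construction follows the stated formulas", {
  dipole <- make_atoms(c(0, 2), 0, 0, charge = c(1, -1))
  ac2 <- approximate_charges(dipole, order = 2)
  expect_equal(nrow(ac2), 2)
  expect_equal(ac2$charge, c(1, -1))
  expect_equal(ac2$x, c(0, 2))

  same <- make_atoms(c(0, 2), 0, 0, charge = c(1, 1))
  ac1 <- approximate_charges(same, order = 1)
  expect_equal(nrow(ac1), 1)
  expect_equal(ac1$charge, 2)
  expect_equal(ac1$x, 1)

  # |q|-weighted centroid of a neutral pair sits at the midpoint
  ac1n <- approximate_charges(dipole, order = 1)
  expect_equal(ac1n$charge, 0)
  expect_equal(ac1n$x, 1)

  # order 2 reduces to order 1 when all charges share one sign
  set.seed(4)
  pos <- make_atoms(runif(6), runif(6), runif(6), charge = runif(6, 0.1, 1))
  expect_equal(approximate_charges(pos, 2), approximate_charges(pos, 1))

  # all-zero charges: order 1 falls back to the geometric center
  zero <- make_atoms(c(0, 4), c(0, 0), c(0, 2), charge = c(0, 0))
  expect_equal(approximate_charges(zero, 1)$x, 2)
})

test_that("charge is conserved at every level and both orders", {
  ens <- synth_ensemble(n = 6, P = 1, base_seed = 300)
  for (e in ens) {
    walk <- function(comp) {
      for (o in c("1", "2")) {
        ac <- comp$approx_charges[[o]]
        expect_lt(abs(sum(ac$charge) - comp$total_charge),
                  1e-12 * max(1, abs(comp$total_charge)))
      }
      if (comp$level != "residue") lapply(comp$children, walk)
      invisible(NULL)
    }
    walk(e$structure$root)
  }
})

test_that("every member atom lies within the bounding radius of its component", {
  s <- generate_structure(synth_spec(3, 10, 5, seed = 17))
  walk <- function(comp) {
    kids <- comp$children
    if (comp$level == "residue") {
      d <- sqrt((kids$x - comp$center[1])^2 + (kids$y - comp$center[2])^2 +
                  (kids$z - comp$center[3])^2)
      expect_true(all(d <= comp$bounding_radius + 1e-12))
    } else {
      expect_gt(length(kids), 0)
      lapply(kids, walk)
    }
    invisible(NULL)
  }
  walk(s$root)
})

test_that("order-2 approximation error decays with probe distance", {
  # relative error at distance D measured as RMS over a fixed probe sphere,
  # so the comparison is not hostage to a single direction where the exact
  # Coulomb sum happens to cancel
  set.seed(23)
  dirs <- matrix(rnorm(3 * 16), 16, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  for (k in 1:50) {
    atoms <- make_atoms(runif(8, -1.8, 1.8), runif(8, -1.8, 1.8),
                        runif(8, -1.8, 1.8), charge = runif(8, -0.5, 0.5))
    ctr <- c(mean(atoms$x), mean(atoms$y), mean(atoms$z))
    ac <- approximate_charges(atoms, order = 2)
    coulomb <- function(src_xyz, src_q, probes) {
      vapply(seq_len(nrow(probes)), function(i) {
        sum(src_q / sqrt((probes[i, 1] - src_xyz[, 1])^2 +
                           (probes[i, 2] - src_xyz[, 2])^2 +
                           (probes[i, 3] - src_xyz[, 3])^2))
      }, 0)
    }
    err_at <- function(D) {
      probes <- sweep(D * dirs, 2, ctr, `+`)
      exact <- coulomb(cbind(atoms$x, atoms$y, atoms$z), atoms$charge, probes)
      approx <- coulomb(cbind(ac$x, ac$y, ac$z), ac$charge, probes)
      sqrt(mean((approx - exact)^2)) / sqrt(mean(exact^2))
    }
    D <- 40
    expect_lte(err_at(2 * D), err_at(D))
  }
})
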