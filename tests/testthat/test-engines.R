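test_that("exact engine reproduces the Coulomb limit on a single atom", {
  s <- build_hierarchy(make_atoms(0, 0, 0, charge = 1))
  v <- vertex_set(matrix(c(0, 0, 2), 1, 3), center = c(0, 0, 0.5))
  p <- alpb_params(eps_in = 80, eps_out = 80)
  res <- esp_exact(s, v, p)
  expect_equal(res$potentials, 0.00625, tolerance = 1e-14)
  expect_equal(res$kernel_calls, 1)
  expect_equal(unname(res$level_usage[["atom"]]), 1)
})

test_that("exact engine matches the independent brute-force double loop", {
  fx <- random_fixture(200, 50, seed = 101)
  s <- build_hierarchy(fx$atoms)
  v <- vertex_set(fx$pts, center = fx$center)
  res <- esp_exact(s, v)
  ora <- oracle_esp(fx$atoms, fx$pts, fx$center)
  expect_equal(res$potentials, ora, tolerance = 1e-10)
  expect_equal(res$kernel_calls, 200 * 50)
  expect_equal(res$total_potential, sum(res$potentials), tolerance = 1e-10)
})

test_that("coincident vertex and atom is a reported domain error", {
  s <- build_hierarchy(make_atoms(c(0, 3), 0, 0, charge = c(0.5, -0.5)))
  v <- vertex_set(matrix(c(3, 0, 0), 1, 3), center = s$center)
  expect_error(esp_exact(s, v), "vertex 1 coincides with atom 2")
  expect_error(esp_hcp(s, v, thresholds = hcp_thresholds(Inf, Inf, Inf)),
               "vertex 1 coincides with atom")
})

test_that("HCP with infinite thresholds is the exact engine", {
  fx <- random_fixture(200, 50, seed = 101, apr = 4L)
  s <- build_hierarchy(fx$atoms)
  v <- vertex_set(fx$pts, center = fx$center)
  ex <- esp_exact(s, v)
  hc <- esp_hcp(s, v, thresholds = hcp_thresholds(Inf, Inf, Inf))
  expect_equal(hc$potentials, ex$potentials, tolerance = 1e-12)
  expect_equal(hc$kernel_calls, ex$kernel_calls)
  expect_equal(unname(hc$level_usage[c("complex", "strand", "residue")]),
               c(0, 0, 0))
  expect_equal(unname(hc$level_usage[["atom"]]), 200 * 50)
})

test_that("single-atom residues approximated at threshold zero stay lossless", {
  set.seed(55)
  atoms <- make_atoms(runif(10, -5, 5), runif(10, -5, 5), runif(10, -5, 5),
                      charge = runif(10, -0.5, 0.5), resno = 1:10)
  s <- build_hierarchy(atoms)
  v <- vertex_set(matrix(c(30, 0, 0, 0, 30, 0), 2, 3, byrow = TRUE),
                  center = s$center)
  ex <- esp_exact(s, v)
  hc <- esp_hcp(s, v, thresholds = hcp_thresholds(residue = 0, strand = Inf),
                order = 2)
  expect_equal(hc$potentials, ex$potentials, tolerance = 1e-12)
  expect_equal(unname(hc$level_usage[["residue"]]), 2 * 10)
})

test_that("far dipole residues contribute through their approximate charges", {
  atoms <- make_atoms(x = c(0, 1, 5, 6), y = 0, z = 0,
                      charge = c(0.5, -0.5, 0.5, -0.5),
                      resno = c(1L, 1L, 2L, 2L))
  s <- build_hierarchy(atoms)
  v <- vertex_set(matrix(c(100, 0, 0), 1, 3), center = s$center)
  hc <- esp_hcp(s, v, thresholds = hcp_thresholds(residue = 10, strand = Inf))
  # hand evaluation: 4 approximate point charges via the scalar kernel
  ac <- do.call(rbind, lapply(s$root$children[[1]]$children,
                              function(r) r$approx_charges[["2"]]))
  r <- sqrt(sum((c(100, 0, 0) - s$center)^2))
  hand <- alpb_potential_batch(ac$charge, 100 - ac$x, rep(r, nrow(ac)))
  expect_equal(hc$potentials, hand, tolerance = 1e-12)
  expect_equal(hc$kernel_calls, 4)
  expect_equal(unname(hc$level_usage[["residue"]]), 2)
})

test_that("finite thresholds never increase work beyond the exact count", {
  ens <- synth_ensemble(n = 5, P = 40, base_seed = 900)
  for (e in ens) {
    n <- nrow(e$structure$atoms) * 40
    for (ord in c(1, 2)) {
      hc <- esp_hcp(e$structure, e$vertices, order = ord)
      expect_lte(hc$kernel_calls, n)
      expect_gte(hc$kernel_calls, 40)
    }
  }
})

test_that("potentials are invariant under rigid motion of the whole scene", {
  s <- generate_structure(synth_spec(2, 15, 4, seed = 77))
  v <- generate_vertices(s, 60, seed = 77)
  ref <- esp_hcp(s, v)

  th <- 1.1
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  tr <- c(-8.25, 14.5, 101)
  a2 <- s$atoms
  xyz <- cbind(a2$x, a2$y, a2$z) %*% t(R)
  a2$x <- xyz[, 1] + tr[1]; a2$y <- xyz[, 2] + tr[2]; a2$z <- xyz[, 3] + tr[3]
  s2 <- build_hierarchy(a2)
  v2 <- vertex_set(sweep(v$points %*% t(R), 2, tr, `+`),
                   center = as.numeric(R %*% v$center) + tr)
  moved <- esp_hcp(s2, v2)
  scale <- sqrt(mean(ref$potentials^2))
  expect_lt(max(abs(moved$potentials - ref$potentials)) / scale, 1e-9)
  expect_equal(moved$kernel_calls, ref$kernel_calls)
})

test_that("scaling table reports exact N*P work and consistent HCP counts", {
  tab <- scaling_experiment(c(125, 250), P = 10, seed = 5)
  expect_equal(tab$n_atoms, c(125, 250))
  expect_equal(tab$kernel_calls_exact, c(1250, 2500))
  expect_true(all(tab$kernel_calls_hcp <= tab$kernel_calls_exact))

  inf_tab <- scaling_experiment(125, P = 10,
                                thresholds = hcp_thresholds(Inf, Inf, Inf),
                                seed = 5)
  expect_equal(inf_tab$kernel_calls_hcp, inf_tab$kernel_calls_exact)
})
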