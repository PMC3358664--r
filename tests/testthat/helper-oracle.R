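# Independent brute-force oracle for the ALPB surface potential, written as a
# plain double loop over vertices and atoms, deliberately separate from the
# package's engine code paths.

oracle_kernel <- function(q, d, r, eps_in = 1, eps_out = 80,
                          alpha = 0.580127, unit_factor = 1) {
  beta <- eps_in / eps_out
  unit_factor * (q / eps_in) / (1 + alpha * beta) *
    ((1 + alpha) / d - alpha * (1 - beta) / r)
}

oracle_esp <- function(atoms, pts, center, eps_in = 1, eps_out = 80,
                       alpha = 0.580127, unit_factor = 1) {
  out <- numeric(nrow(pts))
  for (v in seq_len(nrow(pts))) {
    r <- sqrt(sum((pts[v, ] - center)^2))
    acc <- 0
    for (a in seq_len(nrow(atoms))) {
      d <- sqrt((pts[v, 1] - atoms$x[a])^2 + (pts[v, 2] - atoms$y[a])^2 +
                  (pts[v, 3] - atoms$z[a])^2)
      acc <- acc + oracle_kernel(atoms$charge[a], d, r, eps_in, eps_out,
                                 alpha, unit_factor)
    }
    out[v] <- acc
  }
  out
}

make_atoms <- function(x, y, z, charge, chain = "A", resno = 1L,
                       name = "X", resname = "RES", radius = 1.5) {
  n <- length(x)
  data.frame(serial = seq_len(n), name = name, resname = resname,
             chain = chain, resno = as.integer(resno),
             x = x, y = y, z = z, charge = charge, radius = radius,
             stringsAsFactors = FALSE)
}

# Atoms uniform in a cube, one residue per `apr` consecutive atoms, vertices
# on a sphere well outside the cube.
random_fixture <- function(n_atoms, n_vertices, seed, apr = 5L,
                           box = 20, vertex_radius = NULL) {
  set.seed(seed)
  atoms <- make_atoms(runif(n_atoms, -box, box), runif(n_atoms, -box, box),
                      runif(n_atoms, -box, box), runif(n_atoms, -0.5, 0.5),
                      resno = rep(seq_len(ceiling(n_atoms / apr)),
                                  each = apr)[seq_len(n_atoms)])
  ctr <- c(mean(atoms$x), mean(atoms$y), mean(atoms$z))
  if (is.null(vertex_radius)) vertex_radius <- box * sqrt(3) + 5
  u <- matrix(rnorm(3 * n_vertices), n_vertices, 3)
  u <- u / sqrt(rowSums(u^2))
  pts <- sweep(u * vertex_radius, 2, ctr, `+`)
  list(atoms = atoms, pts = pts, center = ctr)
}
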