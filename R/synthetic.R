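#' Specification for a synthetic hierarchical structure
#'
#' Describes a random multi-strand structure: each strand backbone is an
#' independent 3-D random walk with step `residue_spacing`, each residue's
#' atoms are placed uniformly in a ball of radius `residue_extent` around its
#' backbone point, and charges follow `charge_law`:
#' \describe{
#'   \item{`uniform`}{independent uniform(-0.5, 0.5) per atom.}
#'   \item{`neutral_residues`}{uniform draws shifted so every residue's total
#'     charge is exactly 0.}
#'   \item{`unit_dipole`}{two atoms per residue carrying +0.5 and -0.5
#'     (requires `atoms_per_residue == 2`).}
#' }
#' Strand walk origins are placed uniformly in a ball of radius
#' `strand_spread`, whose default (0 for one strand, otherwise
#' `1.5 * residue_spacing * sqrt(residues_per_strand) * n_strands^(1/3)`)
#' scales like the radius of gyration of the walks times the cube root of the
#' strand count, so multi-strand structures occupy space the way packed
#' complexes do rather than collapsing onto a single origin.
#'
#' @param n_strands number of strands (chains), >= 1 (at most 62, the number
#'   of distinct single-character chain ids).
#' @param residues_per_strand residues per strand, >= 1.
#' @param atoms_per_residue atoms per residue, >= 1.
#' @param residue_spacing backbone step, Angstrom (default 3.8, the
#'   C-alpha - C-alpha distance).
#' @param residue_extent radius of the atom placement ball, Angstrom
#'   (default 1.8).
#' @param charge_law one of `"uniform"`, `"neutral_residues"`,
#'   `"unit_dipole"`.
#' @param strand_spread radius of the strand-origin ball, Angstrom; `NULL`
#'   for the default above.
#' @param seed integer RNG seed; identical specs generate identical
#'   structures.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_strands, residues_per_strand, atoms_per_residue,
                       residue_spacing = 3.8, residue_extent = 1.8,
                       charge_law = c("uniform", "neutral_residues",
                                      "unit_dipole"),
                       strand_spread = NULL, seed = 0) {
  charge_law <- match.arg(charge_law)
  stopifnot(n_strands >= 1, n_strands <= 62, residues_per_strand >= 1,
            atoms_per_residue >= 1, residue_spacing > 0, residue_extent >= 0)
  if (charge_law == "unit_dipole" && atoms_per_residue != 2)
    stop("charge_law 'unit_dipole' requires atoms_per_residue == 2")
  if (is.null(strand_spread)) {
    strand_spread <- if (n_strands == 1) 0
    else 1.5 * residue_spacing * sqrt(residues_per_strand) * n_strands^(1 / 3)
  }
  stopifnot(strand_spread >= 0)
  structure(list(n_strands = as.integer(n_strands),
                 residues_per_strand = as.integer(residues_per_strand),
                 atoms_per_residue = as.integer(atoms_per_residue),
                 residue_spacing = residue_spacing,
                 residue_extent = residue_extent,
                 charge_law = charge_law,
                 strand_spread = strand_spread,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

chain_id_pool <- c(LETTERS, letters, 0:9)

# n uniform points in a ball of given radius
runif_ball <- function(n, radius) {
  if (n == 0) return(matrix(0, 0, 3))
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  u * (radius * runif(n)^(1 / 3))
}

#' Generate a synthetic hierarchical structure
#'
#' Builds atom coordinates and charges according to a [synth_spec()] and
#' returns the fully built hierarchy. Deterministic for a fixed spec (the
#' caller's RNG state is left untouched).
#'
#' @param spec a [synth_spec()].
#' @return An `esp_structure`; the hierarchy census matches the spec counts
#'   exactly.
#' @examples
#' s <- generate_structure(synth_spec(2, 5, 4, seed = 1))
#' s$counts
#' @export
generate_structure <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    ns <- spec$n_strands
    rps <- spec$residues_per_strand
    apr <- spec$atoms_per_residue
    nres <- ns * rps
    n <- nres * apr

    origins <- runif_ball(ns, spec$strand_spread)
    steps <- matrix(rnorm(3 * nres), nres, 3)
    steps <- steps / sqrt(rowSums(steps^2)) * spec$residue_spacing
    backbone <- matrix(0, nres, 3)
    k <- 1L
    for (s in seq_len(ns)) {
      pos <- origins[s, ]
      for (r in seq_len(rps)) {
        pos <- pos + steps[k, ]
        backbone[k, ] <- pos
        k <- k + 1L
      }
    }

    offsets <- runif_ball(n, spec$residue_extent)
    res_of_atom <- rep(seq_len(nres), each = apr)
    xyz <- backbone[res_of_atom, , drop = FALSE] + offsets

    q <- switch(spec$charge_law,
      uniform = runif(n, -0.5, 0.5),
      neutral_residues = {
        q0 <- runif(n, -0.5, 0.5)
        q0 - rep(rowsum_vec(q0, res_of_atom, nres) / apr, each = apr)
      },
      unit_dipole = rep(c(0.5, -0.5), nres)
    )

    strand_of_atom <- rep(seq_len(ns), each = rps * apr)
    atoms <- data.frame(
      serial = seq_len(n),
      name = paste0("X", rep(seq_len(apr), nres)),
      resname = "SYN",
      chain = chain_id_pool[strand_of_atom],
      resno = rep(rep(seq_len(rps), each = apr), ns),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      charge = q,
      radius = 1.5,
      stringsAsFactors = FALSE
    )
    build_hierarchy(atoms)
  })
}

#' Generate surface vertices on a bounding sphere
#'
#' Places `P` points by a Fibonacci spiral lattice on the sphere of radius
#' `R_max + offset` centered at the structure center, where `R_max` is the
#' largest atom distance from the center. The lattice is rotated by a random
#' (seed-determined) rotation so different seeds give different but equally
#' well-spread vertex sets. Every vertex is therefore at least `offset` away
#' from every atom, guaranteeing strictly positive kernel distances; this is
#' asserted before returning.
#'
#' @param structure an `esp_structure`.
#' @param P number of vertices, >= 1.
#' @param offset radial clearance beyond the outermost atom, Angstrom.
#' @param seed integer seed for the lattice rotation.
#' @return A [vertex_set()] with `center` set to the structure center.
#' @export
generate_vertices <- function(structure, P, offset = 2.0, seed = 0) {
  stopifnot(inherits(structure, "esp_structure"), P >= 1, offset > 0)
  ctr <- structure$center
  a <- structure$atoms
  r_max <- sqrt(max((a$x - ctr[1])^2 + (a$y - ctr[2])^2 + (a$z - ctr[3])^2))
  radius <- r_max + offset

  i <- seq_len(P) - 0.5
  z <- 1 - 2 * i / P
  phi <- (seq_len(P) - 1) * pi * (3 - sqrt(5))   # golden angle
  s <- sqrt(pmax(0, 1 - z^2))
  u <- cbind(s * cos(phi), s * sin(phi), z)

  rot <- with_seed(seed, {
    qr_m <- qr(matrix(rnorm(9), 3, 3))
    Q <- qr.Q(qr_m)
    Q * sign(diag(qr.R(qr_m)))[col(Q)]  # unique Q; det may be -1, fine for a frame
  })
  pts <- sweep(u %*% t(rot) * radius, 2, ctr, `+`)

  d2min <- min_vertex_atom_dist2(pts, cbind(a$x, a$y, a$z))
  if (sqrt(d2min) < offset / 2)
    stop("generated vertex closer than offset/2 to an atom; widen offset")
  vertex_set(pts, center = ctr)
}

min_vertex_atom_dist2 <- function(pts, axyz) {
  # block-wise to bound memory on large fixtures
  m <- nrow(pts)
  best <- Inf
  step <- max(1L, as.integer(2e6 / max(1, nrow(axyz))))
  for (start in seq(1L, m, by = step)) {
    blk <- pts[start:min(m, start + step - 1L), , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rowSums(axyz^2), `+`) - 2 * blk %*% t(axyz)
    best <- min(best, min(d2))
  }
  max(best, 0)
}

#' Standard synthetic evaluation ensemble
#'
#' A fixed family of structure/vertex pairs spanning strand counts 2-4,
#' residue counts 20-35 per strand, 3-5 atoms per residue, and both the
#' `uniform` and `neutral_residues` charge laws. Used for distributional
#' claims (error controllability, work reduction) that no single structure
#' can support.
#'
#' @param n ensemble size.
#' @param P vertices per structure.
#' @param base_seed integer; member k uses seed `base_seed + k`.
#' @return A list of `list(structure =, vertices =)` pairs.
#' @export
synth_ensemble <- function(n = 20, P = 80, base_seed = 100) {
  lapply(seq_len(n), function(k) {
    spec <- synth_spec(
      n_strands = 2L + (k %% 3L),
      residues_per_strand = 20L + 5L * (k %% 4L),
      atoms_per_residue = 3L + (k %% 3L),
      charge_law = if (k %% 2L == 0L) "uniform" else "neutral_residues",
      seed = base_seed + k)
    s <- generate_structure(spec)
    list(structure = s,
         vertices = generate_vertices(s, P = P, seed = base_seed + k))
  })
}
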