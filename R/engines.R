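#' HCP distance thresholds
#'
#' One threshold per approximable level. During the top-down traversal a
#' component's approximate charges are used for a vertex when the
#' vertex-to-component-center distance exceeds the threshold of the
#' component's level; otherwise the traversal descends into its children
#' (atoms are always evaluated exactly). Defaults follow the standard
#' parameterization: 10 Angstrom at the residue level (the first
#' approximation applied walking up from atoms), 70 Angstrom at the strand
#' level, and `Inf` at the complex level (a single-complex structure is never
#' approximated whole).
#'
#' @param residue residue-level threshold, Angstrom (>= 0, `Inf` allowed).
#' @param strand strand-level threshold, Angstrom.
#' @param complex complex-level threshold, Angstrom.
#' @return An object of class `hcp_thresholds`.
#' @export
hcp_thresholds <- function(residue = 10, strand = 70, complex = Inf) {
  for (v in list(residue, strand, complex))
    stopifnot(is.numeric(v), length(v) == 1, !is.na(v), v >= 0)
  structure(list(complex = complex, strand = strand, residue = residue),
            class = "hcp_thresholds")
}

#' @export
print.hcp_thresholds <- function(x, ...) {
  cat(sprintf("HCP thresholds (A): residue %g, strand %g, complex %g\n",
              x$residue, x$strand, x$complex))
  invisible(x)
}

new_esp_result <- function(potentials, kernel_calls, level_usage) {
  structure(list(potentials = as.numeric(potentials),
                 kernel_calls = as.numeric(kernel_calls),
                 level_usage = level_usage,
                 total_potential = sum(potentials)),
            class = "esp_result")
}

#' @export
print.esp_result <- function(x, ...) {
  cat(sprintf("ESP result: %d vertices, total potential %.6g\n",
              length(x$potentials), x$total_potential))
  cat(sprintf("  kernel calls: %.0f\n", x$kernel_calls))
  u <- x$level_usage
  cat(sprintf("  level usage: complex %.0f, strand %.0f, residue %.0f, atom %.0f\n",
              u[["complex"]], u[["strand"]], u[["residue"]], u[["atom"]]))
  invisible(x)
}

engine_inputs <- function(structure, vertices, params, precision) {
  stopifnot(inherits(structure, "esp_structure"),
            inherits(vertices, "vertex_set"),
            inherits(params, "alpb_params"))
  if (nrow(vertices$points) == 0) stop("empty vertex set")
  precision <- match.arg(precision, c("double", "single"))
  list(center = vertices$center %||% structure$center,
       single = identical(precision, "single"))
}

#' Exact all-atom ESP evaluation
#'
#' Sums the single-charge ALPB potential over every atom for every vertex:
#' O(NP) work, `N * P` kernel evaluations, atoms visited in input file order.
#' This is the reference the HCP approximation is measured against.
#'
#' @param structure an `esp_structure` from [build_hierarchy()].
#' @param vertices a [vertex_set()].
#' @param params an [alpb_params()] object.
#' @param precision `"double"` (default) or `"single"`; single precision
#'   rounds every kernel evaluation and the accumulation to 32-bit floats.
#' @return An object of class `esp_result`: per-vertex `potentials`,
#'   `kernel_calls`, per-level `level_usage`, and `total_potential` (the
#'   reduce-sum over vertices).
#' @export
esp_exact <- function(structure, vertices, params = alpb_params(),
                      precision = c("double", "single")) {
  ei <- engine_inputs(structure, vertices, params, precision)
  a <- structure$atoms
  res <- cpp_esp_exact(cbind(a$x, a$y, a$z), a$charge, vertices$points,
                       ei$center, unclass(params), ei$single)
  n <- nrow(a) * nrow(vertices$points)
  new_esp_result(res$potentials, res$kernel_calls,
                 c(complex = 0, strand = 0, residue = 0, atom = n))
}

#' Multi-scale ESP evaluation with hierarchical charge partitioning
#'
#' Top-down traversal per vertex: starting at the complex root, a component
#' whose center lies farther from the vertex than its level's threshold
#' contributes through its precomputed approximate point charges; otherwise
#' the traversal descends, down to exact atoms. Every single-charge kernel
#' evaluation is counted, and the per-level usage histogram records how often
#' each approximation level supplied charges. Traversal order is fixed
#' (strands and residues in first-appearance order, atoms in file order), so
#' results are reproducible bit-for-bit for a given platform and precision.
#'
#' @inheritParams esp_exact
#' @param thresholds an [hcp_thresholds()] object.
#' @param order approximation order passed to the precomputed charges: 1
#'   (monopole) or 2 (split positive/negative centroids, the default).
#' @return An `esp_result`; see [esp_exact()].
#' @export
esp_hcp <- function(structure, vertices, params = alpb_params(),
                    thresholds = hcp_thresholds(), order = 2,
                    precision = c("double", "single")) {
  ei <- engine_inputs(structure, vertices, params, precision)
  stopifnot(inherits(thresholds, "hcp_thresholds"), order %in% c(1, 2))
  f <- structure$flat
  ac <- f$ac[[as.character(order)]]
  res <- cpp_esp_hcp(f$axyz, f$aq, f$atom_id, f$res_ptr, f$res_center,
                     f$str_ptr, f$str_center, f$cplx_center,
                     ac$res$ac, ac$res$ptr, ac$str$ac, ac$str$ptr, ac$cplx$ac,
                     vertices$points, ei$center,
                     thresholds$complex, thresholds$strand, thresholds$residue,
                     unclass(params), ei$single)
  new_esp_result(res$potentials, res$kernel_calls, res$level_usage)
}

#' Kernel-call scaling experiment
#'
#' For each requested atom count, generates a spread-out synthetic structure
#' whose strand count grows with size (see [scaling_spec()]), evaluates both
#' engines on the same vertex set, and tabulates the kernel-evaluation
#' counts. The exact engine performs exactly `N * P` evaluations; the HCP
#' engine's count grows sub-linearly in N once far-field approximation
#' applies.
#'
#' @param structure_sizes increasing vector of target atom counts; each is
#'   rounded up to the generator's granularity (125 atoms per strand).
#' @param P number of surface vertices.
#' @param params an [alpb_params()] object.
#' @param thresholds an [hcp_thresholds()] object.
#' @param order approximation order.
#' @param seed integer; the structure for size N uses seed `seed + N`.
#' @return A `data.frame` with columns `n_atoms`, `kernel_calls_exact`,
#'   `kernel_calls_hcp`.
#' @export
scaling_experiment <- function(structure_sizes, P = 100, params = alpb_params(),
                               thresholds = hcp_thresholds(), order = 2,
                               seed = 0) {
  stopifnot(length(structure_sizes) >= 1, all(diff(structure_sizes) > 0))
  rows <- lapply(structure_sizes, function(N) {
    spec <- scaling_spec(N, seed = seed + N)
    s <- generate_structure(spec)
    v <- generate_vertices(s, P = P, seed = seed + N)
    ex <- esp_exact(s, v, params)
    hc <- esp_hcp(s, v, params, thresholds, order)
    data.frame(n_atoms = nrow(s$atoms),
               kernel_calls_exact = ex$kernel_calls,
               kernel_calls_hcp = hc$kernel_calls)
  })
  do.call(rbind, rows)
}

#' Synthetic spec used by the scaling experiment
#'
#' Fixes the fixture shape for [scaling_experiment()]: 5 atoms per residue,
#' 25 residues per strand (125 atoms per strand), with the strand count — and
#' through the default strand spread, the spatial extent — growing with N.
#' Sub-linear kernel-call growth is an asymptotic far-field property; it is
#' only observable when the structure grows in space as well as in atom
#' count, as real multi-chain complexes do.
#'
#' @param n_atoms target atom count (rounded up to a multiple of 125).
#' @param seed generator seed.
#' @return A [synth_spec()].
#' @export
scaling_spec <- function(n_atoms, seed = 0) {
  n_strands <- max(1L, as.integer(ceiling(n_atoms / 125)))
  synth_spec(n_strands = n_strands, residues_per_strand = 25,
             atoms_per_residue = 5, charge_law = "uniform", seed = seed)
}
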