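#' Approximate a set of atomic charges by one or two point charges
#'
#' Order 1 replaces the atoms by a single signed monopole: the total charge
#' placed at the absolute-charge-weighted centroid (geometric center when all
#' charges are zero). Order 2 keeps the leading dipole structure by splitting
#' the atoms into positive and negative subsets and placing each subset's
#' total at its charge-weighted centroid; a side with zero total is omitted,
#' so order 2 reduces to order 1 when all charges share one sign. Both orders
#' conserve the total charge exactly.
#'
#' @param atoms atom `data.frame` (columns `x`, `y`, `z`, `charge`).
#' @param order 1 (monopole) or 2 (split positive/negative centroids).
#' @return A `data.frame` with columns `x`, `y`, `z`, `charge`; 1 row for
#'   order 1, 1 or 2 rows for order 2 (0 rows only for an all-zero charge
#'   set at order 2).
#' @export
approximate_charges <- function(atoms, order = 2) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0, order %in% c(1, 2))
  g <- rep(1L, nrow(atoms))
  ac <- approx_charges_grouped(atoms$x, atoms$y, atoms$z, atoms$charge, g, 1L,
                               order,
                               centers = matrix(c(mean(atoms$x), mean(atoms$y),
                                                  mean(atoms$z)), 1, 3))
  out <- as.data.frame(ac$ac)
  names(out) <- c("x", "y", "z", "charge")
  out
}

# Vectorized approximate-charge construction for many components at once.
# g must be sorted ascending 1..ngroups; centers are the per-group geometric
# centers used as the zero-total-charge fallback of order 1.
approx_charges_grouped <- function(x, y, z, q, g, ngroups, order, centers) {
  if (order == 1) {
    qtot <- rowsum_vec(q, g, ngroups)
    w <- abs(q)
    wtot <- rowsum_vec(w, g, ngroups)
    cx <- ifelse(wtot > 0, rowsum_vec(w * x, g, ngroups) / wtot, centers[, 1])
    cy <- ifelse(wtot > 0, rowsum_vec(w * y, g, ngroups) / wtot, centers[, 2])
    cz <- ifelse(wtot > 0, rowsum_vec(w * z, g, ngroups) / wtot, centers[, 3])
    ac <- cbind(cx, cy, cz, qtot)
    colnames(ac) <- NULL
    return(list(ac = ac, ptr = 0:ngroups))
  }
  qp <- pmax(q, 0)
  qn <- pmin(q, 0)
  Qp <- rowsum_vec(qp, g, ngroups)
  Qn <- rowsum_vec(qn, g, ngroups)
  px <- ifelse(Qp > 0, rowsum_vec(qp * x, g, ngroups) / Qp, 0)
  py <- ifelse(Qp > 0, rowsum_vec(qp * y, g, ngroups) / Qp, 0)
  pz <- ifelse(Qp > 0, rowsum_vec(qp * z, g, ngroups) / Qp, 0)
  nx <- ifelse(Qn < 0, rowsum_vec(qn * x, g, ngroups) / Qn, 0)
  ny <- ifelse(Qn < 0, rowsum_vec(qn * y, g, ngroups) / Qn, 0)
  nz <- ifelse(Qn < 0, rowsum_vec(qn * z, g, ngroups) / Qn, 0)
  has_p <- Qp > 0
  has_n <- Qn < 0
  counts <- as.integer(has_p) + as.integer(has_n)
  ptr <- c(0L, cumsum(counts))
  n_ac <- ptr[ngroups + 1L]
  ac <- matrix(0, n_ac, 4)
  row <- 1L
  for (i in seq_len(ngroups)) {
    if (has_p[i]) {
      ac[row, ] <- c(px[i], py[i], pz[i], Qp[i])
      row <- row + 1L
    }
    if (has_n[i]) {
      ac[row, ] <- c(nx[i], ny[i], nz[i], Qn[i])
      row <- row + 1L
    }
  }
  list(ac = ac, ptr = as.integer(ptr))
}

rowsum_vec <- function(v, g, ngroups) {
  out <- numeric(ngroups)
  s <- rowsum(v, g)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Build the 4-level hierarchy (complex > strand > residue > atom)
#'
#' Groups atoms into residues by (chain id, residue number) and residues into
#' strands by chain id, both in order of first appearance, under a single
#' complex root. For every component the geometric center (unweighted mean of
#' member atom positions), bounding radius (max member-atom distance from the
#' center), total charge, and approximate point charges at both supported
#' orders are precomputed.
#'
#' @param atoms atom `data.frame` as returned by [read_pqr()].
#' @return An object of class `esp_structure` with elements `atoms` (the
#'   input table), `center` (mean atom position), `root` (the nested
#'   `Component` tree), `counts` (hierarchy census), and internal flattened
#'   arrays used by the evaluation engines.
#' @examples
#' a <- data.frame(serial = 1:2, name = "X", resname = "RES", chain = "A",
#'                 resno = 1L, x = c(0, 2), y = 0, z = 0,
#'                 charge = c(1, -1), radius = 1.5)
#' s <- build_hierarchy(a)
#' s$counts
#' @export
build_hierarchy <- function(atoms) {
  if (!is.data.frame(atoms) || nrow(atoms) == 0)
    stop("atoms must be a non-empty data.frame")
  need <- c("chain", "resno", "x", "y", "z", "charge")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)), all(is.finite(atoms$charge)))
  n <- nrow(atoms)

  chain_levels <- unique(atoms$chain)
  s_raw <- match(atoms$chain, chain_levels)
  rkey <- paste(s_raw, atoms$resno, sep = "\r")
  rkey_levels <- unique(rkey)
  r_raw <- match(rkey, rkey_levels)
  rfirst <- match(rkey_levels, rkey)           # first atom of each residue
  r_strand_raw <- s_raw[rfirst]
  r_rank_perm <- order(r_strand_raw, rfirst)   # residues by strand, then appearance
  r_pos <- integer(length(rkey_levels))
  r_pos[r_rank_perm] <- seq_along(rkey_levels)
  res_of_atom <- r_pos[r_raw]

  ord <- order(res_of_atom, seq_len(n))        # stable: file order within residue
  ga <- atoms[ord, , drop = FALSE]
  g_res <- res_of_atom[ord]
  nres <- length(rkey_levels)
  nstr <- length(chain_levels)

  res_sizes <- tabulate(g_res, nbins = nres)
  res_ptr <- c(0L, cumsum(res_sizes))
  strand_of_res <- r_strand_raw[r_rank_perm]   # nondecreasing
  str_sizes <- tabulate(strand_of_res, nbins = nstr)
  str_ptr <- c(0L, cumsum(str_sizes))

  axyz <- cbind(ga$x, ga$y, ga$z)
  aq <- ga$charge
  res_center <- cbind(rowsum_vec(ga$x, g_res, nres),
                      rowsum_vec(ga$y, g_res, nres),
                      rowsum_vec(ga$z, g_res, nres)) / res_sizes
  g_str <- strand_of_res[g_res]
  str_center <- cbind(rowsum_vec(ga$x, g_str, nstr),
                      rowsum_vec(ga$y, g_str, nstr),
                      rowsum_vec(ga$z, g_str, nstr)) /
    tabulate(g_str, nbins = nstr)
  center <- c(mean(ga$x), mean(ga$y), mean(ga$z))

  ac <- lapply(c(1, 2), function(o) {
    list(res = approx_charges_grouped(ga$x, ga$y, ga$z, aq, g_res, nres, o, res_center),
         str = approx_charges_grouped(ga$x, ga$y, ga$z, aq, g_str, nstr, o, str_center),
         cplx = approx_charges_grouped(ga$x, ga$y, ga$z, aq, rep(1L, n), 1L, o,
                                       matrix(center, 1, 3)))
  })
  names(ac) <- c("1", "2")

  flat <- list(axyz = axyz, aq = aq, atom_id = as.integer(ord),
               res_ptr = as.integer(res_ptr), res_center = res_center,
               str_ptr = as.integer(str_ptr), str_center = str_center,
               cplx_center = center, ac = ac)

  root <- build_component_tree(ga, g_res, g_str, res_ptr, str_ptr, res_center,
                               str_center, center, flat, chain_levels)

  structure(list(atoms = atoms, center = center, root = root,
                 counts = c(complexes = 1L, strands = nstr, residues = nres,
                            atoms = n),
                 flat = flat),
            class = "esp_structure")
}

bounding_radius_of <- function(xyz, center) {
  if (nrow(xyz) == 0) return(0)
  sqrt(max(rowSums(sweep(xyz, 2, center)^2)))
}

component <- function(level, children, member_xyz, member_q, center, ac1, ac2) {
  structure(list(level = level, children = children, center = as.numeric(center),
                 bounding_radius = bounding_radius_of(member_xyz, center),
                 total_charge = sum(member_q),
                 n_atoms = nrow(member_xyz),
                 approx_charges = list(`1` = ac1, `2` = ac2)),
            class = "esp_component")
}

ac_rows <- function(acl, i) {
  rows <- (acl$ptr[i] + 1L):acl$ptr[i + 1L]
  if (acl$ptr[i] == acl$ptr[i + 1L]) rows <- integer(0)
  out <- as.data.frame(acl$ac[rows, , drop = FALSE])
  names(out) <- c("x", "y", "z", "charge")
  out
}

build_component_tree <- function(ga, g_res, g_str, res_ptr, str_ptr, res_center,
                                 str_center, center, flat, chain_levels) {
  nres <- nrow(res_center)
  nstr <- nrow(str_center)
  res_comps <- vector("list", nres)
  for (i in seq_len(nres)) {
    rows <- (res_ptr[i] + 1L):res_ptr[i + 1L]
    sub <- ga[rows, , drop = FALSE]
    res_comps[[i]] <- component("residue", sub, cbind(sub$x, sub$y, sub$z),
                                sub$charge, res_center[i, ],
                                ac_rows(flat$ac[["1"]]$res, i),
                                ac_rows(flat$ac[["2"]]$res, i))
  }
  str_comps <- vector("list", nstr)
  for (s in seq_len(nstr)) {
    rr <- (str_ptr[s] + 1L):str_ptr[s + 1L]
    arows <- (res_ptr[str_ptr[s] + 1L] + 1L):res_ptr[str_ptr[s + 1L] + 1L]
    sub <- ga[arows, , drop = FALSE]
    str_comps[[s]] <- component("strand", res_comps[rr],
                                cbind(sub$x, sub$y, sub$z), sub$charge,
                                str_center[s, ],
                                ac_rows(flat$ac[["1"]]$str, s),
                                ac_rows(flat$ac[["2"]]$str, s))
    str_comps[[s]]$chain <- chain_levels[s]
  }
  component("complex", str_comps, cbind(ga$x, ga$y, ga$z), ga$charge, center,
            ac_rows(flat$ac[["1"]]$cplx, 1L), ac_rows(flat$ac[["2"]]$cplx, 1L))
}

#' @export
print.esp_structure <- function(x, ...) {
  cat("Hierarchical structure\n")
  cat(sprintf("  complexes: %d\n  strands:   %d\n  residues:  %d\n  atoms:     %d\n",
              x$counts["complexes"], x$counts["strands"], x$counts["residues"],
              x$counts["atoms"]))
  cat(sprintf("  center: (%.3f, %.3f, %.3f)  total charge: %.4f e\n",
              x$center[1], x$center[2], x$center[3], sum(x$atoms$charge)))
  invisible(x)
}

#' @export
print.esp_component <- function(x, ...) {
  cat(sprintf("%s component: %d atoms, total charge %.4f e, bounding radius %.2f A\n",
              x$level, x$n_atoms, x$total_charge, x$bounding_radius))
  invisible(x)
}
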