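#' Read a PQR structure file
#'
#' Parses `ATOM`/`HETATM` records of a whitespace-delimited PQR file into an
#' atom table. Both common PQR dialects are supported and disambiguated by
#' token count per record: 10 tokens means no chain-id column (chain is set to
#' `""`), 11 tokens means the chain id is present. All other lines are
#' ignored. Coordinates are Angstrom, charges elementary charge units, radii
#' Angstrom; no unit conversion is applied.
#'
#' @param path path to a PQR file.
#' @return A `data.frame` with columns `serial`, `name`, `resname`, `chain`,
#'   `resno`, `x`, `y`, `z`, `charge`, `radius`, one row per atom, in file
#'   order.
#' @seealso [write_pqr()], [build_hierarchy()]
#' @export
read_pqr <- function(path) {
  if (!file.exists(path)) stop("PQR file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  idx <- grep("^(ATOM|HETATM)\\b", lines)
  if (length(idx) == 0) stop("no ATOM/HETATM records found in ", path)
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  nt <- lengths(toks)
  bad <- which(nt != 10L & nt != 11L)
  if (length(bad))
    stop(sprintf("line %d: expected 10 or 11 whitespace-delimited fields, found %d",
                 idx[bad[1]], nt[bad[1]]))

  has_chain <- nt == 11L
  field <- function(k_nochain) {
    # k_nochain indexes the 10-token layout; chain column shifts fields >= 5
    vapply(seq_along(toks), function(i) {
      k <- if (has_chain[i] && k_nochain >= 5L) k_nochain + 1L else k_nochain
      toks[[i]][k]
    }, character(1))
  }
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(sprintf("line %d: cannot parse %s field '%s'", idx[bad[1]], what, s[bad[1]]))
    v
  }
  chain <- ifelse(has_chain, vapply(toks, function(t) t[5L], character(1)), "")
  atoms <- data.frame(
    serial = as.integer(num(field(2L), "serial")),
    name = field(3L),
    resname = field(4L),
    chain = chain,
    resno = as.integer(num(field(5L), "residue-number")),
    x = num(field(6L), "x"),
    y = num(field(7L), "y"),
    z = num(field(8L), "z"),
    charge = num(field(9L), "charge"),
    radius = num(field(10L), "radius"),
    stringsAsFactors = FALSE
  )
  if (any(atoms$radius < 0)) stop("negative radius in ", path)
  stopifnot(nrow(atoms) == length(idx))
  atoms
}

#' Write an atom table to a PQR file
#'
#' Records are written whitespace-delimited; atoms with a non-empty `chain`
#' get the 11-token dialect, atoms with `chain == ""` the 10-token dialect.
#' Coordinates are written to 3 decimals, charge and radius to 4, matching
#' common PQR emitters.
#'
#' @param atoms atom `data.frame` as returned by [read_pqr()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pqr <- function(atoms, path) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  chain_tok <- ifelse(nzchar(atoms$chain), paste0(atoms$chain, " "), "")
  lines <- sprintf("ATOM %6d %-4s %-4s %s%4d %11.3f %11.3f %11.3f %8.4f %7.4f",
                   atoms$serial, atoms$name, atoms$resname, chain_tok,
                   atoms$resno, atoms$x, atoms$y, atoms$z, atoms$charge,
                   atoms$radius)
  writeLines(lines, path)
  invisible(path)
}

#' Surface vertex set
#'
#' A set of evaluation points for the potential, plus (optionally) the
#' reference center used for the kernel's `r` term. Engines fall back to the
#' structure center when `center` is `NULL`.
#'
#' @param points numeric matrix with 3 columns (x, y, z), Angstrom.
#' @param center optional numeric length-3 reference center.
#' @return An object of class `vertex_set`.
#' @export
vertex_set <- function(points, center = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  stopifnot(ncol(points) == 3, nrow(points) >= 1, all(is.finite(points)))
  if (!is.null(center)) {
    center <- as.numeric(center)
    stopifnot(length(center) == 3, all(is.finite(center)))
  }
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points, center = center), class = "vertex_set")
}

#' @export
print.vertex_set <- function(x, ...) {
  cat(sprintf("Vertex set: %d points%s\n", nrow(x$points),
              if (is.null(x$center)) " (no center set)"
              else sprintf(", center (%.3f, %.3f, %.3f)", x$center[1],
                           x$center[2], x$center[3])))
  invisible(x)
}

#' @export
length.vertex_set <- function(x) nrow(x$points)

#' Read surface vertices from a plain-text xyz file
#'
#' One `x y z` triple per line; blank lines and lines starting with `#` are
#' skipped.
#'
#' @param path path to the vertex file.
#' @param center optional length-3 reference center to attach; if omitted the
#'   caller must rely on the structure center at evaluation time.
#' @return A [vertex_set()].
#' @export
read_vertices <- function(path, center = NULL) {
  if (!file.exists(path)) stop("vertex file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) stop("no vertex records found in ", path)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(toks) != 3L)
  if (length(bad))
    stop(sprintf("line %d: expected 3 coordinates, found %d",
                 keep[bad[1]], lengths(toks)[bad[1]]))
  m <- matrix(suppressWarnings(as.numeric(unlist(toks))), ncol = 3, byrow = TRUE)
  nf <- which(!is.finite(m))
  if (length(nf))
    stop(sprintf("line %d: non-numeric coordinate", keep[(nf[1] - 1) %% nrow(m) + 1]))
  vertex_set(m, center)
}

#' Write surface vertices to a plain-text xyz file
#'
#' @param vertices a [vertex_set()] or a 3-column matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vertices <- function(vertices, path) {
  pts <- if (inherits(vertices, "vertex_set")) vertices$points else as.matrix(vertices)
  stopifnot(ncol(pts) == 3, nrow(pts) >= 1)
  writeLines(sprintf("%.6f %.6f %.6f", pts[, 1], pts[, 2], pts[, 3]), path)
  invisible(path)
}

#' Write per-vertex potentials and a run summary
#'
#' Writes a CSV with columns `index,x,y,z,potential` (one row per vertex) at
#' `path`, and a JSON summary (total potential, kernel-evaluation count,
#' per-level usage histogram) next to it with suffix `_summary.json`.
#'
#' @param result an `esp_result` from [esp_exact()] or [esp_hcp()].
#' @param vertices the [vertex_set()] the result was computed on.
#' @param path output CSV path.
#' @return Invisibly, a character vector with the CSV and JSON paths.
#' @export
write_result_table <- function(result, vertices, path) {
  stopifnot(inherits(result, "esp_result"), inherits(vertices, "vertex_set"))
  p <- vertices$points
  if (length(result$potentials) == 0) stop("empty result")
  if (length(result$potentials) != nrow(p))
    stop("result and vertex set have different lengths (",
         length(result$potentials), " vs ", nrow(p), ")")
  lines <- c("index,x,y,z,potential",
             sprintf("%d,%.9g,%.9g,%.9g,%.12g", seq_len(nrow(p)), p[, 1],
                     p[, 2], p[, 3], result$potentials))
  writeLines(lines, path)
  json_path <- paste0(tools::file_path_sans_ext(path), "_summary.json")
  jsonlite::write_json(
    list(total_potential = result$total_potential,
         kernel_calls = result$kernel_calls,
         level_usage = as.list(result$level_usage)),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = path, json = json_path))
}
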