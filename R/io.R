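# Versioned exchange schema for stockholder partitions.
#
# Two dialects carry the same content:
#   qdr-json  one JSON document: meta, atoms table, cell block, pairs table
#   qdr-csv   one text file with [meta]/[atoms]/[pairs] sections
# Coordinates and lattice vectors are Angstrom on disk; multipoles a.u.
# Pairs may be stored once per unordered pair; the loader synthesizes the
# mirrored entries.

FORMAT_NAME <- "qdr-partition"
FORMAT_VERSION <- 1L

atoms_table <- function(p) {
  pos <- bohr_to_ang(p$pos)
  q <- p$quad
  data.frame(
    index = seq_along(p$charge), element = p$z,
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    charge = p$charge,
    mux = p$dipole[, 1], muy = p$dipole[, 2], muz = p$dipole[, 3],
    qxx = q[1, 1, ], qxy = q[1, 2, ], qxz = q[1, 3, ],
    qyy = q[2, 2, ], qyz = q[2, 3, ], qzz = q[3, 3, ],
    n_electrons = p$n_electrons,
    cloud_a = p$cloud_a, cloud_b = p$cloud_b,
    cutoff_radius = p$cutoff_radius
  )
}

partition_from_tables <- function(atoms, pairs, cell, method_name, net_charge,
                                  op_threshold = 1e-4, where = "input") {
  need <- c("index", "element", "x", "y", "z", "charge",
            "mux", "muy", "muz", "qxx", "qxy", "qxz", "qyy", "qyz", "qzz")
  missing <- setdiff(need, names(atoms))
  if (length(missing) > 0) {
    stop(sprintf("%s: atoms table lacks column(s) %s", where,
                 paste(missing, collapse = ", ")))
  }
  atoms <- atoms[order(atoms$index), , drop = FALSE]
  n <- nrow(atoms)
  if (!identical(as.integer(atoms$index), seq_len(n))) {
    stop(sprintf("%s: atom indices must be 1..%d without gaps", where, n))
  }
  quad <- array(0, c(3, 3, n))
  quad[1, 1, ] <- atoms$qxx; quad[2, 2, ] <- atoms$qyy; quad[3, 3, ] <- atoms$qzz
  quad[1, 2, ] <- quad[2, 1, ] <- atoms$qxy
  quad[1, 3, ] <- quad[3, 1, ] <- atoms$qxz
  quad[2, 3, ] <- quad[3, 2, ] <- atoms$qyz
  grab <- function(col, default) {
    if (col %in% names(atoms)) atoms[[col]] else rep(default, n)
  }
  op_table <- NULL
  if (!is.null(pairs) && nrow(pairs) > 0) {
    for (col in c("t1", "t2", "t3")) if (!col %in% names(pairs)) pairs[[col]] <- 0L
    op_table <- pairs[, c("a", "b", "t1", "t2", "t3", "op")]
    bad <- op_table$a < 1 | op_table$a > n | op_table$b < 1 | op_table$b > n
    if (any(bad)) {
      stop(sprintf("%s: pair row %d references atom outside 1..%d",
                   where, which(bad)[1], n))
    }
  }
  stockholder_partition(
    elements = atoms$element,
    positions = as.matrix(atoms[, c("x", "y", "z")]),
    charges = atoms$charge,
    dipoles = as.matrix(atoms[, c("mux", "muy", "muz")]),
    quadrupoles = quad,
    op_table = op_table,
    cell = cell,
    n_electrons = grab("n_electrons", NA_real_),
    cloud_a = grab("cloud_a", NA_real_),
    cloud_b = grab("cloud_b", NA_real_),
    cutoff_radius = grab("cutoff_radius", 5),
    method_name = method_name,
    net_charge = net_charge,
    op_threshold = op_threshold
  )
}

#' Save a stockholder partition to an exchange file
#'
#' @param p a `stockholder_partition`.
#' @param path output file path.
#' @param dialect `"qdr-json"` (default) or `"qdr-csv"`.
#' @return `path`, invisibly.
#' @seealso [load_partition()]
#' @export
save_partition <- function(p, path, dialect = c("qdr-json", "qdr-csv")) {
  dialect <- match.arg(dialect)
  atoms <- atoms_table(p)
  pairs <- p$pairs[, c("a", "b", "t1", "t2", "t3", "op")]
  if (dialect == "qdr-json") {
    doc <- list(
      format = FORMAT_NAME, version = FORMAT_VERSION,
      method_name = p$method_name, net_charge = p$net_charge,
      op_threshold = p$op_threshold,
      coordinate_units = "angstrom",
      cell = if (any(p$cell$periodic)) list(
        lattice = bohr_to_ang(p$cell$lattice),
        periodic = p$cell$periodic
      ) else NULL,
      atoms = atoms, pairs = pairs
    )
    jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                         na = "null", matrix = "rowmajor")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# %s %d", FORMAT_NAME, FORMAT_VERSION), con)
    writeLines("[meta]", con)
    writeLines(sprintf("method_name,%s", p$method_name), con)
    writeLines(sprintf("net_charge,%.15g", p$net_charge), con)
    writeLines(sprintf("op_threshold,%.15g", p$op_threshold), con)
    writeLines(sprintf("periodic,%s", paste(as.integer(p$cell$periodic), collapse = " ")), con)
    if (any(p$cell$periodic)) {
      writeLines(sprintf("lattice,%s",
                         paste(sprintf("%.15g", t(bohr_to_ang(p$cell$lattice))),
                               collapse = " ")), con)
    }
    writeLines("[atoms]", con)
    utils::write.csv(atoms, con, row.names = FALSE, quote = FALSE)
    writeLines("[pairs]", con)
    utils::write.csv(pairs, con, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Load a stockholder partition from an exchange file
#'
#' Reads either dialect of the versioned exchange schema, converts
#' coordinates to bohr, synthesizes missing mirrored pair entries from
#' overlap symmetry, and validates every container invariant. Malformed
#' records and inconsistent duplicates are reported as errors naming the
#' offending record.
#'
#' @param path file path.
#' @param dialect `"qdr-json"` or `"qdr-csv"`; inferred from the file when
#'   omitted.
#' @return A validated `stockholder_partition`.
#' @export
load_partition <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(dialect)) {
    first <- readLines(path, n = 1, warn = FALSE)
    dialect <- if (grepl("^\\s*\\{", first)) "qdr-json" else "qdr-csv"
  }
  if (dialect == "qdr-json") {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(doc$format, FORMAT_NAME)) {
      stop(path, ": not a ", FORMAT_NAME, " file (format field: ",
           doc$format %||% "absent", ")")
    }
    cell <- if (!is.null(doc$cell) && !is.null(doc$cell$lattice)) {
      list(lattice = doc$cell$lattice, periodic = doc$cell$periodic)
    }
    pairs <- if (is.data.frame(doc$pairs) && nrow(doc$pairs) > 0) doc$pairs
    partition_from_tables(doc$atoms, pairs, cell,
                          doc$method_name %||% "unspecified",
                          doc$net_charge,
                          doc$op_threshold %||% 1e-4,
                          where = path)
  } else {
    lines <- readLines(path, warn = FALSE)
    sec <- function(name) {
      i <- which(lines == paste0("[", name, "]"))
      if (length(i) != 1) stop(path, ": missing [", name, "] section")
      ends <- c(grep("^\\[", lines), length(lines) + 1)
      j <- min(ends[ends > i])
      lines[(i + 1):(j - 1)]
    }
    meta <- sec("meta")
    meta_kv <- strsplit(meta, ",", fixed = TRUE)
    meta_get <- function(key, default = NULL) {
      hit <- which(vapply(meta_kv, `[`, character(1), 1) == key)
      if (length(hit) == 0) return(default)
      paste(meta_kv[[hit[1]]][-1], collapse = ",")
    }
    periodic <- as.logical(as.integer(strsplit(meta_get("periodic", "0 0 0"), " ")[[1]]))
    cell <- NULL
    if (any(periodic)) {
      lat <- as.numeric(strsplit(meta_get("lattice"), " ")[[1]])
      cell <- list(lattice = matrix(lat, 3, 3, byrow = TRUE), periodic = periodic)
    }
    atoms <- utils::read.csv(text = sec("atoms"))
    ptxt <- sec("pairs")
    pairs <- if (length(ptxt) > 1) utils::read.csv(text = ptxt)
    partition_from_tables(atoms, pairs, cell,
                          meta_get("method_name", "unspecified"),
                          as.numeric(meta_get("net_charge")),
                          as.numeric(meta_get("op_threshold", "1e-4")),
                          where = path)
  }
}

#' Read a bare geometry from an XYZ file
#'
#' @param path XYZ file (element symbols or atomic numbers, Angstrom).
#' @return List with `elements` (atomic numbers) and `positions`
#'   (n x 3, Angstrom).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1]))
  rows <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  sym <- vapply(rows, `[`, character(1), 1)
  z <- suppressWarnings(as.integer(sym))
  if (anyNA(z)) z <- element_number(sym)
  pos <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
  list(elements = z, positions = pos)
}

ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn")

element_number <- function(sym) {
  z <- match(sym, ELEMENT_SYMBOLS)
  if (anyNA(z)) stop("unknown element symbol: ", sym[is.na(z)][1])
  z
}
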