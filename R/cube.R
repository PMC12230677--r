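# Gaussian cube reader/writer. Cube files are bohr-based: origin and axis
# step vectors in bohr, values looped with the last index fastest.

#' Write a grid to a Gaussian cube file
#'
#' @param grid a `potential_grid`.
#' @param path output path.
#' @param p optional `stockholder_partition` whose atoms populate the
#'   atom block (a single dummy atom at the origin is written otherwise).
#' @param comment first header line.
#' @return `path`, invisibly.
#' @export
write_cube <- function(grid, path, p = NULL, comment = "qdrcharges grid") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(comment, sprintf("kind: %s", grid$kind)), con)
  natoms <- if (is.null(p)) 1L else nrow(p$pos)
  writeLines(sprintf("%5d %15.8f %15.8f %15.8f", natoms,
                     grid$origin[1], grid$origin[2], grid$origin[3]), con)
  for (i in 1:3) {
    writeLines(sprintf("%5d %15.8f %15.8f %15.8f", grid$shape[i],
                       grid$axes[i, 1], grid$axes[i, 2], grid$axes[i, 3]), con)
  }
  if (is.null(p)) {
    writeLines(sprintf("%5d %15.8f %15.8f %15.8f %15.8f", 1L, 0, 0, 0, 0), con)
  } else {
    for (A in seq_len(nrow(p$pos))) {
      writeLines(sprintf("%5d %15.8f %15.8f %15.8f %15.8f", p$z[A],
                         p$charge[A], p$pos[A, 1], p$pos[A, 2], p$pos[A, 3]), con)
    }
  }
  # cube value order: z fastest, then y, then x; six values per line
  vals <- as.vector(aperm(grid$values, c(3, 2, 1)))
  rows <- split(vals, ceiling(seq_along(vals) / 6))
  writeLines(vapply(rows, function(v) paste(sprintf("%14.6e", v), collapse = " "),
                    character(1)), con)
  invisible(path)
}

#' Read a Gaussian cube file
#'
#' @param path cube file path.
#' @param kind `"esp"` or `"density"`; taken from the second header line
#'   when it carries a `kind:` tag.
#' @return List with `grid` (a `potential_grid`) and `atoms` (data frame
#'   of z, charge, and positions in bohr).
#' @export
read_cube <- function(path, kind = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (is.null(kind)) {
    kind <- if (grepl("kind: density", lines[2], fixed = TRUE)) "density" else "esp"
  }
  head <- strsplit(trimws(lines[3:6]), "\\s+")
  natoms <- as.integer(head[[1]][1])
  origin <- as.numeric(head[[1]][2:4])
  shape <- integer(3)
  axes <- matrix(0, 3, 3)
  for (i in 1:3) {
    shape[i] <- as.integer(head[[i + 1]][1])
    axes[i, ] <- as.numeric(head[[i + 1]][2:4])
  }
  atoms <- do.call(rbind, lapply(strsplit(trimws(lines[7:(6 + natoms)]), "\\s+"),
                                 function(x) as.numeric(x)))
  atoms <- data.frame(z = as.integer(atoms[, 1]), charge = atoms[, 2],
                      x = atoms[, 3], y = atoms[, 4], z_pos = atoms[, 5])
  vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:(6 + natoms))]), "\\s+")))
  if (length(vals) != prod(shape)) {
    stop(path, ": expected ", prod(shape), " values, found ", length(vals))
  }
  values <- aperm(array(vals, rev(shape)), c(3, 2, 1))
  grid <- potential_grid(bohr_to_ang(origin), bohr_to_ang(axes), shape,
                         values, kind)
  list(grid = grid, atoms = atoms)
}
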