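# Minimal small-molecule CIF subset: cell parameters, explicit symmetry
# operator loop, atom-site loop, and an optional anisotropic-U loop.

#' Write a crystal structure to a CIF file (small-molecule subset)
#'
#' Emits `_cell_*`, `_symmetry_equiv_pos_as_xyz`, the atom-site loop
#' (fractional coordinates, U_iso, occupancy) and an `_atom_site_aniso`
#' loop for anisotropic sites. Numeric fields are printed with enough
#' digits for a bit-exact round trip at the printed precision.
#'
#' @param structure A `crystal_structure`.
#' @param path Output path.
#' @param data_name CIF data block name.
#' @export
write_cif <- function(structure, path, data_name = "aspherED") {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  cell <- structure$cell
  w("data_%s", data_name)
  w("_cell_length_a    %.6f", cell$abc[1])
  w("_cell_length_b    %.6f", cell$abc[2])
  w("_cell_length_c    %.6f", cell$abc[3])
  w("_cell_angle_alpha %.6f", cell$angles[1])
  w("_cell_angle_beta  %.6f", cell$angles[2])
  w("_cell_angle_gamma %.6f", cell$angles[3])
  w("_symmetry_space_group_name_H-M '%s'", structure$sg$symbol)
  w("loop_")
  w("_symmetry_equiv_pos_as_xyz")
  for (op in structure$sg$ops) w("'%s'", format_symop(op))
  w("loop_")
  w("_atom_site_label")
  w("_atom_site_type_symbol")
  w("_atom_site_fract_x")
  w("_atom_site_fract_y")
  w("_atom_site_fract_z")
  w("_atom_site_occupancy")
  w("_atom_site_U_iso_or_equiv")
  w("_atom_site_adp_type")
  for (s in structure$sites) {
    uiso <- if (is.null(s$uaniso)) s$uiso else u_equiv(structure, s$label)
    w("%s %s %.8f %.8f %.8f %.6f %.8f %s", s$label, s$element,
      s$xyz[1], s$xyz[2], s$xyz[3], s$occupancy, uiso,
      if (is.null(s$uaniso)) "Uiso" else "Uani")
  }
  aniso <- Filter(function(s) !is.null(s$uaniso), structure$sites)
  if (length(aniso)) {
    w("loop_")
    w("_atom_site_aniso_label")
    w("_atom_site_aniso_U_11")
    w("_atom_site_aniso_U_22")
    w("_atom_site_aniso_U_33")
    w("_atom_site_aniso_U_12")
    w("_atom_site_aniso_U_13")
    w("_atom_site_aniso_U_23")
    for (s in aniso) {
      w("%s %.8f %.8f %.8f %.8f %.8f %.8f", s$label,
        s$uaniso[1], s$uaniso[2], s$uaniso[3],
        s$uaniso[4], s$uaniso[5], s$uaniso[6])
    }
  }
  invisible(path)
}

#' Read a CIF file written with [write_cif()] (small-molecule subset)
#'
#' @param path CIF path.
#' @return A `crystal_structure`.
#' @export
read_cif <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  getval <- function(tag) {
    ln <- lines[startsWith(lines, tag)][1]
    as.numeric(strsplit(ln, "[[:space:]]+")[[1]][2])
  }
  cell <- build_cell(getval("_cell_length_a"), getval("_cell_length_b"),
                     getval("_cell_length_c"), getval("_cell_angle_alpha"),
                     getval("_cell_angle_beta"), getval("_cell_angle_gamma"))
  symln <- lines[startsWith(lines, "_symmetry_space_group_name_H-M")][1]
  symbol <- gsub("'", "", sub("^\\S+\\s+", "", symln))
  # symmetry loop: quoted xyz strings after the _symmetry_equiv_pos_as_xyz tag
  i0 <- which(lines == "_symmetry_equiv_pos_as_xyz") + 1
  ops <- character(0)
  i <- i0
  while (i <= length(lines) && grepl("^'", lines[i])) {
    ops <- c(ops, gsub("'", "", lines[i]))
    i <- i + 1
  }
  sg <- space_group(symbol, ops)
  # atom site loop
  i0 <- which(lines == "_atom_site_adp_type") + 1
  sites <- list()
  i <- i0
  while (i <= length(lines) && !startsWith(lines[i], "loop_") &&
         !startsWith(lines[i], "_")) {
    tok <- strsplit(lines[i], "[[:space:]]+")[[1]]
    sites[[tok[1]]] <- list(label = tok[1], element = tok[2],
                            xyz = as.numeric(tok[3:5]),
                            occ = as.numeric(tok[6]),
                            uiso = as.numeric(tok[7]), type = tok[8])
    i <- i + 1
  }
  # aniso loop
  aniso <- list()
  j <- which(lines == "_atom_site_aniso_U_23")
  if (length(j)) {
    i <- j[1] + 1
    while (i <= length(lines) && !startsWith(lines[i], "loop_") &&
           !startsWith(lines[i], "_")) {
      tok <- strsplit(lines[i], "[[:space:]]+")[[1]]
      aniso[[tok[1]]] <- as.numeric(tok[2:7])
      i <- i + 1
    }
  }
  out <- lapply(sites, function(s) {
    atom_site(s$label, s$element, s$xyz,
              uiso = if (s$type == "Uiso") s$uiso else 0,
              uaniso = aniso[[s$label]], occupancy = s$occ)
  })
  crystal_structure(cell, sg, unname(out))
}
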