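# residue name for a molecule given its first bead's role
res_name <- function(role, charge) {
  if (role == "counterion") {
    if (charge > 0) "NA" else "CL"
  } else if (role == "solvent") "W" else "TSK"
}

#' Write a configuration to GRO, PDB or XYZ
#'
#' Fixed-width compliant writers: GRO in nm with 3-decimal positions and a
#' box line, PDB in A with a CRYST1 record, XYZ in A with the box on the
#' comment line.  Molecules are wrapped whole into the box on write (the
#' in-memory configuration stays unwrapped); output is deterministic.
#' PDB serials above 99999 wrap around with a warning.
#'
#' @param config A [cg_configuration()].
#' @param path Output path.
#' @param format `"gro"`, `"pdb"` or `"xyz"`; guessed from the file
#'   extension when missing.
#' @return `path`, invisibly.
#' @export
write_coordinates <- function(config, path, format = NULL) {
  format <- tolower(format %||% tools::file_ext(path))
  if (!format %in% c("gro", "pdb", "xyz")) {
    abort("format must be gro, pdb or xyz.")
  }
  cfg <- wrap_config(config)
  b <- cfg$beads
  resn <- vapply(seq_len(nrow(b)),
                 function(i) res_name(b$role[i], b$charge[i]), character(1))
  lines <- switch(format,
    gro = {
      xyz <- as.matrix(b[, c("x", "y", "z")]) / A_PER_NM
      body <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                      b$molecule %% 100000L, resn, b$name,
                      seq_len(nrow(b)) %% 100000L,
                      xyz[, 1], xyz[, 2], xyz[, 3])
      c("generated by stacksas", sprintf("%5d", nrow(b)), body,
        sprintf("%10.5f%10.5f%10.5f", cfg$box[1] / A_PER_NM,
                cfg$box[2] / A_PER_NM, cfg$box[3] / A_PER_NM))
    },
    pdb = {
      serial <- seq_len(nrow(b))
      if (max(serial) > 99999) {
        warn("more than 99999 atoms: PDB serials wrap around.")
        serial <- serial %% 100000L
      }
      body <- sprintf(
        "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        serial, b$name, resn, b$molecule %% 10000L, b$x, b$y, b$z)
      c(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                cfg$box[1], cfg$box[2], cfg$box[3], 90, 90, 90),
        body, "END")
    },
    xyz = {
      c(sprintf("%d", nrow(b)),
        sprintf("box %.6f %.6f %.6f A", cfg$box[1], cfg$box[2], cfg$box[3]),
        sprintf("%-5s %12.6f %12.6f %12.6f", b$name, b$x, b$y, b$z))
    })
  writeLines(lines, path)
  invisible(path)
}

# rebuild the bead metadata columns from bead names via template/bead table
beads_from_names <- function(names_, molecule, xyz, template) {
  bt <- bead_types()
  if (!is.null(template)) {
    s <- template$sites
    site <- match(names_, s$name)
  } else {
    site <- rep(NA_integer_, length(names_))
  }
  type <- character(length(names_))
  for (i in seq_along(names_)) {
    if (!is.na(site[i]) && !is.null(template)) {
      type[i] <- template$sites$type[site[i]]
    } else if (names_[i] %in% bt$name) {
      type[i] <- names_[i]
    } else if (names_[i] == "NA") {
      type[i] <- "TQ5"
    } else if (names_[i] == "CL") {
      type[i] <- "CL"
    } else {
      abort(paste0("cannot map bead name '", names_[i],
                   "' to a bead type (supply `template`)."))
    }
  }
  info <- bead_row(type, bt)
  # per-molecule site numbering for beads without template match
  out <- tibble(
    molecule = molecule, site = site, name = names_, type = type,
    role = info$role, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    virtual = info$role == "core-virtual", radius = info$radius,
    charge = info$charge, mass = info$mass,
    xray_contrast = info$xray_contrast,
    neutron_contrast = info$neutron_contrast
  )
  miss <- is.na(out$site)
  if (any(miss)) {
    out$site[miss] <- stats::ave(rep(1L, sum(miss)), out$molecule[miss],
                                 FUN = seq_along)
  }
  out
}

#' Read a configuration from GRO, PDB or XYZ
#'
#' Units are normalized to the internal A convention (GRO is nm on file,
#' scaled by 10).  The box comes from the GRO box line / PDB CRYST1 / XYZ
#' comment line; molecule indices from residue numbering (XYZ, which has
#' none, gets consecutive template-sized blocks when a template is given,
#' else one molecule per bead).  Velocities are ignored.
#'
#' @param path File path.
#' @param format `"gro"`, `"pdb"` or `"xyz"`; guessed from the extension.
#' @param template Optional [build_template()] used to map bead names to
#'   types and validate per-molecule layout.
#' @return A [cg_configuration()] (validation relaxed to the file format's
#'   coordinate precision).
#' @export
read_coordinates <- function(path, format = NULL, template = NULL) {
  format <- tolower(format %||% tools::file_ext(path))
  lines <- readLines(path)
  parse_num <- function(s, what, lineno) {
    v <- suppressWarnings(as.numeric(s))
    if (anyNA(v)) {
      abort(sprintf("malformed %s field at line %d of %s.",
                    what, lineno[which(is.na(v))[1]], path))
    }
    v
  }
  if (format == "gro") {
    if (length(lines) < 3) abort("truncated GRO file.")
    n <- suppressWarnings(as.integer(trimws(lines[2])))
    if (is.na(n) || n < 1) abort("GRO file declares no atoms.")
    if (length(lines) < 2 + n + 1) abort("GRO file shorter than declared.")
    at <- lines[3:(2 + n)]
    ln <- 3:(2 + n)
    molecule <- as.integer(parse_num(substr(at, 1, 5), "residue id", ln))
    names_ <- trimws(substr(at, 11, 15))
    x <- parse_num(substr(at, 21, 28), "x", ln)
    y <- parse_num(substr(at, 29, 36), "y", ln)
    z <- parse_num(substr(at, 37, 44), "z", ln)
    box <- parse_num(strsplit(trimws(lines[3 + n]), "\\s+")[[1]][1:3],
                     "box", rep(3 + n, 3)) * A_PER_NM
    xyz <- cbind(x, y, z) * A_PER_NM
  } else if (format == "pdb") {
    cry <- grep("^CRYST1", lines, value = TRUE)
    if (!length(cry)) abort("PDB file lacks a CRYST1 box record.")
    box <- as.numeric(c(substr(cry[1], 7, 15), substr(cry[1], 16, 24),
                        substr(cry[1], 25, 33)))
    ati <- grep("^(ATOM  |HETATM)", lines)
    if (!length(ati)) abort("PDB file contains no atoms.")
    at <- lines[ati]
    molecule <- as.integer(parse_num(substr(at, 23, 26), "residue id", ati))
    names_ <- trimws(substr(at, 13, 16))
    xyz <- cbind(parse_num(substr(at, 31, 38), "x", ati),
                 parse_num(substr(at, 39, 46), "y", ati),
                 parse_num(substr(at, 47, 54), "z", ati))
  } else if (format == "xyz") {
    n <- suppressWarnings(as.integer(trimws(lines[1])))
    if (is.na(n) || n < 1) abort("XYZ file declares no atoms.")
    cm <- strsplit(trimws(lines[2]), "\\s+")[[1]]
    if (length(cm) >= 4 && cm[1] == "box") {
      box <- as.numeric(cm[2:4])
    } else {
      abort("XYZ comment line must carry 'box Lx Ly Lz'.")
    }
    at <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
    names_ <- vapply(at, `[`, character(1), 1)
    xyz <- t(vapply(at, function(f) {
      parse_num(f[2:4], "coordinate", 0)
    }, numeric(3)))
    if (!is.null(template)) {
      ntpl <- nrow(template$sites)
      n_mol <- n %/% ntpl
      molecule <- c(rep(seq_len(n_mol), each = ntpl),
                    n_mol + seq_len(n - n_mol * ntpl))
    } else {
      molecule <- seq_len(n)
    }
  } else {
    abort("format must be gro, pdb or xyz.")
  }
  beads <- beads_from_names(names_, molecule, xyz, template)
  cg_configuration(beads, box, template, validate = FALSE)
}
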