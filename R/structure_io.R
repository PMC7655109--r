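# Fixed-column PDB reading/writing and the Structure / Trajectory containers.
#
# The trajectory dialect is multi-model PDB (MODEL/ENDMDL delimited); a
# single-model file yields a one-frame trajectory. Coordinates are in
# angstrom, times in picoseconds, residue numbering 1-based as in PDB.

# Two-character element symbols that can occur in columns 13-14 of the atom
# name field; used when the element columns (77-78) are blank.
.two_letter_elements <- c(
  "FE", "CL", "BR", "NA", "MG", "ZN", "CA", "MN", "CU", "NI", "CO", "SE", "CD"
)

.infer_element <- function(name4, resname) {
  stripped <- gsub("[^A-Za-z]", "", name4)
  if (!nzchar(stripped)) {
    return("")
  }
  # A name that starts in column 13 with a letter signals a two-character
  # element symbol (FE, CL, NA, ...); names starting with a digit are
  # hydrogens like "1HB2". Everything else keys on the first letter.
  two <- toupper(substr(stripped, 1, 2))
  if (substr(name4, 1, 1) != " " && !grepl("^[0-9]", name4) &&
      two %in% .two_letter_elements) {
    return(paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))))
  }
  toupper(substr(stripped, 1, 1))
}

.parse_atom_line <- function(line) {
  pad <- function(x, n) formatC(x, width = n, flag = "-")
  line <- pad(line, 80)
  xs <- suppressWarnings(as.numeric(substr(line, 31, 38)))
  ys <- suppressWarnings(as.numeric(substr(line, 39, 46)))
  zs <- suppressWarnings(as.numeric(substr(line, 47, 54)))
  serial <- suppressWarnings(as.integer(substr(line, 7, 11)))
  resno <- suppressWarnings(as.integer(substr(line, 23, 26)))
  if (anyNA(c(xs, ys, zs, resno))) {
    return(NULL)
  }
  name <- trimws(substr(line, 13, 16))
  resname <- trimws(substr(line, 18, 20))
  elem <- trimws(substr(line, 77, 78))
  if (!nzchar(elem)) elem <- .infer_element(substr(line, 13, 16), resname)
  if (!nzchar(elem)) {
    return(NULL)
  }
  occ <- suppressWarnings(as.numeric(substr(line, 55, 60)))
  bf <- suppressWarnings(as.numeric(substr(line, 61, 66)))
  list(
    serial = if (is.na(serial)) 0L else serial,
    name = name,
    element = paste0(
      toupper(substr(elem, 1, 1)),
      tolower(substr(elem, 2, 2))
    ),
    resname = resname,
    resno = resno,
    icode = trimws(substr(line, 27, 27)),
    chain = trimws(substr(line, 22, 22)),
    altloc = trimws(substr(line, 17, 17)),
    x = xs, y = ys, z = zs,
    occ = if (is.na(occ)) 1 else occ,
    b = if (is.na(bf)) 0 else bf,
    het = startsWith(line, "HETATM")
  )
}

#' Create a Structure object
#'
#' A Structure holds an ordered atom table plus optional inferred bonds. Most
#' users obtain one from [read_structure()] or the synthetic generators.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resno`, `icode`, `chain`, `altloc`, `x`, `y`, `z`, `occ`,
#'   `b`, `het`.
#' @param bonds optional two-column integer matrix of atom indices.
#' @param identifier free-text identifier.
#' @return An object of class `Structure`.
#' @export
new_structure <- function(atoms, bonds = NULL, identifier = "") {
  required <- c(
    "serial", "name", "element", "resname", "resno", "icode",
    "chain", "altloc", "x", "y", "z", "occ", "b", "het"
  )
  missing <- setdiff(required, names(atoms))
  if (length(missing)) {
    stop("atoms table lacks columns: ", paste(missing, collapse = ", "))
  }
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (any(!nzchar(atoms$element))) stop("empty element symbols")
  if (!is.null(bonds) && length(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2L)
    if (any(bonds < 1L) || any(bonds > nrow(atoms))) {
      stop("bond indices out of range")
    }
    if (any(bonds[, 1] == bonds[, 2])) stop("self-bonds are not allowed")
  }
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms, bonds = bonds, identifier = identifier),
    class = "Structure"
  )
}

#' @export
print.Structure <- function(x, ...) {
  cat(
    "<Structure>", x$identifier, "-", nrow(x$atoms), "atoms,",
    length(unique(x$atoms$chain)), "chain(s),",
    if (is.null(x$bonds)) 0L else nrow(x$bonds), "bonds\n"
  )
  invisible(x)
}

#' Coordinates of a Structure
#'
#' @param x a `Structure`.
#' @return n x 3 numeric matrix (angstrom).
#' @export
coords <- function(x) {
  stopifnot(inherits(x, "Structure"))
  m <- as.matrix(x$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Replace the coordinates of a Structure
#'
#' @param x a `Structure`.
#' @param value n x 3 numeric matrix.
#' @return the updated `Structure`.
#' @export
`coords<-` <- function(x, value) {
  stopifnot(inherits(x, "Structure"), nrow(value) == nrow(x$atoms))
  x$atoms$x <- value[, 1]
  x$atoms$y <- value[, 2]
  x$atoms$z <- value[, 3]
  x
}

#' Create a Trajectory object
#'
#' @param topology a `Structure` giving atom identities.
#' @param frames list of n x 3 coordinate matrices, one per frame.
#' @param times numeric vector of frame times in ps, strictly increasing.
#' @return An object of class `Trajectory`.
#' @export
new_trajectory <- function(topology, frames, times) {
  stopifnot(inherits(topology, "Structure"))
  n <- nrow(topology$atoms)
  ok <- vapply(frames, function(f) nrow(f) == n && ncol(f) == 3, logical(1))
  if (!all(ok)) stop("every frame must have one coordinate triple per atom")
  if (length(times) != length(frames)) {
    stop("times and frames lengths differ")
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("times must be strictly increasing")
  }
  structure(
    list(topology = topology, frames = frames, times = as.numeric(times)),
    class = "Trajectory"
  )
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(
    "<Trajectory>", x$topology$identifier, "-",
    nrow(x$topology$atoms), "atoms x", length(x$frames), "frames",
    sprintf(
      "(t = %g..%g ps)\n", min(x$times), max(x$times)
    )
  )
  invisible(x)
}

#' Number of frames in a Trajectory
#' @param traj a `Trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Extract one frame of a Trajectory as a Structure
#'
#' @param traj a `Trajectory`.
#' @param i frame index (1-based).
#' @return a `Structure` carrying the frame's coordinates.
#' @export
frame_structure <- function(traj, i) {
  stopifnot(i >= 1, i <= length(traj$frames))
  s <- traj$topology
  coords(s) <- traj$frames[[i]]
  s
}

# Altloc policy: keep the highest-occupancy conformer per
# (chain, resno, icode, name); ties broken by altloc letter, 'A' first.
.resolve_altlocs <- function(atoms) {
  if (!any(nzchar(atoms$altloc))) {
    return(atoms)
  }
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$name, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    if (length(idx) == 1L) {
      return(idx)
    }
    o <- order(-atoms$occ[idx], atoms$altloc[idx])
    idx[o[1L]]
  }), use.names = FALSE)
  atoms[sort(keep), , drop = FALSE]
}

#' Read a structure or multi-model trajectory from PDB text
#'
#' Parses fixed-column `ATOM`/`HETATM` records; `MODEL`/`ENDMDL` pairs
#' delimit frames and a single-model file yields a one-frame trajectory.
#' Elements come from columns 77-78, falling back to inference from the atom
#' name. Alternate locations are collapsed to the highest-occupancy conformer
#' (ties: altloc 'A' first).
#'
#' @param source path to a PDB file, or a character vector of PDB lines.
#' @param strict if `TRUE`, malformed atom lines raise an error; otherwise
#'   they are skipped with a warning.
#' @param times optional frame times (ps); defaults to
#'   `frame index * default_stride`.
#' @param default_stride default inter-frame spacing in ps when `times` is
#'   absent (500 ps, the production-analysis stride).
#' @return a `Trajectory`.
#' @export
read_structure <- function(source, strict = FALSE, times = NULL,
                           default_stride = 500) {
  lines <- if (length(source) == 1L && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    as.character(source)
  }
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  is_model <- startsWith(lines, "MODEL")
  is_endmdl <- startsWith(lines, "ENDMDL")

  model_of <- cumsum(is_model)
  has_models <- any(is_model)
  atoms_idx <- which(is_atom)
  if (!length(atoms_idx)) stop("no ATOM/HETATM records found")

  parse_block <- function(idx, model_id) {
    parsed <- lapply(lines[idx], .parse_atom_line)
    bad <- vapply(parsed, is.null, logical(1))
    if (any(bad)) {
      msg <- sprintf(
        "%d malformed ATOM/HETATM line(s)%s", sum(bad),
        if (has_models) sprintf(" in model %d", model_id) else ""
      )
      if (strict) stop(msg)
      warning(msg, call. = FALSE)
      parsed <- parsed[!bad]
    }
    if (!length(parsed)) {
      return(NULL)
    }
    df <- do.call(
      rbind,
      lapply(parsed, function(p) as.data.frame(p, stringsAsFactors = FALSE))
    )
    .resolve_altlocs(df)
  }

  if (!has_models) {
    atoms <- parse_block(atoms_idx, 1L)
    if (is.null(atoms)) stop("no parsable atoms")
    topo <- new_structure(atoms, identifier = .source_id(source))
    frames <- list(coords(topo))
  } else {
    ids <- sort(unique(model_of[atoms_idx]))
    ids <- ids[ids > 0]
    blocks <- lapply(ids, function(m) {
      parse_block(atoms_idx[model_of[atoms_idx] == m], m)
    })
    blocks <- blocks[!vapply(blocks, is.null, logical(1))]
    if (!length(blocks)) stop("no parsable atoms")
    counts <- vapply(blocks, nrow, integer(1))
    if (length(unique(counts)) != 1L) {
      bad <- which(counts != counts[1L])[1L]
      stop(sprintf(
        "inconsistent atom count across models: model %d has %d atoms, model 1 has %d",
        bad, counts[bad], counts[1L]
      ))
    }
    topo <- new_structure(blocks[[1L]], identifier = .source_id(source))
    frames <- lapply(blocks, function(b) {
      m <- as.matrix(b[, c("x", "y", "z")])
      dimnames(m) <- NULL
      m
    })
  }
  if (is.null(times)) times <- seq_along(frames) * default_stride
  new_trajectory(topo, frames, times)
}

.source_id <- function(source) {
  if (length(source) == 1L && file.exists(source)) {
    sub("\\.pdb$", "", basename(source))
  } else {
    "pdb"
  }
}

.format_atom_line <- function(a, serial) {
  name <- a$name
  # PDB convention: 1-3 character names start in column 14 unless the
  # element symbol is two characters.
  nm <- if (nchar(name) >= 4L || nchar(a$element) == 2L) {
    formatC(name, width = -4)
  } else {
    paste0(" ", formatC(name, width = -3))
  }
  sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    if (a$het) "HETATM" else "ATOM", serial %% 100000L, nm,
    substr(a$altloc, 1, 1), a$resname, substr(a$chain, 1, 1),
    a$resno %% 10000L, substr(a$icode, 1, 1),
    a$x, a$y, a$z, a$occ, a$b, toupper(a$element)
  )
}

#' Write a Structure or Trajectory as PDB text
#'
#' @param x a `Structure` or `Trajectory`.
#' @param path output file path; when `NULL` the lines are returned.
#' @return invisibly, the character vector of PDB lines.
#' @export
write_structure <- function(x, path = NULL) {
  if (inherits(x, "Structure")) {
    x <- new_trajectory(x, list(coords(x)), times = 0)
  }
  stopifnot(inherits(x, "Trajectory"))
  atoms <- x$topology$atoms
  multi <- length(x$frames) > 1L
  out <- character(0)
  for (f in seq_along(x$frames)) {
    if (multi) out <- c(out, sprintf("MODEL %8d", f))
    a <- atoms
    a$x <- x$frames[[f]][, 1]
    a$y <- x$frames[[f]][, 2]
    a$z <- x$frames[[f]][, 3]
    body <- vapply(
      seq_len(nrow(a)),
      function(i) .format_atom_line(as.list(a[i, ]), i),
      character(1)
    )
    out <- c(out, body, if (multi) "ENDMDL")
  }
  out <- c(out, "END")
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
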