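# Structure I/O: fixed-column PDB (multi-model), a whitespace XYZ trajectory
# dialect, mask configs, and toy force-field topologies. The parser enforces
# the contracts downstream code relies on: line-numbered errors on malformed
# ATOM records, identical atom counts across MODEL blocks, and an explicit
# error (never silent truncation) when a coordinate overflows the 8.3 field.

.parse_atom_line <- function(line, lineno) {
  # PDB fixed columns (1-based, inclusive):
  # record 1-6, serial 7-11, name 13-16, altLoc 17, resName 18-20,
  # chain 22, resSeq 23-26, iCode 27, x 31-38, y 39-46, z 47-54, element 77-78
  if (nchar(line) < 54L) {
    abort(sprintf("Malformed ATOM/HETATM record at line %d: too short.", lineno))
  }
  num <- function(s, what) {
    v <- suppressWarnings(as.numeric(trimws(s)))
    if (is.na(v)) {
      abort(sprintf("Malformed ATOM/HETATM record at line %d: bad %s field '%s'.",
                    lineno, what, trimws(s)))
    }
    v
  }
  list(
    serial = as.integer(num(substr(line, 7, 11), "serial")),
    name = trimws(substr(line, 13, 16)),
    altloc = substr(line, 17, 17),
    resname = trimws(substr(line, 18, 20)),
    chain = trimws(substr(line, 22, 22)),
    resno = as.integer(num(substr(line, 23, 26), "residue number")),
    icode = trimws(substr(line, 27, 27)),
    x = num(substr(line, 31, 38), "x"),
    y = num(substr(line, 39, 46), "y"),
    z = num(substr(line, 47, 54), "z"),
    element = if (nchar(line) >= 77L) trimws(substr(line, 77, 78)) else ""
  )
}

#' Read a (multi-model) PDB file into a conformational ensemble
#'
#' `MODEL`/`ENDMDL` blocks delimit frames; a file without `MODEL` records
#' yields a single-frame ensemble. Only `ATOM`/`HETATM` records are read.
#' For alternate locations the first altloc encountered is kept; insertion
#' codes are treated as distinct residues.
#'
#' @param path Path to a PDB-dialect text file.
#' @return A [conf_ensemble()].
#' @export
read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(lines, "MODEL")
  if (!any(is_atom)) abort(sprintf("No ATOM/HETATM records found in '%s'.", path))

  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id[] <- 1L
  model_id[model_id == 0L] <- 1L  # atoms before the first MODEL card

  atom_lines <- which(is_atom)
  parsed <- lapply(atom_lines, function(i) .parse_atom_line(lines[i], i))
  frames_of <- model_id[atom_lines]

  split_idx <- split(seq_along(parsed), frames_of)
  n_per <- lengths(split_idx)
  build_frame <- function(ii) {
    p <- parsed[ii]
    tibble(
      serial = vapply(p, `[[`, integer(1), "serial"),
      name = vapply(p, `[[`, character(1), "name"),
      altloc = vapply(p, `[[`, character(1), "altloc"),
      resname = vapply(p, `[[`, character(1), "resname"),
      chain = vapply(p, `[[`, character(1), "chain"),
      resno = vapply(p, `[[`, integer(1), "resno"),
      icode = vapply(p, `[[`, character(1), "icode"),
      x = vapply(p, `[[`, numeric(1), "x"),
      y = vapply(p, `[[`, numeric(1), "y"),
      z = vapply(p, `[[`, numeric(1), "z"),
      element = vapply(p, `[[`, character(1), "element")
    )
  }
  tabs <- lapply(split_idx, build_frame)

  # First-altloc filter, applied identically to every frame.
  drop_altloc <- function(tb) {
    key <- paste(tb$chain, tb$resno, tb$icode, tb$name, sep = "|")
    tb[!duplicated(key), , drop = FALSE]
  }
  tabs <- lapply(tabs, drop_altloc)
  counts <- vapply(tabs, nrow, integer(1))
  if (length(unique(counts)) != 1L) {
    abort(sprintf(
      "Inconsistent atom counts across MODEL blocks in '%s': %s.",
      path, paste(counts, collapse = ", ")))
  }

  meta <- tabs[[1]][c("serial", "name", "resname", "chain", "resno",
                      "icode", "element")]
  coords <- array(NA_real_, dim = c(length(tabs), nrow(meta), 3L))
  for (f in seq_along(tabs)) {
    coords[f, , 1] <- tabs[[f]]$x
    coords[f, , 2] <- tabs[[f]]$y
    coords[f, , 3] <- tabs[[f]]$z
  }
  conf_ensemble(meta, coords)
}

#' Write a conformational ensemble as fixed-column PDB text
#'
#' Multi-frame ensembles are written as one `MODEL`/`ENDMDL` block per frame.
#' A coordinate that cannot be represented in the PDB 8.3 fixed field
#' (outside (-1000, 10000)) raises an error rather than being truncated.
#'
#' @param ensemble A [conf_ensemble()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  xyz <- ensemble$coords
  if (any(xyz <= -1000 | xyz >= 10000)) {
    bad <- which(xyz <= -1000 | xyz >= 10000)[1]
    abort(sprintf(
      "Coordinate %.3f does not fit the PDB 8.3 fixed field; refusing to truncate.",
      xyz[bad]))
  }
  at <- ensemble$atoms
  pdb_name <- ifelse(nchar(at$name) >= 4L, substr(at$name, 1, 4),
                     sprintf(" %-3s", at$name))
  multi <- n_frames(ensemble) > 1L
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(ensemble))) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    m <- frame_coords(ensemble, f)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      at$serial, pdb_name, at$resname,
      ifelse(at$chain == "", " ", at$chain), at$resno,
      ifelse(at$icode == "", " ", at$icode),
      m[, 1], m[, 2], m[, 3], 1.00, 0.00, at$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read/write a whitespace XYZ trajectory
#'
#' Dialect: repeated blocks of `N` / comment line / `N` lines of
#' `element x y z`. Used mainly for synthetic ensembles, where PDB residue
#' bookkeeping adds nothing.
#'
#' @param path File path.
#' @return A [conf_ensemble()] with one residue per atom.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  pos <- 1L
  frames <- list()
  elements <- NULL
  while (pos <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n < 1L) {
      abort(sprintf("Malformed XYZ atom count at line %d.", pos))
    }
    if (pos + 1L + n > length(lines)) {
      abort(sprintf("Truncated XYZ frame starting at line %d.", pos))
    }
    block <- lines[(pos + 2L):(pos + 1L + n)]
    toks <- strsplit(trimws(block), "\\s+")
    bad <- which(lengths(toks) < 4L)
    if (length(bad) > 0L) {
      abort(sprintf("Malformed XYZ atom line at line %d.", pos + 1L + bad[1]))
    }
    el <- vapply(toks, `[[`, character(1), 1L)
    m <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    if (any(is.na(m))) abort(sprintf("Non-numeric XYZ coordinates in frame at line %d.", pos))
    if (is.null(elements)) {
      elements <- el
    } else if (length(el) != length(elements)) {
      abort("Inconsistent atom counts across XYZ frames.")
    }
    frames[[length(frames) + 1L]] <- m
    pos <- pos + 2L + n
  }
  coords <- array(NA_real_, dim = c(length(frames), length(elements), 3L))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  atoms <- tibble(serial = seq_along(elements), name = elements,
                  resname = "UNK", chain = "A",
                  resno = seq_along(elements), icode = "",
                  element = toupper(elements))
  conf_ensemble(atoms, coords)
}

#' @rdname read_xyz
#' @param ensemble A [conf_ensemble()].
#' @param comment Comment line written into each frame block.
#' @export
write_xyz <- function(ensemble, path, comment = "polsite ensemble") {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  el <- ensemble$atoms$element
  el[!nzchar(el)] <- "X"
  for (f in seq_len(n_frames(ensemble))) {
    m <- frame_coords(ensemble, f)
    writeLines(as.character(n_atoms(ensemble)), con)
    writeLines(sprintf("%s frame %d", comment, f), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", el, m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

# ---- Subdomain masks -------------------------------------------------------

#' Subdomain masks: named atom selections
#'
#' A `subdomain_mask` is a named set of atom indices resolved against a
#' specific ensemble; every trajectory metric is restricted through one
#' (e.g. Palm, Fingers, Thumb, DNA primer/template, or a fit reference).
#'
#' @param name Mask name.
#' @param atom_idx Integer atom indices into the ensemble the mask was
#'   resolved against.
#' @return A `subdomain_mask`.
#' @export
subdomain_mask <- function(name, atom_idx) {
  atom_idx <- sort(unique(as.integer(atom_idx)))
  if (length(atom_idx) == 0L) {
    abort(sprintf("Mask '%s' selects no atoms.", name))
  }
  structure(list(name = name, atom_idx = atom_idx), class = "subdomain_mask")
}

#' @export
print.subdomain_mask <- function(x, ...) {
  cat(sprintf("<subdomain_mask> %s: %d atoms\n", x$name, length(x$atom_idx)))
  invisible(x)
}

# Accept either a mask or a bare index vector everywhere.
mask_indices <- function(x) {
  if (inherits(x, "subdomain_mask")) x$atom_idx else as.integer(x)
}

#' Select atoms of an ensemble by chain / residue range / atom name
#'
#' Residue ranges are inclusive at both endpoints; residue numbering is
#' 1-based as in PDB.
#'
#' @param ensemble A [conf_ensemble()].
#' @param chain Chain identifier(s), or `NULL` for any.
#' @param resno Integer vector of residue numbers (e.g. `815:910`), or `NULL`.
#' @param name Atom name(s), or `NULL`.
#' @param element Element symbol(s), or `NULL`.
#' @return Integer atom indices.
#' @export
select_atoms <- function(ensemble, chain = NULL, resno = NULL, name = NULL,
                         element = NULL) {
  stopifnot(inherits(ensemble, "conf_ensemble"))
  at <- ensemble$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  if (!is.null(resno)) keep <- keep & at$resno %in% as.integer(resno)
  if (!is.null(name)) keep <- keep & trimws(at$name) %in% name
  if (!is.null(element)) keep <- keep & at$element %in% element
  which(keep)
}

#' Load a mask configuration and resolve it against a reference structure
#'
#' The config is YAML of the form
#' ```
#' masks:
#'   - name: Palm
#'     chain: A
#'     residues: [815, 910]     # inclusive range
#'   - name: Fingers
#'     chain: A
#'     residues: [[911, 1000], [1050, 1060]]   # multiple segments
#' ```
#' Every residue named by the config must exist in the reference structure;
#' unresolvable residues raise an error listing them. Overlapping masks are
#' allowed (a residue may serve several selections).
#'
#' @param path Path to the YAML mask config.
#' @param ensemble Reference [conf_ensemble()] to resolve against.
#' @return Named list of [subdomain_mask()] objects.
#' @export
load_mask_config <- function(path, ensemble) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$masks) || length(cfg$masks) == 0L) {
    abort(sprintf("Mask config '%s' defines no masks.", path))
  }
  masks <- lapply(cfg$masks, function(m) resolve_mask_entry(m, ensemble, path))
  names(masks) <- vapply(masks, `[[`, character(1), "name")
  masks
}

resolve_mask_entry <- function(m, ensemble, path = "<config>") {
  if (is.null(m$name)) abort(sprintf("Mask entry in '%s' lacks a name.", path))
  segs <- m$residues
  if (is.null(segs)) abort(sprintf("Mask '%s' lacks a residue range.", m$name))
  if (!is.list(segs[[1]]) && length(segs) == 2L && !is.list(segs)) {
    segs <- list(segs)
  } else if (!is.list(segs[[1]])) {
    segs <- list(unlist(segs))
  }
  wanted <- unique(unlist(lapply(segs, function(s) {
    s <- as.integer(unlist(s))
    if (length(s) != 2L || s[1] > s[2]) {
      abort(sprintf("Mask '%s': residue segment must be [lo, hi].", m$name))
    }
    s[1]:s[2]
  })))
  chain <- m$chain %||% unique(ensemble$atoms$chain)[1]
  present <- unique(ensemble$atoms$resno[ensemble$atoms$chain %in% chain])
  missing <- setdiff(wanted, present)
  if (length(missing) > 0L) {
    abort(sprintf(
      "Mask '%s': residues not present in reference structure (chain %s): %s.",
      m$name, paste(chain, collapse = ","),
      paste(head(missing, 20), collapse = ", ")))
  }
  idx <- select_atoms(ensemble, chain = chain, resno = wanted)
  subdomain_mask(m$name, idx)
}

# ---- Toy topology ----------------------------------------------------------

#' Toy force-field topology
#'
#' Per-atom partial charges (e), Lennard-Jones `sigma` (Angstrom) and
#' `epsilon` (kcal/mol), a bond graph, and residue membership. This is the
#' minimal parameter set the energy-decomposition module needs; it makes no
#' attempt to be a production force field.
#'
#' @param charge,sigma,epsilon Numeric per-atom vectors.
#' @param residue Integer per-atom residue ids.
#' @param bonds Two-column integer matrix of bonded atom-index pairs
#'   (may have zero rows).
#' @param resname Optional character vector of residue names, indexed by
#'   residue id.
#' @return A `toy_topology`.
#' @export
toy_topology <- function(charge, sigma, epsilon, residue, bonds,
                         resname = NULL) {
  n <- length(charge)
  if (length(sigma) != n || length(epsilon) != n || length(residue) != n) {
    abort("charge, sigma, epsilon and residue must have equal length.")
  }
  if (any(!is.finite(charge))) abort("Charges must be finite.")
  if (any(sigma <= 0)) abort("All LJ sigma values must be > 0.")
  if (any(epsilon < 0)) abort("All LJ epsilon values must be >= 0.")
  bonds <- matrix(as.integer(bonds), ncol = 2L)
  if (nrow(bonds) > 0L && (any(bonds < 1L) || any(bonds > n))) {
    abort("Bond graph references atoms outside the topology.")
  }
  structure(
    list(charge = as.numeric(charge), sigma = as.numeric(sigma),
         epsilon = as.numeric(epsilon), residue = as.integer(residue),
         bonds = bonds,
         resname = resname %||%
           paste0("RES", seq_len(max(as.integer(residue))))),
    class = "toy_topology"
  )
}

#' @export
print.toy_topology <- function(x, ...) {
  cat(sprintf("<toy_topology> %d atoms, %d residues, %d bonds, net charge %+.2f e\n",
              length(x$charge), length(unique(x$residue)), nrow(x$bonds),
              sum(x$charge)))
  invisible(x)
}

#' Read / write a toy topology config
#'
#' YAML with an `atoms` list (`charge`, `sigma`, `epsilon`, `residue`) and a
#' `bonds` list of index pairs; optional `resnames`.
#'
#' @param path File path.
#' @return A [toy_topology()] (for the reader); `path` invisibly (writer).
#' @export
read_topology_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$atoms)) abort(sprintf("Topology config '%s' lacks atoms.", path))
  g <- function(f) vapply(cfg$atoms, function(a) as.numeric(a[[f]]), numeric(1))
  bonds <- if (is.null(cfg$bonds)) matrix(integer(0), ncol = 2L) else {
    do.call(rbind, lapply(cfg$bonds, as.integer))
  }
  toy_topology(g("charge"), g("sigma"), g("epsilon"), as.integer(g("residue")),
               bonds, resname = cfg$resnames)
}

#' @rdname read_topology_config
#' @param topology A [toy_topology()].
#' @export
write_topology_config <- function(topology, path) {
  stopifnot(inherits(topology, "toy_topology"))
  atoms <- lapply(seq_along(topology$charge), function(i) {
    list(charge = topology$charge[i], sigma = topology$sigma[i],
         epsilon = topology$epsilon[i], residue = topology$residue[i])
  })
  bonds <- if (nrow(topology$bonds) > 0L) {
    lapply(seq_len(nrow(topology$bonds)), function(i) as.list(topology$bonds[i, ]))
  } else {
    list()
  }
  yaml::write_yaml(list(atoms = atoms, bonds = bonds,
                        resnames = topology$resname), path)
  invisible(path)
}
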