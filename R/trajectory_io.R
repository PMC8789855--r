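#' Construct a single-frame coordinate set
#'
#' A frame is the basic coordinate container: an ordered atom table plus an
#' optional orthorhombic box. Coordinates are in angstrom throughout the
#' package; energies are in kJ/mol.
#'
#' @param atoms Data frame with columns `serial`, `name`, `resname`, `resid`,
#'   `chain`, `element`, `x`, `y`, `z` and optionally `vdw` (assigned from the
#'   bundled element table when absent).
#' @param box Orthorhombic box lengths, a positive length-3 numeric vector in
#'   angstrom, or `NULL` for non-periodic data.
#' @param index Zero-based frame index.
#' @param vdw_overrides Optional named vector of per-element van der Waals
#'   radius overrides (angstrom).
#' @return An object of class `frame`.
#' @export
new_frame <- function(atoms, box = NULL, index = 0L, vdw_overrides = NULL) {
  required <- c("serial", "name", "resname", "resid", "chain", "element",
                "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in atom table")
  if (any(!nzchar(atoms$element)))
    stop("empty element symbols in atom table")
  if (is.null(atoms$vdw))
    atoms$vdw <- vdw_radius(atoms$element, vdw_overrides)
  if (any(atoms$vdw <= 0)) stop("van der Waals radii must be positive")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
      stop("box must be 3 positive lengths (angstrom)")
  }
  structure(list(atoms = atoms, box = box, index = as.integer(index)),
            class = "frame")
}

#' @export
print.frame <- function(x, ...) {
  cat("<frame> ", nrow(x$atoms), " atoms",
      if (!is.null(x$box)) paste0(", box ", paste(round(x$box, 2), collapse = " x "), " A"),
      ", index ", x$index, "\n", sep = "")
  invisible(x)
}

#' Construct a trajectory
#'
#' Frames of one trajectory share a single atom table (the topology); only
#' coordinates vary. Role tags name the atom index sets that the analysis
#' stages operate on (collar side chains, tail termini, the Thr96 reference,
#' water oxygens, the tracked K+ ion, lipid head-group phosphates, and the
#' canonical head-group binding site).
#'
#' @param topology Atom table as for [new_frame()] (coordinate columns
#'   ignored if present).
#' @param coords Numeric array of dimension `n_atoms x 3 x n_frames`.
#' @param box Orthorhombic box (angstrom) shared by all frames, or `NULL`.
#' @param dt Frame spacing in ps (must be positive).
#' @param tags Named list of integer index vectors (roles).
#' @return An object of class `trajectory`.
#' @export
new_trajectory <- function(topology, coords, box = NULL, dt = 10,
                           tags = list()) {
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    stop("coords must be an n_atoms x 3 x n_frames array")
  if (dim(coords)[1] != nrow(topology))
    stop("topology/coords atom count mismatch")
  if (dt <= 0) stop("dt must be positive (ps)")
  topology <- as.data.frame(topology, stringsAsFactors = FALSE)
  if (is.null(topology$vdw)) topology$vdw <- vdw_radius(topology$element)
  for (nm in names(tags)) {
    idx <- tags[[nm]]
    if (length(idx) && (min(idx) < 1 || max(idx) > nrow(topology)))
      stop("tag '", nm, "' indexes atoms outside the topology")
  }
  structure(list(topology = topology, coords = coords, box = box,
                 dt = dt, tags = tags),
            class = "trajectory")
}

#' Number of frames in a trajectory
#' @param traj A `trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame from a trajectory
#'
#' @param traj A `trajectory`.
#' @param i Zero-based frame index (frames are 0-indexed throughout).
#' @return A `frame`.
#' @export
get_frame <- function(traj, i) {
  nf <- n_frames(traj)
  if (i < 0 || i >= nf) stop("frame index ", i, " out of range [0, ", nf - 1, "]")
  atoms <- traj$topology
  atoms$x <- traj$coords[, 1, i + 1]
  atoms$y <- traj$coords[, 2, i + 1]
  atoms$z <- traj$coords[, 3, i + 1]
  new_frame(atoms, box = traj$box, index = i)
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", n_frames(x), " frames x ", nrow(x$topology),
      " atoms, dt = ", x$dt, " ps\n", sep = "")
  if (length(x$tags))
    cat("  tags:", paste(names(x$tags), collapse = ", "), "\n")
  invisible(x)
}

# ---- reading -----------------------------------------------------------

.element_from_name <- function(name) {
  # PDB convention: a leading digit belongs to the name, not the element
  e <- sub("^[0-9]*", "", name)
  e <- substr(e, 1, 1)
  toupper(e)
}

.read_pdb_frames <- function(path) {
  if (file.size(path) == 0) stop("empty input file: ", path)
  # light structural validation with line numbers before delegating parsing
  lines <- readLines(path, warn = FALSE)
  atom_lines <- grep("^(ATOM  |HETATM)", lines)
  if (!length(atom_lines)) stop("no ATOM/HETATM records in ", path)
  short <- atom_lines[nchar(lines[atom_lines]) < 54]
  if (length(short))
    stop("malformed ATOM record at line ", short[1], " of ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  bad <- is.na(elem) | !nzchar(trimws(elem))
  elem[bad] <- .element_from_name(at$elety[bad])
  topo <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    resname = trimws(at$resid),
    resid = at$resno,
    chain = ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain),
    element = toupper(trimws(elem)),
    stringsAsFactors = FALSE
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nfr <- nrow(xyz)
  nat <- ncol(xyz) / 3
  if (nat != nrow(topo) && nfr > 1) {
    # bio3d keeps one atom table; per-model counts are consistent by format
    nat <- nrow(topo)
  }
  coords <- array(NA_real_, c(nrow(topo), 3, nfr))
  for (k in seq_len(nfr)) {
    m <- matrix(xyz[k, ], ncol = 3, byrow = TRUE)
    if (nrow(m) != nrow(topo))
      stop("inconsistent atom count across MODEL blocks in ", path)
    coords[, , k] <- m
  }
  box <- NULL
  cry <- grep("^CRYST1", lines, value = TRUE)
  if (length(cry)) {
    b <- as.numeric(c(substr(cry[1], 7, 15), substr(cry[1], 16, 24),
                      substr(cry[1], 25, 33)))
    if (all(is.finite(b)) && all(b > 0) && any(b != 1)) box <- b
  }
  list(topology = topo, coords = coords, box = box)
}

.read_table_frames <- function(path) {
  if (file.size(path) == 0) stop("empty input file: ", path)
  tab <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) stop("cannot parse table file ", path,
                                           ": ", conditionMessage(e)))
  required <- c("frame", "serial", "name", "resname", "resid", "chain",
                "element", "x", "y", "z")
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop("table file ", path, " lacks columns: ", paste(miss, collapse = ", "))
  bad <- which(!complete.cases(tab[, c("x", "y", "z")]))
  if (length(bad))
    stop("malformed coordinate at data line ", bad[1], " of ", path)
  frames <- sort(unique(tab$frame))
  first <- tab[tab$frame == frames[1], ]
  nat <- nrow(first)
  coords <- array(NA_real_, c(nat, 3, length(frames)))
  for (k in seq_along(frames)) {
    fr <- tab[tab$frame == frames[k], ]
    if (nrow(fr) != nat)
      stop("inconsistent atom count across frames in ", path)
    coords[, , k] <- as.matrix(fr[, c("x", "y", "z")])
  }
  topo <- first[, c("serial", "name", "resname", "resid", "chain", "element")]
  rownames(topo) <- NULL
  list(topology = topo, coords = coords, box = NULL)
}

#' Read a single structure
#'
#' Reads the first (or only) model of a coordinate file. Van der Waals radii
#' are assigned from a bundled Bondi-style element table; elements absent
#' from the table receive a carbon-like default of 1.70 angstrom.
#'
#' @param path File path.
#' @param dialect `"pdb"` (single- or multi-MODEL PDB) or `"table"` (CSV with
#'   columns frame, serial, name, resname, resid, chain, element, x, y, z).
#' @param vdw_overrides Optional named per-element radius overrides.
#' @return A `frame`.
#' @export
read_structure <- function(path, dialect = c("pdb", "table"),
                           vdw_overrides = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- if (dialect == "pdb") .read_pdb_frames(path) else .read_table_frames(path)
  atoms <- raw$topology
  atoms$x <- raw$coords[, 1, 1]
  atoms$y <- raw$coords[, 2, 1]
  atoms$z <- raw$coords[, 3, 1]
  new_frame(atoms, box = raw$box, index = 0L, vdw_overrides = vdw_overrides)
}

#' Read a multi-frame trajectory
#'
#' Frames are ordered by model number (PDB) or frame column (table); a
#' constant atom ordering across frames is required and verified.
#'
#' @inheritParams read_structure
#' @param dt Frame spacing, ps.
#' @param tag_config Optional named list of selection expression strings used
#'   to populate role tags (see [default_tag_config()]).
#' @return A `trajectory`.
#' @export
read_trajectory <- function(path, dialect = c("pdb", "table"), dt = 10,
                            tag_config = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- if (dialect == "pdb") .read_pdb_frames(path) else .read_table_frames(path)
  if (dim(raw$coords)[3] < 1) stop("no frames in ", path)
  traj <- new_trajectory(raw$topology, raw$coords, box = raw$box, dt = dt)
  if (!is.null(tag_config)) traj <- resolve_tags(traj, tag_config)
  traj
}

# ---- writing -----------------------------------------------------------

.format_pdb_atom <- function(a) {
  nm <- a$name
  nm <- ifelse(nchar(nm) < 4, sprintf(" %-3s", nm), sprintf("%-4s", nm))
  sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a$serial %% 100000, nm, substr(a$resname, 1, 3), substr(a$chain, 1, 1),
          a$resid %% 10000, a$x, a$y, a$z, 1.0, 0.0, a$element)
}

#' Write a structure or trajectory to file
#'
#' @param x A `frame` or `trajectory`.
#' @param path Output path.
#' @param dialect `"pdb"` or `"table"` (see [read_structure()]).
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, dialect = c("pdb", "table")) {
  dialect <- match.arg(dialect)
  frames <- if (inherits(x, "trajectory"))
    lapply(seq_len(n_frames(x)) - 1L, function(i) get_frame(x, i))
  else list(x)
  if (dialect == "pdb") {
    out <- character(0)
    box <- frames[[1]]$box
    if (!is.null(box))
      out <- c(out, sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                            box[1], box[2], box[3], 90, 90, 90))
    multi <- length(frames) > 1
    for (k in seq_along(frames)) {
      if (multi) out <- c(out, sprintf("MODEL     %4d", k))
      out <- c(out, .format_pdb_atom(frames[[k]]$atoms), "TER")
      if (multi) out <- c(out, "ENDMDL")
    }
    out <- c(out, "END")
    writeLines(out, path)
  } else {
    tabs <- lapply(seq_along(frames), function(k) {
      a <- frames[[k]]$atoms
      data.frame(frame = frames[[k]]$index,
                 a[, c("serial", "name", "resname", "resid", "chain",
                       "element", "x", "y", "z")])
    })
    write.csv(do.call(rbind, tabs), path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_structure
#' @export
write_trajectory <- function(x, path, dialect = c("pdb", "table")) {
  stopifnot(inherits(x, "trajectory"))
  write_structure(x, path, dialect)
}

# ---- selections --------------------------------------------------------

#' Atom selections
#'
#' A selection is a deterministic predicate over the atom-table columns
#' (`name`, `resname`, `resid`, `chain`, `element`), evaluated against a
#' frame's topology. It never depends on coordinates or frame order, so the
#' same selection resolves identically on every frame of a conformant
#' trajectory.
#'
#' @param expr Unquoted logical expression over atom-table columns, e.g.
#'   `name == "CD1" & resid == 124`.
#' @param string Alternatively, the expression as a character string.
#' @return An object of class `selection`.
#' @examples
#' sel <- selection(resname == "LEU" & resid == 124)
#' @export
selection <- function(expr, string = NULL) {
  e <- if (!is.null(string)) str2lang(string) else substitute(expr)
  structure(list(expr = e), class = "selection")
}

#' Resolve a selection against a frame or trajectory
#'
#' @param sel A `selection` (or character string).
#' @param x A `frame`, `trajectory`, or atom table.
#' @return Sorted integer vector of atom indices (possibly empty).
#' @export
resolve <- function(sel, x) {
  if (is.character(sel)) sel <- selection(string = sel)
  atoms <- if (inherits(x, "frame")) x$atoms
           else if (inherits(x, "trajectory")) x$topology
           else x
  if (!nrow(atoms)) stop("cannot resolve selection on an empty frame")
  keep <- eval(sel$expr, atoms, parent.frame())
  keep[is.na(keep)] <- FALSE
  sort(which(keep))
}

#' Default role-tag configuration
#'
#' Selection expression strings mapping each analysis role to atoms, matching
#' the naming scheme of the synthetic generators; override per dataset (e.g.
#' from a JSON config) for real trajectories.
#'
#' @return Named list of selection strings.
#' @export
default_tag_config <- function() {
  list(
    collar_sidechain = 'resname == "LEU" & name %in% c("CD1", "CD2")',
    tail_terminus = 'resname == "LIP" & name == "C16"',
    reference_T96 = 'resname == "THR" & resid == 96',
    water_O = 'resname == "HOH" & name == "O"',
    ion_K = 'element == "K" & resname == "K"',
    headgroup_P = 'resname == "LIP" & name == "P"',
    site_HRW = 'resname %in% c("HIS", "TRP", "ARG")'
  )
}

#' Populate trajectory role tags from selection expressions
#'
#' @param traj A `trajectory`.
#' @param config Named list of selection strings (see [default_tag_config()]).
#' @return The trajectory with `tags` populated.
#' @export
resolve_tags <- function(traj, config = default_tag_config()) {
  traj$tags <- lapply(config, function(s) resolve(s, traj))
  traj
}

# ---- geometry helpers --------------------------------------------------

#' Pairwise distances with the minimum-image convention
#'
#' @param A,B Coordinate matrices (n x 3 and m x 3, angstrom).
#' @param box Orthorhombic box lengths or `NULL` to disable periodicity.
#' @return n x m matrix of distances.
#' @export
pair_dists <- function(A, B, box = NULL) {
  A <- matrix(A, ncol = 3)
  B <- matrix(B, ncol = 3)
  d2 <- matrix(0, nrow(A), nrow(B))
  for (k in 1:3) {
    dk <- outer(A[, k], B[, k], "-")
    if (!is.null(box)) dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

frame_xyz <- function(frame, idx = NULL) {
  a <- frame$atoms
  if (!is.null(idx)) a <- a[idx, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}
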