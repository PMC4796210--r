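# Molecular structures: atom tables, PDB input/output, containers.

.atom_cols <- c("serial", "name", "element", "resname", "resno", "chain",
                "x", "y", "z", "charge", "vdw_class", "hbond_role",
                "is_heavy")

#' Empty atom table
#'
#' Zero-row data frame with the canonical atom columns.
#' @export
empty_atoms <- function() {
  data.frame(serial = integer(), name = character(), element = character(),
             resname = character(), resno = integer(), chain = character(),
             x = numeric(), y = numeric(), z = numeric(),
             charge = numeric(), vdw_class = character(),
             hbond_role = character(), is_heavy = logical(),
             stringsAsFactors = FALSE)
}

#' Build a molecular structure from an atom table
#'
#' The atom table is a data frame with one row per atom and columns
#' `serial`, `name`, `element`, `resname`, `resno`, `chain`, `x`, `y`, `z`
#' plus (after typing) `charge`, `vdw_class`, `hbond_role`, `is_heavy`.
#'
#' @param atoms atom data frame.
#' @param role one of `"receptor"`, `"ligand"`, `"water"`.
#' @param provenance free-text origin tag.
#' @return an object of class `MolecularStructure`.
#' @export
new_structure <- function(atoms, role = "receptor", provenance = "") {
  stopifnot(is.data.frame(atoms))
  for (col in c("charge", "vdw_class", "hbond_role", "is_heavy")) {
    if (is.null(atoms[[col]])) {
      atoms[[col]] <- if (col == "charge") NA_real_
                      else if (col == "is_heavy") !(atoms$element %in% "H")
                      else NA_character_
    }
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  if (anyDuplicated(atoms$serial)) stop("duplicate atom serials")
  structure(list(atoms = atoms[, .atom_cols], role = role,
                 provenance = provenance),
            class = "MolecularStructure")
}

#' @export
print.MolecularStructure <- function(x, ...) {
  cat(sprintf("MolecularStructure <%s>: %d atoms (%d heavy), %d residues\n",
              x$role, nrow(x$atoms), sum(x$atoms$is_heavy, na.rm = TRUE),
              nrow(unique(x$atoms[, c("chain", "resno")]))))
  invisible(x)
}

#' Atom coordinates as a matrix
#'
#' @param structure a `MolecularStructure`.
#' @return numeric matrix (n x 3), A.
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Assemble a receptor complex
#'
#' A receptor complex holds a receptor, an optional ligand and a table of
#' explicit waters.  A complex is pseudo-apo if and only if it has no
#' ligand.
#'
#' @param receptor `MolecularStructure` with role receptor.
#' @param ligand optional `MolecularStructure` with role ligand.
#' @param waters water table as produced by [new_waters()]; may be empty.
#' @return an object of class `ReceptorComplex`.
#' @export
new_complex <- function(receptor, ligand = NULL, waters = new_waters()) {
  structure(list(receptor = receptor, ligand = ligand, waters = waters),
            class = "ReceptorComplex")
}

#' @export
print.ReceptorComplex <- function(x, ...) {
  cat(sprintf("ReceptorComplex: %d receptor atoms, %s, %d waters (%s)\n",
              nrow(x$receptor$atoms),
              if (is.null(x$ligand)) "apo" else
                sprintf("%d ligand atoms", nrow(x$ligand$atoms)),
              nrow(x$waters),
              if (is.null(x$ligand)) "pseudo-apo candidate" else "holo"))
  invisible(x)
}

is_apo <- function(complex) is.null(complex$ligand)

#' Collect all environment atoms of a complex
#'
#' Concatenates receptor, ligand and water atoms into a single typed atom
#' table (waters are expanded to O, H1, H2 records).  Used as the
#' "environment" for probe-field and pairwise energy evaluations.
#'
#' @param complex a `ReceptorComplex` (or a single `MolecularStructure`).
#' @param include character subset of `c("receptor","ligand","water")`.
#' @return atom data frame.
#' @export
env_atoms <- function(complex,
                      include = c("receptor", "ligand", "water")) {
  if (inherits(complex, "MolecularStructure")) return(complex$atoms)
  parts <- list()
  if ("receptor" %in% include) parts$receptor <- complex$receptor$atoms
  if ("ligand" %in% include && !is.null(complex$ligand)) {
    parts$ligand <- complex$ligand$atoms
  }
  if ("water" %in% include && nrow(complex$waters) > 0) {
    parts$water <- water_atoms(complex$waters)
  }
  if (length(parts) == 0) return(empty_atoms())
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out$serial <- seq_len(nrow(out))
  out
}

# ---- PDB input/output -------------------------------------------------------

parse_pdb_lines <- function(lines) {
  sel <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(sel)) stop("no ATOM/HETATM records found")
  ln <- lines[sel]
  lineno <- which(sel)
  num <- function(s, what, i) {
    v <- suppressWarnings(as.numeric(s))
    bad <- is.na(v) & nzchar(trimws(s))
    if (any(bad) || any(!nzchar(trimws(s)))) {
      stop(sprintf("malformed %s field in PDB record at line %d",
                   what, lineno[which(bad | !nzchar(trimws(s)))[1]]))
    }
    v
  }
  name <- trimws(substr(ln, 13, 16))
  element <- trimws(substr(ln, 77, 78))
  guess <- toupper(substr(gsub("[0-9']", "", name), 1, 1))
  element <- ifelse(nzchar(element), element, guess)
  data.frame(
    record = substr(ln, 1, 6),
    serial = as.integer(num(substr(ln, 7, 11), "serial", NULL)),
    name = name,
    resname = trimws(substr(ln, 18, 20)),
    chain = trimws(substr(ln, 22, 22)),
    resno = as.integer(num(substr(ln, 23, 26), "residue number", NULL)),
    x = num(substr(ln, 31, 38), "x", NULL),
    y = num(substr(ln, 39, 46), "y", NULL),
    z = num(substr(ln, 47, 54), "z", NULL),
    element = toupper(element),
    stringsAsFactors = FALSE
  )
}

#' Read a PDB file into a receptor complex
#'
#' ATOM/HETATM records are partitioned into receptor, ligand and waters.
#' Waters are all `HOH` residues; the ligand is the non-water HETATM group
#' (residue) with the largest heavy-atom count; everything else is receptor.
#' Crystallographic waters lacking hydrogens get canonical hydrogens so the
#' three-site geometry invariant holds.  All structures are atom-typed on
#' the way in.
#'
#' @param path PDB file path.
#' @return a `ReceptorComplex`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty PDB file: ", path)
  tab <- parse_pdb_lines(lines)
  tab$is_heavy <- tab$element != "H"

  is_water <- tab$resname == "HOH"
  het <- tab$record == "HETATM" & !is_water
  lig_rows <- integer(0)
  if (any(het)) {
    key <- paste(tab$resname, tab$chain, tab$resno)[het]
    heavy <- tab$is_heavy[het]
    counts <- tapply(heavy, key, sum)
    best <- names(counts)[which.max(counts)]
    lig_rows <- which(het)[key == best]
  }

  mk <- function(rows, role) {
    at <- tab[rows, c("serial", "name", "element", "resname", "resno",
                      "chain", "x", "y", "z", "is_heavy"), drop = FALSE]
    rownames(at) <- NULL
    assign_atom_types(new_structure(at, role = role, provenance = path))
  }

  rec_rows <- which(!is_water & !(seq_len(nrow(tab)) %in% lig_rows))
  receptor <- mk(rec_rows, "receptor")
  ligand <- if (length(lig_rows)) mk(lig_rows, "ligand") else NULL

  waters <- new_waters()
  if (any(is_water)) {
    wt <- tab[is_water, , drop = FALSE]
    for (k in unique(paste(wt$chain, wt$resno))) {
      g <- wt[paste(wt$chain, wt$resno) == k, , drop = FALSE]
      o <- g[g$element == "O", , drop = FALSE]
      if (nrow(o) != 1) stop("water residue without a single oxygen: ", k)
      h <- g[g$element == "H", , drop = FALSE]
      if (nrow(h) == 2) {
        waters <- rbind(waters, water_row(
          as.numeric(o[1, c("x", "y", "z")]),
          as.numeric(h[1, c("x", "y", "z")]),
          as.numeric(h[2, c("x", "y", "z")])))
      } else {
        waters <- rbind(waters, make_water(as.numeric(o[1, c("x", "y", "z")])))
      }
    }
  }
  new_complex(receptor, ligand, waters)
}

fmt_pdb_atom <- function(serial, name, resname, chain, resno, xyz, element,
                         record = "ATOM") {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else substr(name, 1, 4)
  sprintf("%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial %% 100000, nm, resname, chain, resno %% 10000,
          xyz[1], xyz[2], xyz[3], 1, 0, element)
}

#' Write a receptor complex as PDB
#'
#' Receptor atoms are written as ATOM records, ligand atoms as HETATM, and
#' waters as HOH residues with explicit hydrogens (three records each).
#'
#' @param complex a non-empty `ReceptorComplex`.
#' @param path output file path.
#' @export
write_pdb <- function(complex, path) {
  n_total <- nrow(complex$receptor$atoms) +
    (if (is.null(complex$ligand)) 0 else nrow(complex$ligand$atoms)) +
    nrow(complex$waters)
  if (n_total == 0) stop("refusing to write an empty complex")
  out <- character(0)
  serial <- 0
  emit <- function(at, record) {
    vapply(seq_len(nrow(at)), function(i) {
      serial <<- serial + 1
      fmt_pdb_atom(serial, at$name[i], at$resname[i], at$chain[i],
                   at$resno[i], c(at$x[i], at$y[i], at$z[i]),
                   at$element[i], record)
    }, character(1))
  }
  out <- c(out, emit(complex$receptor$atoms, "ATOM"))
  if (!is.null(complex$ligand)) {
    out <- c(out, emit(complex$ligand$atoms, "HETATM"))
  }
  if (nrow(complex$waters) > 0) {
    wa <- water_atoms(complex$waters)
    wa$resno <- wa$resno + 9000L  # avoid clashing with receptor numbering
    out <- c(out, emit(wa, "HETATM"))
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

# ---- atom typing ------------------------------------------------------------

.typing_cache <- new.env(parent = emptyenv())

default_typing_table <- function() {
  if (is.null(.typing_cache$tab)) {
    path <- system.file("extdata", "atom_types.yaml", package = "hydrosite")
    if (!nzchar(path)) path <- file.path("inst", "extdata", "atom_types.yaml")
    .typing_cache$tab <- yaml::read_yaml(path)
  }
  .typing_cache$tab
}

#' Assign simplified force-field atom types
#'
#' Every atom gains a van der Waals class, a partial charge and a
#' hydrogen-bond role from a packaged lookup keyed by (residue name, atom
#' name), with an element-level fallback (neutral charge) for unknown
#' combinations.  Carbon atoms never end up as donors or acceptors.
#'
#' @param structure a `MolecularStructure`.
#' @param table optional typing table (parsed YAML list) overriding the
#'   packaged one.
#' @return the structure with typed atoms.
#' @export
assign_atom_types <- function(structure, table = default_typing_table()) {
  at <- structure$atoms
  n <- nrow(at)
  vdw <- character(n); q <- numeric(n); hb <- character(n)
  for (i in seq_len(n)) {
    entry <- table$residues[[at$resname[i]]][[at$name[i]]]
    if (is.null(entry)) entry <- table$elements[[at$element[i]]]
    if (is.null(entry)) {
      stop(sprintf("cannot type atom %s %s/%s%d (element '%s' unknown)",
                   at$name[i], at$resname[i], at$chain[i], at$resno[i],
                   at$element[i]))
    }
    vdw[i] <- entry$vdw; q[i] <- entry$q; hb[i] <- entry$hb
  }
  at$vdw_class <- vdw
  at$charge <- q
  at$hbond_role <- hb
  at$is_heavy <- at$element != "H"
  structure$atoms <- at
  structure
}

# ---- structure edits --------------------------------------------------------

.backbone_names <- c("N", "CA", "C", "O", "OXT", "H", "HA", "CB")

#' Mutate a residue to alanine
#'
#' Deletes the side-chain atoms beyond C-beta, retypes C-beta as the alanine
#' methyl carbon and renames the residue ALA.  Backbone coordinates are
#' untouched.  Mutating GLY is an error (no C-beta); mutating ALA is a
#' no-op and is flagged via the `"noop"` attribute on the result.
#'
#' @param complex a `ReceptorComplex`.
#' @param chain chain identifier.
#' @param residue_number residue number.
#' @return the edited complex (attribute `noop` is `TRUE` for ALA->ALA).
#' @export
mutate_to_alanine <- function(complex, chain, residue_number) {
  at <- complex$receptor$atoms
  sel <- at$chain == chain & at$resno == residue_number
  if (!any(sel)) {
    stop(sprintf("residue %s/%d not found", chain, residue_number))
  }
  resname <- unique(at$resname[sel])
  if (length(resname) != 1) stop("inconsistent residue names at target")
  if (resname == "GLY") stop("cannot mutate GLY to ALA: no C-beta")
  if (resname == "ALA") {
    return(structure(complex, noop = TRUE))
  }
  drop <- sel & !(at$name %in% .backbone_names)
  at <- at[!drop, , drop = FALSE]
  sel2 <- at$chain == chain & at$resno == residue_number
  at$resname[sel2] <- "ALA"
  rownames(at) <- NULL
  complex$receptor$atoms <- at
  complex$receptor <- assign_atom_types(complex$receptor)
  structure(complex, noop = FALSE)
}

#' Remove the ligand from a complex
#'
#' Produces the pseudo-apo form: the ligand is dropped, receptor and waters
#' are untouched.
#'
#' @param complex a holo `ReceptorComplex`.
#' @return the pseudo-apo complex.
#' @export
make_pseudo_apo <- function(complex) {
  if (is_apo(complex)) stop("complex is already apo")
  complex$ligand <- NULL
  complex
}

#' Strip a terminal substituent from a ligand
#'
#' Removes a terminal heavy atom (exactly one heavy-atom neighbour within
#' 1.8 A) together with its bonded hydrogens, and caps the attachment atom
#' with one hydrogen along the vacated bond vector at 1.09 A.  All other
#' atoms are untouched.
#'
#' @param ligand a typed `MolecularStructure` with role ligand.
#' @param atom_serial serial of the atom to strip.
#' @return the edited ligand.
#' @export
strip_substituent <- function(ligand, atom_serial) {
  at <- ligand$atoms
  i <- which(at$serial == atom_serial)
  if (length(i) != 1) stop("atom serial not found: ", atom_serial)
  if (!at$is_heavy[i]) stop("target atom is a hydrogen")
  xyz <- coords(ligand)
  d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
  heavy_nb <- which(d < 1.8 & d > 1e-6 & at$is_heavy)
  if (length(heavy_nb) != 1) {
    stop("atom is not terminal (", length(heavy_nb),
         " heavy neighbours); stripping would fragment the ligand")
  }
  h_nb <- which(d < 1.3 & d > 1e-6 & !at$is_heavy)
  j <- heavy_nb
  bond <- xyz[i, ] - xyz[j, ]
  bond <- bond / sqrt(sum(bond^2))
  cap <- xyz[j, ] + 1.09 * bond
  keep <- setdiff(seq_len(nrow(at)), c(i, h_nb))
  at2 <- at[keep, , drop = FALSE]
  hrow <- at[j, , drop = FALSE]
  hrow$serial <- max(at$serial) + 1L
  hrow$name <- "H99"; hrow$element <- "H"
  hrow$x <- cap[1]; hrow$y <- cap[2]; hrow$z <- cap[3]
  hrow$is_heavy <- FALSE
  at2 <- rbind(at2, hrow)
  rownames(at2) <- NULL
  ligand$atoms <- at2
  assign_atom_types(ligand)
}
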