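#' @importFrom stats setNames
NULL

.atom_columns <- c("atom_name", "element", "x", "y", "z",
                   "residue_name", "residue_number", "chain_id",
                   "alt_loc", "occupancy", "het")

#' Construct a structure model
#'
#' Lightweight container for an atomic model: one data frame of atom records
#' (coordinates in Angstrom) plus free-form metadata. All downstream stages
#' (pigment extraction, geometry, networks, censuses) consume this type.
#'
#' @param atoms data frame with columns `atom_name`, `element`, `x`, `y`, `z`,
#'   `residue_name`, `residue_number`, `chain_id`, and optionally `alt_loc`,
#'   `occupancy`, `het` (logical HETATM flag, default `TRUE` for residues that
#'   are not standard amino acids).
#' @param metadata named list carried along unchanged.
#' @return object of class `structure_model` with elements `atoms`, `chains`,
#'   `metadata`.
#' @export
structure_model <- function(atoms, metadata = list()) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (nrow(atoms) > 0) {
    needed <- c("atom_name", "x", "y", "z", "residue_name",
                "residue_number", "chain_id")
    missing_cols <- setdiff(needed, names(atoms))
    if (length(missing_cols) > 0) {
      stop("atoms is missing column(s): ", paste(missing_cols, collapse = ", "))
    }
    if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
      stop("non-finite coordinates in atom table")
    }
    if (any(!nzchar(atoms$residue_name) | is.na(atoms$residue_name))) {
      stop("empty residue_name in atom table")
    }
  }
  if (is.null(atoms$element)) atoms$element <- .element_from_name(atoms$atom_name)
  if (is.null(atoms$alt_loc)) atoms$alt_loc <- rep("", nrow(atoms))
  if (is.null(atoms$occupancy)) atoms$occupancy <- rep(1, nrow(atoms))
  if (is.null(atoms$het)) {
    atoms$het <- !(atoms$residue_name %in% names(.aa_residue_masses))
  }
  atoms <- atoms[, .atom_columns, drop = FALSE]
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms,
         chains = sort(unique(as.character(atoms$chain_id))),
         metadata = metadata),
    class = "structure_model"
  )
}

# Crude element guess from an atom name: leading letters, digits stripped,
# two-letter metals recognised.
.element_from_name <- function(nm) {
  if (length(nm) == 0) return(character(0))
  lead <- toupper(sub("[0-9'].*$", "", nm))
  ifelse(lead %in% c("MG", "FE", "CL", "BR", "ZN", "MN", "NA+"), lead,
         substr(lead, 1, 1))
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model> ", nrow(x$atoms), " atoms, ",
      length(x$chains), " chains (",
      paste(utils::head(x$chains, 10), collapse = ","),
      if (length(x$chains) > 10) ",..." else "", ")\n", sep = "")
  invisible(x)
}

.sniff_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) return("mmcif")
  if (ext %in% c("pdb", "ent")) return("pdb")
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  if (any(grepl("^data_|^_atom_site\\.", head_lines))) return("mmcif")
  if (any(grepl("^(ATOM|HETATM|HEADER|CRYST1)", head_lines))) return("pdb")
  stop("cannot determine coordinate format of ", path,
       " (expected mmCIF or PDB)")
}

#' Read a macromolecular coordinate file
#'
#' Parses mmCIF or PDB into a [structure_model()]. All ATOM and HETATM
#' records are retained with chain and residue identity; where a residue has
#' alternate locations for an atom, exactly one copy is kept (highest
#' occupancy, ties broken by alternate-location label order).
#'
#' @param path coordinate file.
#' @param format `"auto"` (by extension, then content sniffing), `"pdb"`, or
#'   `"mmcif"`.
#' @return a `structure_model`.
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("coordinate file not found: ", path)
  if (format == "auto") format <- .sniff_format(path)
  parsed <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    } else {
      suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    },
    error = function(e) {
      stop("failed to parse ", format, " file ", path, ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  at <- parsed$atom
  atoms <- data.frame(
    atom_name = ifelse(is.na(at$elety), "NA", as.character(at$elety)),
    element = ifelse(is.na(at$elesy), "", as.character(at$elesy)),
    x = at$x, y = at$y, z = at$z,
    residue_name = ifelse(is.na(at$resid), "NA", as.character(at$resid)),
    residue_number = as.integer(at$resno),
    chain_id = ifelse(is.na(at$chain), "", as.character(at$chain)),
    alt_loc = ifelse(is.na(at$alt), "", as.character(at$alt)),
    occupancy = ifelse(is.na(at$o), 1, at$o),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms <- .collapse_alt_locs(atoms)
  structure_model(atoms, metadata = list(source = path, format = format))
}

# Keep one record per (chain, residue, atom name): highest occupancy first,
# then alternate-location label order.
.collapse_alt_locs <- function(atoms) {
  if (nrow(atoms) == 0) return(atoms)
  key <- paste(atoms$chain_id, atoms$residue_number,
               atoms$residue_name, atoms$atom_name, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occupancy, atoms$alt_loc)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
}

#' Write a structure model to mmCIF or PDB
#'
#' PDB output keeps coordinates to 3 decimal places (format limit); mmCIF
#' output keeps 6. `parse_structure(write_structure(m, f), f)` therefore
#' reproduces atom names, residues, chains exactly and coordinates within the
#' format precision.
#'
#' @param model a [structure_model()].
#' @param path output file.
#' @param format `"auto"` (by extension), `"pdb"`, or `"mmcif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "mmcif")) {
  stopifnot(inherits(model, "structure_model"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  at <- model$atoms
  if (format == "pdb") {
    if (nrow(at) == 0) {
      writeLines("END", path)
      return(invisible(path))
    }
    if (any(nchar(at$chain_id) > 1)) {
      stop("PDB dialect limits chain ids to one character; use mmCIF")
    }
    bio3d::write.pdb(
      pdb = NULL, file = path,
      xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
      type = ifelse(at$het, "HETATM", "ATOM"),
      resno = at$residue_number, resid = at$residue_name,
      eleno = seq_len(nrow(at)), elety = at$atom_name,
      chain = at$chain_id, o = at$occupancy, b = rep(0, nrow(at)),
      elesy = at$element
    )
  } else {
    .write_mmcif(at, path)
  }
  invisible(path)
}

# Minimal PDBx/mmCIF atom_site writer (canonical column order).
.write_mmcif <- function(at, path) {
  fields <- c("group_PDB", "id", "type_symbol", "label_atom_id",
              "label_alt_id", "label_comp_id", "label_asym_id",
              "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
              "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
              "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
              "auth_comp_id", "auth_asym_id", "auth_atom_id",
              "pdbx_PDB_model_num")
  header <- c("data_model", "#", "loop_", paste0("_atom_site.", fields))
  if (nrow(at) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  rows <- sprintf(
    "%s %d %s %s %s %s %s 1 %d ? %.6f %.6f %.6f %.2f 0.00 ? %d %s %s %s 1",
    ifelse(at$het, "HETATM", "ATOM"), seq_len(nrow(at)),
    ifelse(nzchar(at$element), at$element, "X"), at$atom_name,
    ifelse(nzchar(at$alt_loc), at$alt_loc, "."), at$residue_name,
    ifelse(nzchar(at$chain_id), at$chain_id, "."), at$residue_number,
    at$x, at$y, at$z, at$occupancy,
    at$residue_number, at$residue_name,
    ifelse(nzchar(at$chain_id), at$chain_id, "."), at$atom_name
  )
  writeLines(c(header, rows, "#"), path)
  invisible(path)
}

#' Construct a pigment instance
#'
#' One cofactor molecule: its class, chain/residue identity, atom records,
#' and a site label. Labels follow the green-lineage antenna nomenclature:
#' chlorins numbered 600-699 get labels like `"a603"`/`"b606"`; everything
#' else is `"chain:resnum"`.
#'
#' @param pigment_class one of [PIGMENT_CLASSES].
#' @param chain_id,residue_number,residue_name residue identity.
#' @param atoms data frame with at least `atom_name`, `x`, `y`, `z`.
#' @param label optional site label; derived if `NULL`.
#' @param degenerate logical: required atoms for the class missing.
#' @return object of class `pigment_instance`.
#' @export
pigment_instance <- function(pigment_class, chain_id, residue_number,
                             residue_name, atoms, label = NULL,
                             degenerate = FALSE) {
  stopifnot(pigment_class %in% PIGMENT_CLASSES)
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(label)) {
    label <- if (pigment_class %in% CHLORIN_CLASSES &&
                 residue_number >= 600 && residue_number <= 699) {
      paste0(if (pigment_class == "CHL_A") "a" else "b", residue_number)
    } else {
      paste0(chain_id, ":", residue_number)
    }
  }
  structure(
    list(pigment_class = pigment_class, chain_id = chain_id,
         residue_number = residue_number, residue_name = residue_name,
         atoms = atoms, label = label, degenerate = degenerate),
    class = "pigment_instance"
  )
}

#' @export
print.pigment_instance <- function(x, ...) {
  cat("<pigment_instance> ", x$pigment_class, " ", x$chain_id, ":",
      x$residue_number, " (", x$residue_name, ", ", nrow(x$atoms), " atoms",
      if (x$degenerate) ", DEGENERATE" else "", ")\n", sep = "")
  invisible(x)
}

# Pigment id used as network node name: "chain:resnum".
pigment_id <- function(p) paste0(p$chain_id, ":", p$residue_number)

# Coordinates of named atoms (or all) as an n x 3 matrix.
pigment_coords <- function(p, atom_names = NULL) {
  at <- p$atoms
  if (!is.null(atom_names)) {
    at <- at[match(atom_names, at$atom_name), , drop = FALSE]
    at <- at[!is.na(at$atom_name), , drop = FALSE]
  }
  m <- as.matrix(at[, c("x", "y", "z")])
  rownames(m) <- at$atom_name
  m
}

.is_degenerate_for_class <- function(cls, atom_names, registry) {
  if (cls %in% CHLORIN_CLASSES) {
    has_mg <- "MG" %in% atom_names
    has_n4 <- all(registry$macrocycle_n %in% atom_names)
    return(!(has_mg || has_n4))
  }
  if (cls %in% CAROTENOID_CLASSES) {
    return(sum(atom_names %in% paste0("C", 1:40)) < 4)
  }
  FALSE
}

#' Extract pigment instances from a structure model
#'
#' Emits one [pigment_instance()] per (chain, residue) whose residue code is
#' in the registry map. Residues missing the atoms their class requires
#' (chlorins: MG or the four macrocycle nitrogens; carotenoids: at least four
#' backbone carbons) are kept but flagged degenerate so geometric stages can
#' refuse them explicitly. Unmapped heteroatoms (waters, unmodelled ligands)
#' are ignored.
#'
#' @param model a [structure_model()].
#' @param registry a [default_registry()].
#' @return list of `pigment_instance`, class `pigment_set`, ordered by
#'   (chain, residue number).
#' @export
extract_pigments <- function(model, registry = default_registry()) {
  stopifnot(inherits(model, "structure_model"))
  if (length(registry$map) == 0) stop("registry map is empty")
  at <- model$atoms
  keep <- at$residue_name %in% names(registry$map)
  at <- at[keep, , drop = FALSE]
  out <- list()
  if (nrow(at) > 0) {
    key <- paste(at$chain_id, at$residue_number, at$residue_name, sep = "\r")
    for (k in unique(key)) {
      sub <- at[key == k, , drop = FALSE]
      cls <- unname(registry$map[[sub$residue_name[1]]])
      p <- pigment_instance(
        pigment_class = cls,
        chain_id = sub$chain_id[1],
        residue_number = sub$residue_number[1],
        residue_name = sub$residue_name[1],
        atoms = sub[, c("atom_name", "element", "x", "y", "z")],
        degenerate = .is_degenerate_for_class(cls, sub$atom_name, registry)
      )
      out[[length(out) + 1L]] <- p
    }
  }
  ord <- order(vapply(out, function(p) p$chain_id, ""),
               vapply(out, function(p) p$residue_number, 0))
  structure(out[ord], class = "pigment_set")
}

#' @export
print.pigment_set <- function(x, ...) {
  cls <- vapply(x, function(p) p$pigment_class, "")
  cat("<pigment_set> ", length(x), " pigments\n", sep = "")
  if (length(x)) print(table(cls))
  invisible(x)
}

#' Summarise a pigment set as a data frame
#'
#' @param x a `pigment_set` from [extract_pigments()].
#' @param row.names,optional,... ignored (S3 signature).
#' @return data frame with chain, resnum, class, label, n_atoms, degenerate.
#' @export
as.data.frame.pigment_set <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  data.frame(
    chain = vapply(x, function(p) p$chain_id, ""),
    resnum = vapply(x, function(p) p$residue_number, 0),
    class = vapply(x, function(p) p$pigment_class, ""),
    label = vapply(x, function(p) p$label, ""),
    n_atoms = vapply(x, function(p) nrow(p$atoms), 0),
    degenerate = vapply(x, function(p) p$degenerate, TRUE),
    stringsAsFactors = FALSE
  )
}
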