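#' Pigment classes recognised by the pipeline
#'
#' Character vector of the cofactor classes used throughout the package:
#' chlorophyll a/b, beta-carotene, diadinoxanthin, phylloquinone,
#' Fe4S4 cluster, lipid, and a catch-all.
#'
#' @export
PIGMENT_CLASSES <- c("CHL_A", "CHL_B", "BCAR", "DDX", "PQN",
                     "FE4S4", "LIPID", "OTHER")

#' @rdname PIGMENT_CLASSES
#' @export
CHLORIN_CLASSES <- c("CHL_A", "CHL_B")

#' @rdname PIGMENT_CLASSES
#' @export
CAROTENOID_CLASSES <- c("BCAR", "DDX")

# Chromophore classes counted as "pigment molecules" in census summaries.
CHROMOPHORE_CLASSES <- c("CHL_A", "CHL_B", "BCAR", "DDX")

# Average (not monoisotopic) masses, Da, of the free cofactor molecules.
# Chl a C55H72MgN4O5, Chl b C55H70MgN4O6, beta-carotene C40H56,
# diadinoxanthin C40H54O3, phylloquinone C31H46O2, Fe4S4 cluster, and
# nominal masses for the common thylakoid lipids.
.default_cofactor_masses <- c(
  CLA = 893.49, CHL = 907.47, BCR = 536.87, DD6 = 582.85, DDX = 582.85,
  PQN = 450.70, PHQ = 450.70, SF4 = 351.64,
  SQD = 794.12, LHG = 722.94, LMG = 756.60, DGD = 918.75
)

# Average residue masses (Da, water subtracted) for the 20 standard amino
# acids, keyed by 3-letter code; water added back once per chain.
.aa_residue_masses <- c(
  ALA = 71.08, ARG = 156.19, ASN = 114.10, ASP = 115.09, CYS = 103.14,
  GLU = 129.12, GLN = 128.13, GLY = 57.05, HIS = 137.14, ILE = 113.16,
  LEU = 113.16, LYS = 128.17, MET = 131.19, PHE = 147.18, PRO = 97.12,
  SER = 87.08, THR = 101.10, TRP = 186.21, TYR = 163.18, VAL = 99.13
)

.water_mass <- 18.02

#' Build the pigment registry
#'
#' The registry maps chemical-component residue codes to pigment classes and
#' carries the per-class conventions the geometry and inventory stages need:
#' the atoms that define a chlorin (central MG, macrocycle nitrogens
#' NA/NB/NC/ND), the Qy transition-dipole atom pair, the ordered carotenoid
#' backbone atom names, and cofactor masses for the mass estimate.
#'
#' Default residue-code mapping: CLA -> CHL_A, CHL -> CHL_B, BCR -> BCAR,
#' DD6/DDX -> DDX, PQN/PHQ -> PQN, SF4 -> FE4S4, SQD/LHG/LMG/DGD -> LIPID.
#' Every aspect can be overridden, either programmatically or from a YAML
#' config file (see [read_registry_config()]), because deposited models name
#' pigments by chemical-component code while the literature names them
#' chemically.
#'
#' @param map named character vector, residue code -> pigment class. Replaces
#'   the default mapping entirely when supplied.
#' @param extra_map named character vector merged over the default mapping.
#' @param qy_atoms length-2 character: atom pair defining the Qy dipole
#'   direction (from first to second). Default `c("NB", "ND")`; the common
#'   alternative is `c("NA", "NC")`.
#' @param backbone named list, residue code -> ordered backbone atom names for
#'   polyene dihedral analysis. Defaults to C1..C30 for BCR/DD6/DDX.
#' @param masses named numeric, residue code -> average molecular mass (Da),
#'   merged over the defaults.
#' @return object of class `pigment_registry`.
#' @seealso [extract_pigments()], [cofactor_census()], [mass_estimate()]
#' @examples
#' reg <- default_registry()
#' reg$map[["CLA"]]
#' @export
default_registry <- function(map = NULL, extra_map = NULL,
                             qy_atoms = c("NB", "ND"),
                             backbone = NULL, masses = NULL) {
  base_map <- c(
    CLA = "CHL_A", CHL = "CHL_B", BCR = "BCAR", DD6 = "DDX", DDX = "DDX",
    PQN = "PQN", PHQ = "PQN", SF4 = "FE4S4",
    SQD = "LIPID", LHG = "LIPID", LMG = "LIPID", DGD = "LIPID"
  )
  if (!is.null(map)) {
    base_map <- map
  }
  if (!is.null(extra_map)) {
    base_map[names(extra_map)] <- extra_map
  }
  bad <- setdiff(unique(base_map), PIGMENT_CLASSES)
  if (length(bad) > 0) {
    stop("unknown pigment class(es) in registry map: ",
         paste(bad, collapse = ", "))
  }
  if (anyDuplicated(names(base_map))) {
    stop("registry map has duplicated residue codes")
  }
  if (length(qy_atoms) != 2L || anyNA(qy_atoms)) {
    stop("qy_atoms must be two atom names")
  }
  base_backbone <- list(
    BCR = paste0("C", 1:30),
    DD6 = paste0("C", 1:30),
    DDX = paste0("C", 1:30)
  )
  if (!is.null(backbone)) {
    base_backbone[names(backbone)] <- backbone
  }
  mass_tab <- .default_cofactor_masses
  if (!is.null(masses)) {
    mass_tab[names(masses)] <- masses
  }
  structure(
    list(
      map = base_map,
      qy_atoms = qy_atoms,
      macrocycle_n = c("NA", "NB", "NC", "ND"),
      backbone = base_backbone,
      masses = mass_tab
    ),
    class = "pigment_registry"
  )
}

#' Read registry overrides from a YAML config file
#'
#' The file may contain any of the keys `map`, `extra_map`, `qy_atoms`,
#' `backbone`, `masses`, interpreted as the matching arguments of
#' [default_registry()].
#'
#' @param path YAML file.
#' @return a `pigment_registry`.
#' @export
read_registry_config <- function(path) {
  if (!file.exists(path)) stop("registry config not found: ", path)
  cfg <- yaml::read_yaml(path)
  allowed <- c("map", "extra_map", "qy_atoms", "backbone", "masses")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad) > 0) {
    stop("unknown registry config key(s): ", paste(bad, collapse = ", "))
  }
  args <- list()
  for (key in intersect(allowed, names(cfg))) {
    val <- cfg[[key]]
    args[[key]] <- switch(key,
      map = ,
      extra_map = unlist(val),
      qy_atoms = as.character(unlist(val)),
      backbone = lapply(val, as.character),
      masses = unlist(val)
    )
  }
  do.call(default_registry, args)
}

#' @export
print.pigment_registry <- function(x, ...) {
  cat("<pigment_registry>\n")
  cat("  residue codes:", length(x$map), "mapped to",
      length(unique(x$map)), "classes\n")
  tab <- table(x$map)
  cat(" ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  Qy dipole atoms:", paste(x$qy_atoms, collapse = " -> "), "\n")
  invisible(x)
}
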