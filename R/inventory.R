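#' Cofactor census of a structure model
#'
#' Counts every registry-mapped residue by pigment class, per chain and in
#' total. Protein chains are chains containing at least one standard
#' amino-acid residue. Two summary totals are reported alongside the
#' per-class counts, with their definitions printed in the output so the
#' conventions are auditable:
#' \itemize{
#'   \item `n_chromophores`: CHL_A + CHL_B + BCAR + DDX (light-absorbing
#'     pigments),
#'   \item `n_cofactors`: all registry-mapped residues (chromophores plus
#'     PQN, FE4S4, LIPID, OTHER).
#' }
#'
#' @param model a [structure_model()].
#' @param registry a [default_registry()].
#' @return object of class `cofactor_census`: `per_chain` (chain x class
#'   count matrix), `totals` (named vector over [PIGMENT_CLASSES]),
#'   `n_protein_chains`, `n_chromophores`, `n_cofactors`.
#' @export
cofactor_census <- function(model, registry = default_registry()) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  mapped <- at[at$residue_name %in% names(registry$map), , drop = FALSE]
  if (nrow(mapped) > 0) {
    key <- !duplicated(paste(mapped$chain_id, mapped$residue_number,
                             mapped$residue_name, sep = "\r"))
    res <- mapped[key, , drop = FALSE]
    cls <- unname(registry$map[res$residue_name])
    per_chain <- table(factor(res$chain_id),
                       factor(cls, levels = PIGMENT_CLASSES))
    per_chain <- unclass(per_chain)
  } else {
    per_chain <- matrix(0L, 0, length(PIGMENT_CLASSES),
                        dimnames = list(NULL, PIGMENT_CLASSES))
  }
  totals <- if (nrow(per_chain) > 0) colSums(per_chain) else
    stats::setNames(rep(0L, length(PIGMENT_CLASSES)), PIGMENT_CLASSES)
  aa_chains <- unique(at$chain_id[at$residue_name %in%
                                    names(.aa_residue_masses)])
  structure(
    list(per_chain = per_chain,
         totals = totals,
         n_protein_chains = length(aa_chains),
         n_chromophores = sum(totals[CHROMOPHORE_CLASSES]),
         n_cofactors = sum(totals)),
    class = "cofactor_census"
  )
}

#' @export
print.cofactor_census <- function(x, ...) {
  cat("<cofactor_census>\n")
  nz <- x$totals[x$totals > 0]
  cat("  totals:", if (length(nz)) paste(sprintf("%s=%d", names(nz), nz),
                                         collapse = ", ") else "(empty)", "\n")
  cat("  chromophores (CHL_A+CHL_B+BCAR+DDX):", x$n_chromophores, "\n")
  cat("  cofactors (all mapped residues):    ", x$n_cofactors, "\n")
  cat("  protein chains:", x$n_protein_chains, "\n")
  invisible(x)
}

#' Chlorophyll a/b ratio of a chain (or the whole complex)
#'
#' Ratio of Chl a to Chl b counts. Chains binding no Chl b (the Lhca-type
#' antenna proteins) are flagged `a_only` with an undefined ratio rather
#' than an infinite one.
#'
#' @param census a [cofactor_census()].
#' @param chain chain id; `NULL` for whole-complex totals.
#' @return list with `chl_a`, `chl_b`, `ratio` (`NA` when `a_only`),
#'   `a_only`.
#' @export
chl_ab_ratio <- function(census, chain = NULL) {
  stopifnot(inherits(census, "cofactor_census"))
  if (is.null(chain)) {
    a <- census$totals[["CHL_A"]]
    b <- census$totals[["CHL_B"]]
  } else {
    if (!chain %in% rownames(census$per_chain)) {
      stop("chain ", chain, " not in census")
    }
    a <- census$per_chain[chain, "CHL_A"]
    b <- census$per_chain[chain, "CHL_B"]
  }
  a_only <- b == 0
  list(chl_a = as.integer(a), chl_b = as.integer(b),
       ratio = if (a_only) NA_real_ else a / b,
       a_only = a_only)
}

#' Estimate the molecular mass of the modelled complex
#'
#' Sum of average amino-acid residue masses over polymer residues (one water
#' added per protein chain) plus registry cofactor masses. Residues with no
#' mass entry are excluded from the sum and listed in the gap report, so the
#' estimate is auditable against the model contents.
#'
#' @param model a [structure_model()].
#' @param registry a [default_registry()].
#' @return list with `total_kda`, `protein_kda`, `cofactor_kda`, and `gaps`
#'   (data frame of residue codes without a mass entry and their counts).
#' @export
mass_estimate <- function(model, registry = default_registry()) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  res <- at[!duplicated(paste(at$chain_id, at$residue_number,
                              at$residue_name, sep = "\r")),
            c("chain_id", "residue_number", "residue_name")]
  is_aa <- res$residue_name %in% names(.aa_residue_masses)
  protein_da <- sum(.aa_residue_masses[res$residue_name[is_aa]])
  protein_da <- protein_da + .water_mass * length(unique(res$chain_id[is_aa]))
  has_cof_mass <- res$residue_name %in% names(registry$masses)
  cof_da <- sum(registry$masses[res$residue_name[!is_aa & has_cof_mass]])
  unknown <- res$residue_name[!is_aa & !has_cof_mass &
                                res$residue_name != "HOH"]
  gaps <- if (length(unknown)) {
    as.data.frame(table(residue_name = unknown), stringsAsFactors = FALSE)
  } else {
    data.frame(residue_name = character(0), Freq = integer(0))
  }
  list(total_kda = (protein_da + cof_da) / 1000,
       protein_kda = protein_da / 1000,
       cofactor_kda = cof_da / 1000,
       gaps = gaps)
}

# Find a residue in a model by "chain:resnum" and wrap it as an instance.
.residue_as_instance <- function(model, chain, resnum,
                                 registry = default_registry()) {
  at <- model$atoms
  sub <- at[at$chain_id == chain & at$residue_number == resnum, , drop = FALSE]
  if (nrow(sub) == 0) return(NULL)
  rn <- sub$residue_name[1]
  cls <- if (rn %in% names(registry$map)) unname(registry$map[[rn]]) else "OTHER"
  pigment_instance(cls, chain, resnum, rn,
                   sub[, c("atom_name", "element", "x", "y", "z")])
}

#' Closest-approach distance report
#'
#' Minimum interatomic distance (and the closest atom pair) for a list of
#' residue pair queries, each given as `"chain:resnum"` strings. This is how
#' headline contacts such as a carotenoid head group abutting a core
#' chlorophyll are measured.
#'
#' @param model a [structure_model()].
#' @param queries data frame with columns `a`, `b` (strings `"chain:resnum"`),
#'   or a list of length-2 character vectors.
#' @param registry a [default_registry()].
#' @return data frame with one row per query: `a`, `b`, `distance_A`,
#'   `atom_a`, `atom_b`, `status` (`"ok"`, `"self"`, or `"missing"`). Rows
#'   with missing residues carry `NA` distances; the other rows are still
#'   computed.
#' @export
distance_report <- function(model, queries, registry = default_registry()) {
  if (is.list(queries) && !is.data.frame(queries)) {
    queries <- data.frame(a = vapply(queries, `[`, "", 1),
                          b = vapply(queries, `[`, "", 2),
                          stringsAsFactors = FALSE)
  }
  parse_q <- function(s) {
    parts <- strsplit(s, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("query must be \"chain:resnum\", got ", s)
    list(chain = parts[1], resnum = as.integer(parts[2]))
  }
  rows <- lapply(seq_len(nrow(queries)), function(i) {
    qa <- parse_q(queries$a[i])
    qb <- parse_q(queries$b[i])
    pa <- .residue_as_instance(model, qa$chain, qa$resnum, registry)
    pb <- .residue_as_instance(model, qb$chain, qb$resnum, registry)
    if (is.null(pa) || is.null(pb)) {
      return(data.frame(a = queries$a[i], b = queries$b[i],
                        distance_A = NA_real_, atom_a = NA_character_,
                        atom_b = NA_character_, status = "missing",
                        stringsAsFactors = FALSE))
    }
    md <- min_interatomic_distance(pa, pb)
    data.frame(a = queries$a[i], b = queries$b[i],
               distance_A = md$distance, atom_a = md$atom_a,
               atom_b = md$atom_b,
               status = if (identical(queries$a[i], queries$b[i]))
                 "self" else "ok",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
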