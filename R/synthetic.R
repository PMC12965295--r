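# Seeded generators with known ground truth. Every generated object is a
# regular package type (pigment_instance / structure_model / ta_surface), so
# fixtures exercise the same readers and extractors as real data.

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(seed, code)
}

.MG_N_DIST <- 2.05  # Mg-N coordination distance of the chlorin macrocycle, A

#' Generate a synthetic chlorin with prescribed geometry
#'
#' Places MG at `center` and the macrocycle nitrogens NA/NB/NC/ND at
#' 2.05 Angstrom from the center in the plane perpendicular to `normal`,
#' oriented so the NB -> ND axis equals `qy_direction` (projected into the
#' ring plane if not exactly perpendicular to the normal). Four methine
#' carbons CHA..CHD are added so the ring-plane fit has enough atoms.
#' [magnesium_center()], [qy_dipole()] and [ring_plane()] invert this
#' construction exactly.
#'
#' @param center ring center, Angstrom.
#' @param normal ring-plane normal (any non-zero vector).
#' @param qy_direction desired Qy (NB -> ND) direction.
#' @param kind `"CHL_A"` or `"CHL_B"`.
#' @param chain_id,residue_number residue identity.
#' @param include_mg drop the MG atom when `FALSE` (to exercise the
#'   N-centroid fallback).
#' @param out_of_plane_sd Gaussian jitter (Angstrom) applied along the normal
#'   to the ring atoms, for plane-fit noise studies; uses the current RNG.
#' @return a `pigment_instance`.
#' @export
make_chlorin <- function(center, normal, qy_direction, kind = "CHL_A",
                         chain_id = "A", residue_number = 601,
                         include_mg = TRUE, out_of_plane_sd = 0) {
  stopifnot(kind %in% CHLORIN_CLASSES)
  if (.vnorm(normal) < 1e-12 || .vnorm(qy_direction) < 1e-12) {
    stop("normal and qy_direction must be non-zero vectors")
  }
  nhat <- .unit(as.numeric(normal))
  q <- as.numeric(qy_direction)
  q <- q - sum(q * nhat) * nhat
  if (.vnorm(q) < 1e-9) {
    stop("qy_direction is parallel to the ring normal")
  }
  qhat <- .unit(q)
  phat <- c(nhat[2] * qhat[3] - nhat[3] * qhat[2],
            nhat[3] * qhat[1] - nhat[1] * qhat[3],
            nhat[1] * qhat[2] - nhat[2] * qhat[1])
  center <- as.numeric(center)
  ring <- rbind(
    NB = center - .MG_N_DIST * qhat,
    ND = center + .MG_N_DIST * qhat,
    "NA" = center - .MG_N_DIST * phat,
    NC = center + .MG_N_DIST * phat,
    CHA = center + 3.0 * (qhat + phat) / sqrt(2),
    CHB = center + 3.0 * (-qhat + phat) / sqrt(2),
    CHC = center + 3.0 * (-qhat - phat) / sqrt(2),
    CHD = center + 3.0 * (qhat - phat) / sqrt(2)
  )
  if (out_of_plane_sd > 0) {
    ring <- ring + outer(stats::rnorm(nrow(ring), 0, out_of_plane_sd), nhat)
  }
  xyz <- if (include_mg) rbind(MG = center, ring) else ring
  atoms <- data.frame(
    atom_name = rownames(xyz),
    element = ifelse(rownames(xyz) == "MG", "MG",
                     substr(rownames(xyz), 1, 1)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  )
  pigment_instance(kind, chain_id, residue_number,
                   if (kind == "CHL_A") "CLA" else "CHL", atoms)
}

# NeRF-style internal-coordinate placement: position of the next backbone
# atom given the previous three, bond length r, bond angle theta, torsion phi.
.place_next <- function(a, b, c, r, theta_deg, phi_deg) {
  th <- theta_deg * pi / 180
  ph <- phi_deg * pi / 180
  bc <- .unit(c - b)
  ab <- b - a
  nvec <- c(ab[2] * bc[3] - ab[3] * bc[2],
            ab[3] * bc[1] - ab[1] * bc[3],
            ab[1] * bc[2] - ab[2] * bc[1])
  nhat <- .unit(nvec)
  m <- c(nhat[2] * bc[3] - nhat[3] * bc[2],
         nhat[3] * bc[1] - nhat[1] * bc[3],
         nhat[1] * bc[2] - nhat[2] * bc[1])
  d <- r * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + cbind(bc, m, nhat) %*% d
}

#' Generate a synthetic polyene with prescribed cis bonds
#'
#' Builds a conjugated backbone C1..Cn (n = `n_bonds + 3`, so bonds
#' 2..`n_bonds + 1` have a measurable torsion) with 1.4-Angstrom bonds and
#' 120-degree bond angles, all-trans (180-degree torsions) except for
#' 0-degree torsions at `cis_positions`. [polyene_dihedrals()] followed by
#' [classify_cis_trans()] recovers the planted labels.
#'
#' @param n_bonds number of measurable backbone bonds.
#' @param cis_positions integer bond indices in `2:(n_bonds + 1)` to twist
#'   to cis.
#' @param kind `"BCAR"` or `"DDX"`.
#' @param chain_id,residue_number residue identity.
#' @return a `pigment_instance` with residue code BCR (BCAR) or DD6 (DDX).
#' @export
make_polyene <- function(n_bonds, cis_positions = integer(0), kind = "BCAR",
                         chain_id = "A", residue_number = 701) {
  stopifnot(kind %in% CAROTENOID_CLASSES, n_bonds >= 2)
  valid <- 2:(n_bonds + 1)
  cis_positions <- as.integer(cis_positions)
  if (length(cis_positions) && !all(cis_positions %in% valid)) {
    stop("cis position(s) out of range: valid bond indices are ",
         min(valid), "..", max(valid))
  }
  n_atoms <- n_bonds + 3L
  xyz <- matrix(0, n_atoms, 3)
  xyz[2, ] <- c(1.4, 0, 0)
  xyz[3, ] <- xyz[2, ] + 1.4 * c(cos(pi / 3), sin(pi / 3), 0)
  for (i in 4:n_atoms) {
    bond <- i - 2L  # torsion about bond (i-2, i-1) is set by atom i
    phi <- if (bond %in% cis_positions) 0 else 180
    xyz[i, ] <- .place_next(xyz[i - 3, ], xyz[i - 2, ], xyz[i - 1, ],
                            1.4, 120, phi)
  }
  atoms <- data.frame(
    atom_name = paste0("C", seq_len(n_atoms)),
    element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE
  )
  pigment_instance(kind, chain_id, residue_number,
                   if (kind == "BCAR") "BCR" else "DD6", atoms)
}

.chain_id_pool <- c(LETTERS, letters, as.character(0:9))

#' Generate a multi-chain toy complex with known EET ground truth
#'
#' Randomly places and orients chlorins on the requested chains inside a
#' cubic box, enforcing a minimum pairwise Mg-Mg separation by rejection
#' sampling. The ground truth carries each pigment's planted center, ring
#' normal and Qy direction plus the full directed edge table under `params`,
#' computed here by an explicit double loop over pairs — independent of the
#' vectorised [build_network()] path it is used to check.
#'
#' @param n_chains number of chains.
#' @param chlorins_per_chain chlorins on each chain (scalar or length
#'   `n_chains`).
#' @param box cube side, Angstrom.
#' @param min_sep minimum Mg-Mg separation, Angstrom.
#' @param seed RNG seed (fixes the structure bit-for-bit).
#' @param chl_b_per_chain how many chlorins per chain are Chl b (scalar or
#'   per-chain vector); the first residues of each chain.
#' @param params [fret_params()] under which the truth edge table is
#'   computed.
#' @param max_attempts rejection-sampling cap per pigment.
#' @return list with `model` (a [structure_model()]) and `truth` (list:
#'   `pigments` data frame, `edges` data frame, `params`).
#' @export
make_toy_complex <- function(n_chains = 4, chlorins_per_chain = 8,
                             box = 60, min_sep = 8, seed = NULL,
                             chl_b_per_chain = 0,
                             params = fret_params(),
                             max_attempts = 5000) {
  if (n_chains > length(.chain_id_pool)) {
    stop("at most ", length(.chain_id_pool), " chains supported")
  }
  counts <- rep_len(chlorins_per_chain, n_chains)
  nb <- rep_len(chl_b_per_chain, n_chains)
  if (any(nb > counts)) stop("chl_b_per_chain exceeds chlorins_per_chain")
  .with_seed(seed, {
    n_total <- sum(counts)
    centers <- matrix(NA_real_, n_total, 3)
    placed <- 0L
    for (i in seq_len(n_total)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        cand <- stats::runif(3, -box / 2, box / 2)
        if (placed == 0L ||
            min(sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) -
                                cand)^2))) >= min_sep) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("packing failure: could not place pigment ", i, " with ",
             "min_sep = ", min_sep, " in a box of side ", box)
      }
      centers[i, ] <- cand
      placed <- i
    }
    rand_unit <- function() .unit(stats::rnorm(3))
    chains <- rep(.chain_id_pool[seq_len(n_chains)], counts)
    is_b <- unlist(lapply(seq_len(n_chains), function(ci) {
      c(rep(TRUE, nb[ci]), rep(FALSE, counts[ci] - nb[ci]))
    }))
    resnos <- unlist(lapply(counts, function(k) 600L + seq_len(k)))
    pigs <- vector("list", n_total)
    truth_rows <- vector("list", n_total)
    for (i in seq_len(n_total)) {
      nrm <- rand_unit()
      qy <- stats::rnorm(3)
      qy <- qy - sum(qy * nrm) * nrm
      while (.vnorm(qy) < 1e-6) {
        qy <- stats::rnorm(3)
        qy <- qy - sum(qy * nrm) * nrm
      }
      qy <- .unit(qy)
      kind <- if (is_b[i]) "CHL_B" else "CHL_A"
      pigs[[i]] <- make_chlorin(centers[i, ], nrm, qy, kind = kind,
                                chain_id = chains[i],
                                residue_number = resnos[i])
      truth_rows[[i]] <- data.frame(
        id = paste0(chains[i], ":", resnos[i]),
        chain = chains[i], resnum = resnos[i], class = kind,
        cx = centers[i, 1], cy = centers[i, 2], cz = centers[i, 3],
        nx = nrm[1], ny = nrm[2], nz = nrm[3],
        qx = qy[1], qy_ = qy[2], qz = qy[3],
        stringsAsFactors = FALSE
      )
    }
    truth_pig <- do.call(rbind, truth_rows)
    atoms <- do.call(rbind, lapply(pigs, function(p) {
      cbind(p$atoms, residue_name = p$residue_name,
            residue_number = p$residue_number, chain_id = p$chain_id,
            stringsAsFactors = FALSE)
    }))
    atoms$het <- TRUE
    model <- structure_model(atoms)
    edges <- .brute_force_edges(truth_pig, params)
    list(model = model,
         truth = list(pigments = truth_pig, edges = edges, params = params))
  })
}

# Straightforward all-pairs oracle over the planted centers/dipoles.
.brute_force_edges <- function(truth_pig, params) {
  n <- nrow(truth_pig)
  donor <- acceptor <- character(0)
  R_A <- kappa2 <- k_per_ps <- numeric(0)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      xi <- c(truth_pig$cx[i], truth_pig$cy[i], truth_pig$cz[i])
      xj <- c(truth_pig$cx[j], truth_pig$cy[j], truth_pig$cz[j])
      mi <- c(truth_pig$qx[i], truth_pig$qy_[i], truth_pig$qz[i])
      mj <- c(truth_pig$qx[j], truth_pig$qy_[j], truth_pig$qz[j])
      R <- sqrt(sum((xj - xi)^2))
      if (R > params$r_max) next
      rhat <- (xj - xi) / R
      kap <- sum(mi * mj) - 3 * sum(mi * rhat) * sum(mj * rhat)
      C <- .lookup_C(params, truth_pig$class[i], truth_pig$class[j])
      k <- C * kap^2 / (params$n^4 * R^6)
      if (k <= 0) next
      m <- length(donor) + 1L
      donor[m] <- truth_pig$id[i]
      acceptor[m] <- truth_pig$id[j]
      R_A[m] <- R
      kappa2[m] <- kap^2
      k_per_ps[m] <- k
    }
  }
  data.frame(donor = donor, acceptor = acceptor, R_A = R_A,
             kappa2 = kappa2, k_per_ps = k_per_ps, tau_ps = 1 / k_per_ps,
             stringsAsFactors = FALSE)
}

#' Toy supercomplex echoing the PSI-LHCE architecture
#'
#' One core chain of 88 chlorophylls plus 16 antenna chains of 8-16
#' chlorins each, mirroring the architecture of a PSI core ringed by two
#' antenna belts, at realistic packing density. Mainly for network-scale
#' exercises; ground truth as in [make_toy_complex()].
#'
#' @param seed RNG seed.
#' @param params [fret_params()].
#' @return as [make_toy_complex()].
#' @export
make_supercomplex_toy <- function(seed = 1, params = fret_params()) {
  .with_seed(seed, {
    sizes <- c(88L, sample(8:16, 16, replace = TRUE))
    make_toy_complex(n_chains = 17, chlorins_per_chain = sizes,
                     box = 110, min_sep = 7, seed = NULL, params = params)
  })
}

#' Five-component kinetic scheme used for realistic TA simulations
#'
#' Lifetimes 0.36, 3, 15, 72 and 2500 ps: the sub-picosecond intradomain
#' relaxation, a few-picosecond bulk-to-red antenna transfer (3 ps is this
#' package's convention for a component reported only as "a few
#' picoseconds"), two equilibration components (15 and 72 ps, the second
#' being the dominant antenna-to-trap component), and a nanosecond tail from
#' kinetically uncoupled chlorophylls. Each component carries a single
#' Gaussian band; signs mix ground-state bleach (negative) with
#' excited-state absorption (positive), with the 72 ps component dominant.
#'
#' @return list with `lifetimes` (ps) and `dads_spec` (data frame:
#'   `center_nm`, `width_nm`, `amplitude`).
#' @export
ta_scheme_psi_lhce <- function() {
  list(
    lifetimes = c(0.36, 3, 15, 72, 2500),
    dads_spec = data.frame(
      center_nm = c(686, 706, 694, 700, 682),
      width_nm = c(14, 10, 12, 11, 12),
      amplitude = c(-0.8, 0.5, -0.6, -1.0, -0.3)
    )
  )
}

#' Simulate a transient-absorption surface with known ground truth
#'
#' \eqn{\Delta A(t, \lambda) = \sum_i \mathrm{DADS}_i(\lambda)
#' D(t; \tau_i, t_0, \sigma) + \epsilon}, with Gaussian spectral bands,
#' the IRF-convolved decays of [irf_decay()], and homoscedastic Gaussian
#' noise. Default axes are 150 log-spaced delays from 0.05 ps to 7 ns and
#' 60 wavelengths across 640-760 nm; default noise is 1 percent of the peak
#' absolute signal.
#'
#' @param lifetimes distinct positive lifetimes, ps.
#' @param dads_spec data frame `center_nm`, `width_nm`, `amplitude`, one row
#'   per component.
#' @param delays,wavelengths axes (ps, nm).
#' @param irf_sigma Gaussian IRF width, ps.
#' @param t0 time zero, ps.
#' @param noise_frac noise SD as a fraction of `max(abs(signal))`.
#' @param noise_sd absolute noise SD (delta OD); overrides `noise_frac`.
#' @param seed RNG seed.
#' @return list with `surface` (a [ta_surface()]) and `truth` (list:
#'   `lifetimes`, `dads` matrix, `t0`, `sigma`, `noise_sd`).
#' @export
simulate_ta <- function(lifetimes = ta_scheme_psi_lhce()$lifetimes,
                        dads_spec = ta_scheme_psi_lhce()$dads_spec,
                        delays = exp(seq(log(0.05), log(7000),
                                         length.out = 150)),
                        wavelengths = seq(640, 760, length.out = 60),
                        irf_sigma = 0.1, t0 = 0,
                        noise_frac = 0.01, noise_sd = NULL,
                        seed = NULL) {
  if (anyDuplicated(lifetimes)) stop("lifetimes must be distinct")
  if (any(lifetimes <= 0)) stop("lifetimes must be positive")
  if (nrow(dads_spec) != length(lifetimes)) {
    stop("dads_spec needs one row per lifetime")
  }
  dads <- t(vapply(seq_len(nrow(dads_spec)), function(i) {
    dads_spec$amplitude[i] *
      exp(-(wavelengths - dads_spec$center_nm[i])^2 /
            (2 * dads_spec$width_nm[i]^2))
  }, numeric(length(wavelengths))))
  B <- .decay_basis(delays, lifetimes, t0, irf_sigma)
  clean <- B %*% dads
  sd_use <- if (!is.null(noise_sd)) noise_sd else noise_frac * max(abs(clean))
  dA <- .with_seed(seed, {
    clean + if (sd_use > 0) {
      matrix(stats::rnorm(length(clean), 0, sd_use), nrow(clean))
    } else 0
  })
  list(
    surface = ta_surface(delays, wavelengths, dA,
                         irf_sigma = irf_sigma, t0 = t0),
    truth = list(lifetimes = lifetimes, dads = dads, t0 = t0,
                 sigma = irf_sigma, noise_sd = sd_use)
  )
}
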