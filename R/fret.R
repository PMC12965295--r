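#' Parameters of the Forster rate expression
#'
#' The pairwise rate is \eqn{k_{FRET} = C\kappa^2 / (n^4 R^6)} with `R` the
#' Mg-Mg distance in Angstrom, so `C` has units of rate times Angstrom^6 and
#' `k` comes out in ps^-1 when `C` is in ps^-1 Angstrom^6. The overlap-integral
#' factor `C` depends on the donor/acceptor pigment classes (the
#' Chl b -> Chl a overlap differs from Chl a -> Chl a); it can be a single
#' number or a named vector keyed `"DONOR>ACCEPTOR"` (e.g. `"CHL_B>CHL_A"`)
#' with an optional `"default"` entry.
#'
#' The default `C = 1` yields *relative* rates only: the network topology,
#' rankings and pathway structure are meaningful, absolute ps^-1 values are
#' not until a calibrated `C` (and refractive index `n`) is supplied.
#'
#' @param C scalar or named numeric, overlap factor(s), rate * Angstrom^6.
#' @param n refractive index of the protein medium (dimensionless).
#' @param r_max edge-inclusion cutoff on the Mg-Mg distance, Angstrom.
#' @return object of class `fret_params`.
#' @export
fret_params <- function(C = 1.0, n = 1.55, r_max = 30) {
  if (any(C <= 0)) stop("C must be positive")
  if (n <= 0) stop("refractive index n must be positive")
  if (r_max <= 0) stop("r_max must be positive")
  structure(list(C = C, n = n, r_max = r_max), class = "fret_params")
}

.lookup_C <- function(params, donor_class, acceptor_class) {
  C <- params$C
  if (length(C) == 1 && is.null(names(C))) return(unname(C))
  key <- paste0(donor_class, ">", acceptor_class)
  if (key %in% names(C)) return(unname(C[[key]]))
  if ("default" %in% names(C)) return(unname(C[["default"]]))
  stop("no overlap factor C for class pair ", key,
       " and no \"default\" entry")
}

#' Pairwise Forster rate between two transition dipoles
#'
#' @param d,a donor and acceptor `transition_dipole` objects.
#' @param params a [fret_params()].
#' @param donor_class,acceptor_class pigment classes used to look up `C`.
#' @return one-row data frame (an EET edge): `R_A` (Mg-Mg distance,
#'   Angstrom), `kappa2`, `k_per_ps`, `tau_ps` (= 1/k), and
#'   `non_transferring` (`TRUE` when kappa^2 = 0, giving k = 0 and an
#'   infinite transfer time; such edges are excluded from networks).
#' @export
pair_rate <- function(d, a, params = fret_params(),
                      donor_class = "CHL_A", acceptor_class = "CHL_A") {
  R <- .vnorm(a$anchor - d$anchor)
  if (R < 1e-9) stop("coincident dipole anchors")
  k2 <- kappa_squared(d, a)
  C <- .lookup_C(params, donor_class, acceptor_class)
  k <- C * k2 / (params$n^4 * R^6)
  data.frame(R_A = R, kappa2 = k2, k_per_ps = k,
             tau_ps = if (k > 0) 1 / k else Inf,
             non_transferring = k == 0)
}

#' Assemble the excitation-energy-transfer network
#'
#' Computes all ordered donor/acceptor pairs of non-degenerate chlorins with
#' Mg-Mg distance at most `r_max` and positive rate, as a directed edge
#' table. With the default symmetric `C` the two directions of each pair
#' carry equal rates. Nodes are ordered deterministically by (chain, residue
#' number); node ids are `"chain:resnum"`.
#'
#' @param pigments a `pigment_set` (or plain list of `pigment_instance`).
#' @param params a [fret_params()].
#' @param registry a [default_registry()].
#' @return object of class `eet_network`: list with `nodes` (data frame: id,
#'   chain, resnum, class, label), `edges` (data frame: donor, acceptor,
#'   R_A, kappa2, k_per_ps, tau_ps), and `params`.
#' @export
build_network <- function(pigments, params = fret_params(),
                          registry = default_registry()) {
  chlorins <- Filter(function(p) p$pigment_class %in% CHLORIN_CLASSES &&
                       !p$degenerate, pigments)
  if (length(chlorins) < 2) stop("need at least 2 non-degenerate chlorins")
  ord <- order(vapply(chlorins, function(p) p$chain_id, ""),
               vapply(chlorins, function(p) p$residue_number, 0))
  chlorins <- chlorins[ord]
  n <- length(chlorins)
  nodes <- data.frame(
    id = vapply(chlorins, pigment_id, ""),
    chain = vapply(chlorins, function(p) p$chain_id, ""),
    resnum = vapply(chlorins, function(p) p$residue_number, 0),
    class = vapply(chlorins, function(p) p$pigment_class, ""),
    label = vapply(chlorins, function(p) p$label, ""),
    stringsAsFactors = FALSE
  )
  anchors <- t(vapply(chlorins, magnesium_center, numeric(3),
                      registry = registry))
  dips <- t(vapply(chlorins, function(p) qy_dipole(p, registry)$direction,
                   numeric(3)))
  # pairwise kappa via dot-product matrices:
  # kappa_ij = mu_i.mu_j - 3 (mu_i.Rhat_ij)(mu_j.Rhat_ij)
  G <- dips %*% t(anchors)            # G[i,j] = mu_i . x_j
  s <- rowSums(dips * anchors)        # mu_i . x_i
  D2 <- outer(rowSums(anchors^2), rowSums(anchors^2), "+") -
    2 * anchors %*% t(anchors)
  D2[D2 < 0] <- 0
  R <- sqrt(D2)
  Rsafe <- R + diag(1, n)
  proj_d <- (sweep(G, 1, s, "-")) / Rsafe                  # mu_i.(x_j-x_i)/R
  proj_a <- (matrix(s, n, n, byrow = TRUE) - t(G)) / Rsafe # mu_j.(x_j-x_i)/R
  MU <- dips %*% t(dips)
  kappa <- MU - 3 * proj_d * proj_a
  kappa2 <- kappa^2
  Cmat <- matrix(0, n, n)
  for (dc in unique(nodes$class)) {
    for (ac in unique(nodes$class)) {
      Cmat[nodes$class == dc, nodes$class == ac] <- .lookup_C(params, dc, ac)
    }
  }
  K <- Cmat * kappa2 / (params$n^4 * Rsafe^6)
  offdiag <- !diag(TRUE, n)
  sel <- which(offdiag & R <= params$r_max & K > 0, arr.ind = TRUE)
  edges <- data.frame(
    donor = nodes$id[sel[, 1]],
    acceptor = nodes$id[sel[, 2]],
    R_A = R[sel], kappa2 = kappa2[sel],
    k_per_ps = K[sel], tau_ps = 1 / K[sel],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(match(edges$donor, nodes$id),
                       match(edges$acceptor, nodes$id)), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, params = params),
            class = "eet_network")
}

#' @export
print.eet_network <- function(x, ...) {
  cat("<eet_network> ", nrow(x$nodes), " chlorins, ",
      nrow(x$edges), " directed edges (r_max = ", x$params$r_max,
      " A, n = ", x$params$n, ")\n", sep = "")
  invisible(x)
}

# Resolve a grouping spec to a named vector node id -> subunit.
.resolve_grouping <- function(net, grouping) {
  if (is.null(grouping)) {
    g <- stats::setNames(net$nodes$chain, net$nodes$id)
  } else {
    g <- grouping[net$nodes$id]
    if (anyNA(g)) {
      stop("ungrouped node(s): ",
           paste(net$nodes$id[is.na(g)], collapse = ", "))
    }
    names(g) <- net$nodes$id
  }
  g
}

#' Inter-subunit rate matrix
#'
#' Aggregates the directed edge table over a pigment -> subunit grouping:
#' entry (i, j) is the summed rate over all edges from subunit i pigments to
#' subunit j pigments. The diagonal (intra-subunit transfer) is set to zero.
#'
#' @param net an [build_network()] result.
#' @param grouping named character vector, node id -> subunit name; default
#'   groups by chain.
#' @return square numeric matrix, subunits in sorted order; rates in the
#'   units of the network (ps^-1 under a calibrated `C`).
#' @export
intersubunit_matrix <- function(net, grouping = NULL) {
  stopifnot(inherits(net, "eet_network"))
  g <- .resolve_grouping(net, grouping)
  subs <- sort(unique(unname(g)))
  m <- matrix(0, length(subs), length(subs), dimnames = list(subs, subs))
  if (nrow(net$edges) > 0) {
    ds <- g[net$edges$donor]
    as_ <- g[net$edges$acceptor]
    keep <- ds != as_
    if (any(keep)) {
      agg <- tapply(net$edges$k_per_ps[keep],
                    list(factor(ds[keep], levels = subs),
                         factor(as_[keep], levels = subs)), sum)
      agg[is.na(agg)] <- 0
      m <- m + agg
    }
  }
  m
}

#' Fastest transfer pathways between two subunits
#'
#' Ranks simple paths from any pigment of the source subunit to any pigment
#' of the sink subunit by total transfer time, the sum of per-hop times
#' \eqn{\tau = 1/k} (mean first-passage time along a chain under
#' irreversible hopping). The alternative cost `"neglog"` ranks by branching
#' probability: each hop costs \eqn{-\log(k_{ij} / \sum_l k_{il})}. Ties are
#' broken by fewer hops, then lexicographic node order.
#'
#' @param net an [build_network()] result.
#' @param from_subunit,to_subunit subunit names under `grouping`.
#' @param k_paths maximum number of paths returned.
#' @param grouping as in [intersubunit_matrix()].
#' @param cost `"time"` (default) or `"neglog"`.
#' @return data frame with one row per path: `path` (node ids joined by
#'   `" -> "`), `total_cost` (ps for `"time"`), `n_hops`. Zero rows when the
#'   sink is unreachable.
#' @export
fastest_paths <- function(net, from_subunit, to_subunit, k_paths = 5,
                          grouping = NULL, cost = c("time", "neglog")) {
  stopifnot(inherits(net, "eet_network"))
  cost <- match.arg(cost)
  g <- .resolve_grouping(net, grouping)
  src_nodes <- names(g)[g == from_subunit]
  snk_nodes <- names(g)[g == to_subunit]
  if (length(src_nodes) == 0) stop("no nodes in subunit ", from_subunit)
  if (length(snk_nodes) == 0) stop("no nodes in subunit ", to_subunit)
  ed <- net$edges
  w <- if (cost == "time") {
    ed$tau_ps
  } else {
    ksum <- tapply(ed$k_per_ps, ed$donor, sum)
    -log(ed$k_per_ps / ksum[ed$donor])
  }
  empty <- data.frame(path = character(0), total_cost = numeric(0),
                      n_hops = integer(0), stringsAsFactors = FALSE)
  if (nrow(ed) == 0) return(empty)
  SRC <- ".SRC."
  SNK <- ".SNK."
  edf <- rbind(
    data.frame(from = ed$donor, to = ed$acceptor, weight = w,
               stringsAsFactors = FALSE),
    data.frame(from = SRC, to = src_nodes, weight = 0,
               stringsAsFactors = FALSE),
    data.frame(from = snk_nodes, to = SNK, weight = 0,
               stringsAsFactors = FALSE)
  )
  gr <- igraph::graph_from_data_frame(edf,
                                      vertices = c(net$nodes$id, SRC, SNK))
  if (!is.finite(igraph::distances(gr, v = SRC, to = SNK,
                                   mode = "out")[1, 1])) {
    return(empty)
  }
  # over-request so deterministic tie-breaking survives the truncation
  res <- igraph::k_shortest_paths(gr, from = SRC, to = SNK,
                                  k = k_paths + 10L)
  paths <- lapply(res$vpaths, function(vp) {
    nm <- igraph::as_ids(vp)
    nm[!(nm %in% c(SRC, SNK))]
  })
  paths <- paths[vapply(paths, length, 0L) > 0]
  if (length(paths) == 0) return(empty)
  wlook <- stats::setNames(w, paste(ed$donor, ed$acceptor, sep = "\r"))
  costs <- vapply(paths, function(p) {
    if (length(p) == 1) return(0)
    sum(wlook[paste(p[-length(p)], p[-1], sep = "\r")])
  }, 0)
  hops <- vapply(paths, length, 0L) - 1L
  pstr <- vapply(paths, paste, "", collapse = " -> ")
  keep <- !duplicated(pstr)
  ord <- order(costs[keep], hops[keep], pstr[keep])
  out <- data.frame(path = pstr[keep][ord],
                    total_cost = costs[keep][ord],
                    n_hops = hops[keep][ord],
                    stringsAsFactors = FALSE)
  utils::head(out, k_paths)
}

#' Detect candidate red-chlorophyll pairs
#'
#' Tightly coupled Chl a dimers (the structural signature of red-shifted
#' absorbing pairs such as a603-a609) are flagged by two geometric criteria:
#' Mg-Mg separation at most `d_max` and ring-plane angle at most `angle_max`
#' (near-parallel macrocycles). Each qualifying unordered pair is reported
#' once with its geometry.
#'
#' @param pigments a `pigment_set`.
#' @param d_max Mg-Mg cutoff, Angstrom.
#' @param angle_max interplane-angle cutoff, degrees.
#' @param registry a [default_registry()].
#' @return data frame: `id_a`, `id_b`, `label_a`, `label_b`,
#'   `mg_distance_A`, `interplane_angle_deg`.
#' @export
detect_red_pairs <- function(pigments, d_max = 10, angle_max = 35,
                             registry = default_registry()) {
  chla <- Filter(function(p) p$pigment_class == "CHL_A" && !p$degenerate,
                 pigments)
  out <- data.frame(id_a = character(0), id_b = character(0),
                    label_a = character(0), label_b = character(0),
                    mg_distance_A = numeric(0),
                    interplane_angle_deg = numeric(0),
                    stringsAsFactors = FALSE)
  n <- length(chla)
  if (n < 2) return(out)
  centers <- t(vapply(chla, magnesium_center, numeric(3),
                      registry = registry))
  planes <- lapply(chla, ring_plane, registry = registry)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dmg <- .vnorm(centers[i, ] - centers[j, ])
      if (dmg > d_max) next
      ang <- interplane_angle(planes[[i]], planes[[j]])
      if (ang > angle_max) next
      rows[[length(rows) + 1L]] <- data.frame(
        id_a = pigment_id(chla[[i]]), id_b = pigment_id(chla[[j]]),
        label_a = chla[[i]]$label, label_b = chla[[j]]$label,
        mg_distance_A = dmg, interplane_angle_deg = ang,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows)) out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
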