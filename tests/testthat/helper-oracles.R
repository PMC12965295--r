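# Independent oracles and small fixture builders shared across tests.

# O(n*m) brute-force closest approach between two atom coordinate matrices.
brute_min_distance <- function(ma, mb) {
  best <- Inf
  for (i in seq_len(nrow(ma))) {
    for (j in seq_len(nrow(mb))) {
      d <- sqrt(sum((ma[i, ] - mb[j, ])^2))
      if (d < best) best <- d
    }
  }
  best
}

# Exhaustive simple-path enumeration between two node sets on a directed
# edge table; returns data frame of all paths with costs, sorted by
# (cost, hops, lexicographic path string) — the same tie-break the package
# documents.
enumerate_simple_paths <- function(edges, src_nodes, snk_nodes) {
  adj <- split(seq_len(nrow(edges)), edges$donor)
  out_paths <- character(0)
  out_costs <- numeric(0)
  out_hops <- integer(0)
  walk <- function(node, visited, cost) {
    if (node %in% snk_nodes) {
      out_paths[[length(out_paths) + 1]] <<- paste(visited, collapse = " -> ")
      out_costs[[length(out_costs) + 1]] <<- cost
      out_hops[[length(out_hops) + 1]] <<- length(visited) - 1L
    }
    for (ei in adj[[node]]) {
      nxt <- edges$acceptor[ei]
      if (nxt %in% visited) next
      walk(nxt, c(visited, nxt), cost + edges$tau_ps[ei])
    }
  }
  for (s in src_nodes) walk(s, s, 0)
  ord <- order(out_costs, out_hops, out_paths)
  data.frame(path = out_paths[ord], total_cost = out_costs[ord],
             n_hops = out_hops[ord], stringsAsFactors = FALSE)
}

# Random proper rotation matrix.
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Apply a rigid transform to a pigment instance.
rigid_transform <- function(p, R = diag(3), shift = c(0, 0, 0)) {
  xyz <- as.matrix(p$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, shift, "+")
  p$atoms$x <- xyz[, 1]
  p$atoms$y <- xyz[, 2]
  p$atoms$z <- xyz[, 3]
  p
}

# Hand-build an eet_network from explicit edges (for path-search tests).
manual_network <- function(node_ids, chains, edges_df,
                           params = fret_params()) {
  structure(
    list(
      nodes = data.frame(id = node_ids, chain = chains,
                         resnum = seq_along(node_ids),
                         class = "CHL_A", label = node_ids,
                         stringsAsFactors = FALSE),
      edges = edges_df, params = params
    ),
    class = "eet_network"
  )
}

# A tiny two-chain PDB fixture with one CLA (with alternate locations on one
# atom), one CHL, a water, and a short glycine stretch.
write_two_residue_pdb <- function(path) {
  lines <- c(
    "HETATM    1 MG   CLA A 601      10.000  10.000  10.000  1.00  0.00          MG",
    "HETATM    2 NA   CLA A 601      12.050  10.000  10.000  1.00  0.00           N",
    "HETATM    3 NB   CLA A 601      10.000  12.050  10.000  1.00  0.00           N",
    "HETATM    4 NC   CLA A 601       7.950  10.000  10.000  1.00  0.00           N",
    "HETATM    5 ND   CLA A 601      10.000   7.950  10.000  1.00  0.00           N",
    "HETATM    6 CAA ACLA A 601      11.000  11.000  10.000  0.40  0.00           C",
    "HETATM    7 CAA BCLA A 601      11.100  11.000  10.000  0.60  0.00           C",
    "HETATM    8 MG   CHL B 602      20.000  10.000  10.000  1.00  0.00          MG",
    "HETATM    9 NB   CHL B 602      20.000  12.050  10.000  1.00  0.00           N",
    "HETATM   10 ND   CHL B 602      20.000   7.950  10.000  1.00  0.00           N",
    "HETATM   11  O   HOH B 901      25.000  10.000  10.000  1.00  0.00           O",
    "ATOM     12  CA  GLY B   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM     13  CA  GLY B   2       3.800   0.000   0.000  1.00  0.00           C",
    "END"
  )
  writeLines(lines, path)
  path
}
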