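test_that("pair_rate follows the unit case and the R^-6 / n^-4 laws", {
  d <- transition_dipole(c(0, 0, 0), c(1, 0, 0))
  a <- transition_dipole(c(0, 0, 1), c(1, 0, 0))  # parallel, both
  # perpendicular to the separation: kappa^2 = 1
  e <- pair_rate(d, a, fret_params(C = 1, n = 1, r_max = 100))
  expect_equal(e$kappa2, 1)
  expect_equal(e$k_per_ps, 1)
  expect_equal(e$tau_ps, 1)
  # doubling R at fixed orientation divides k by 2^6
  a2 <- transition_dipole(c(0, 0, 2), c(1, 0, 0))
  e2 <- pair_rate(d, a2, fret_params(C = 1, n = 1, r_max = 100))
  expect_equal(e$k_per_ps / e2$k_per_ps, 64, tolerance = 1e-9)
  # k * R^6 is constant along the R axis
  set.seed(3)
  kR6 <- vapply(runif(20, 1, 60), function(R) {
    aa <- transition_dipole(c(0, 0, R), c(1, 0, 0))
    pair_rate(d, aa, fret_params(C = 1, n = 1, r_max = 100))$k_per_ps * R^6
  }, 0)
  expect_equal(max(abs(kR6 - 1)), 0, tolerance = 1e-9)
  # n = sqrt(2) divides k by 4
  e3 <- pair_rate(d, a, fret_params(C = 1, n = sqrt(2), r_max = 100))
  expect_equal(e$k_per_ps / e3$k_per_ps, 4, tolerance = 1e-9)
  # kappa^2 = 0 edges are flagged non-transferring
  aperp <- transition_dipole(c(0, 0, 1), c(0, 0, 1))
  e4 <- pair_rate(d, aperp, fret_params(C = 1, n = 1, r_max = 100))
  expect_true(e4$non_transferring)
  expect_equal(e4$k_per_ps, 0)
})

test_that("per-class-pair overlap factors are honoured", {
  p <- fret_params(C = c("CHL_B>CHL_A" = 10, default = 2), n = 1,
                   r_max = 100)
  d <- transition_dipole(c(0, 0, 0), c(1, 0, 0))
  a <- transition_dipole(c(0, 0, 1), c(1, 0, 0))
  expect_equal(pair_rate(d, a, p, "CHL_B", "CHL_A")$k_per_ps, 10)
  expect_equal(pair_rate(d, a, p, "CHL_A", "CHL_A")$k_per_ps, 2)
  expect_error(pair_rate(d, a, fret_params(C = c("CHL_A>CHL_A" = 1)),
                         "CHL_B", "CHL_A"), "no overlap factor")
})

test_that("build_network matches collinear closed form and rate symmetry", {
  # three collinear equidistant chlorins, dipoles perpendicular to the axis
  pigs <- structure(lapply(1:3, function(i) {
    make_chlorin(c(0, 0, 5 * (i - 1)), c(1, 0, 0), c(0, 1, 0),
                 chain_id = "A", residue_number = 600 + i)
  }), class = "pigment_set")
  net <- build_network(pigs, fret_params(C = 1, n = 1, r_max = 1e6))
  expect_equal(nrow(net$edges), 6)
  k_near <- net$edges$k_per_ps[net$edges$donor == "A:601" &
                                 net$edges$acceptor == "A:602"]
  k_far <- net$edges$k_per_ps[net$edges$donor == "A:601" &
                                net$edges$acceptor == "A:603"]
  expect_equal(k_near / k_far, 64, tolerance = 1e-9)
  # symmetric C: k(d->a) = k(a->d) exactly
  ed <- net$edges
  rev_k <- mapply(function(d, a) ed$k_per_ps[ed$donor == a & ed$acceptor == d],
                  ed$donor, ed$acceptor)
  expect_identical(ed$k_per_ps, unname(rev_k))
  # r_max below all separations: empty edge set
  net0 <- build_network(pigs, fret_params(r_max = 1))
  expect_equal(nrow(net0$edges), 0)
})

test_that("network edge table equals the generator's brute-force oracle", {
  tc <- make_toy_complex(n_chains = 4, chlorins_per_chain = 10,
                         box = 55, min_sep = 7, seed = 99)
  net <- build_network(extract_pigments(tc$model), tc$truth$params)
  truth <- tc$truth$edges
  key <- function(e) paste(e$donor, e$acceptor)
  expect_setequal(key(net$edges), key(truth))
  m <- merge(net$edges, truth, by = c("donor", "acceptor"))
  expect_equal(m$k_per_ps.x, m$k_per_ps.y, tolerance = 1e-9)
  expect_equal(m$R_A.x, m$R_A.y, tolerance = 1e-9)
  expect_equal(m$kappa2.x, m$kappa2.y, tolerance = 1e-9)
})

test_that("intersubunit matrix aggregates, permutes, and conserves totals", {
  ed <- data.frame(donor = c("A:1", "B:2"), acceptor = c("B:2", "A:1"),
                   R_A = 10, kappa2 = 1, k_per_ps = 0.5, tau_ps = 2,
                   stringsAsFactors = FALSE)
  net <- manual_network(c("A:1", "B:2"), c("A", "B"), ed)
  m <- intersubunit_matrix(net)
  expect_equal(m, matrix(c(0, 0.5, 0.5, 0), 2,
                         dimnames = list(c("A", "B"), c("A", "B"))))
  # random toy: equals an independent filter-and-sum over the edge table,
  # and the off-diagonal sum conserves the aggregate rate
  tc <- make_toy_complex(n_chains = 3, chlorins_per_chain = 6,
                         box = 45, min_sep = 7, seed = 4)
  net2 <- build_network(extract_pigments(tc$model), tc$truth$params)
  m2 <- intersubunit_matrix(net2)
  ed2 <- net2$edges
  chain_of <- function(id) sub(":.*$", "", id)
  for (ci in rownames(m2)) {
    for (cj in colnames(m2)) {
      expected <- if (ci == cj) 0 else
        sum(ed2$k_per_ps[chain_of(ed2$donor) == ci &
                           chain_of(ed2$acceptor) == cj])
      expect_equal(m2[ci, cj], expected)
    }
  }
  inter <- chain_of(ed2$donor) != chain_of(ed2$acceptor)
  expect_equal(sum(m2), sum(ed2$k_per_ps[inter]))
  # permuting the grouping labels conjugates the matrix
  g <- setNames(chain_of(net2$nodes$id), net2$nodes$id)
  g2 <- c(A = "s3", B = "s1", C = "s2")[g]
  names(g2) <- names(g)
  m3 <- intersubunit_matrix(net2, g2)
  remap <- c(A = "s3", B = "s1", C = "s2")
  expect_equal(m3[remap[rownames(m2)], remap[colnames(m2)]], m2,
               ignore_attr = TRUE)
  gbad <- g[-1]
  expect_error(intersubunit_matrix(net2, gbad), "ungrouped")
})

test_that("fastest paths: chain and triangle closed forms, tie-breaks", {
  mk_edges <- function(d, a, tau) {
    data.frame(donor = d, acceptor = a, R_A = 10, kappa2 = 1,
               k_per_ps = 1 / tau, tau_ps = tau, stringsAsFactors = FALSE)
  }
  # linear chain A -> B -> C with tau = 1, 1
  net <- manual_network(c("A:1", "B:1", "C:1"), c("A", "B", "C"),
                        mk_edges(c("A:1", "B:1"), c("B:1", "C:1"), c(1, 1)))
  p <- fastest_paths(net, "A", "C")
  expect_equal(nrow(p), 1)
  expect_equal(p$total_cost, 2)
  expect_equal(p$path, "A:1 -> B:1 -> C:1")
  # triangle: direct slow edge (tau 10) loses to the two-hop route (2 + 2)
  net2 <- manual_network(c("A:1", "B:1", "C:1"), c("A", "B", "C"),
                         mk_edges(c("A:1", "A:1", "B:1"),
                                  c("C:1", "B:1", "C:1"), c(10, 2, 2)))
  p2 <- fastest_paths(net2, "A", "C", k_paths = 2)
  expect_equal(p2$total_cost, c(4, 10))
  expect_equal(p2$path[1], "A:1 -> B:1 -> C:1")
  # cost ties break by fewer hops
  net3 <- manual_network(c("A:1", "B:1", "B:2", "C:1"),
                         c("A", "B", "B", "C"),
                         mk_edges(c("A:1", "A:1", "B:1", "B:2"),
                                  c("B:1", "B:2", "B:2", "C:1"),
                                  c(1, 2, 1, 1)))
  p3 <- fastest_paths(net3, "A", "C", k_paths = 3)
  expect_equal(p3$total_cost[1:2], c(3, 3))
  expect_equal(p3$n_hops[1], 2)  # cost tie broken by fewer hops
  expect_equal(p3$path[1], "A:1 -> B:2 -> C:1")
  # unreachable sink: empty result, not an error
  net4 <- manual_network(c("A:1", "C:1"), c("A", "C"),
                         mk_edges("C:1", "A:1", 1))
  expect_equal(nrow(fastest_paths(net4, "A", "C")), 0)
})

test_that("fastest paths equal exhaustive enumeration on small toy nets", {
  for (s in c(11, 12, 13)) {
    tc <- make_toy_complex(n_chains = 2, chlorins_per_chain = 4,
                           box = 28, min_sep = 7, seed = s)
    net <- build_network(extract_pigments(tc$model), tc$truth$params)
    oracle <- enumerate_simple_paths(
      net$edges,
      net$nodes$id[net$nodes$chain == "A"],
      net$nodes$id[net$nodes$chain == "B"]
    )
    got <- fastest_paths(net, "A", "B", k_paths = 5)
    k <- nrow(got)
    expect_gt(k, 0)
    expect_equal(got$total_cost, oracle$total_cost[seq_len(k)],
                 tolerance = 1e-9)
    expect_equal(got$path[1], oracle$path[1])
  }
})

test_that("red-pair detector keys on distance and coplanarity", {
  mk_pair <- function(sep, tilt_deg, base = c(0, 0, 0), chain = "A",
                      res0 = 601) {
    n2 <- c(sin(tilt_deg * pi / 180), 0, cos(tilt_deg * pi / 180))
    list(make_chlorin(base, c(0, 0, 1), c(1, 0, 0), chain_id = chain,
                      residue_number = res0),
         make_chlorin(base + c(sep, 0, 0), n2, c(0, 1, 0), chain_id = chain,
                      residue_number = res0 + 1))
  }
  close_flat <- structure(mk_pair(8, 0), class = "pigment_set")
  expect_equal(nrow(detect_red_pairs(close_flat, 10, 30)), 1)
  tilted <- structure(mk_pair(8, 80), class = "pigment_set")
  expect_equal(nrow(detect_red_pairs(tilted, 10, 30)), 0)
  # 3 planted pairs among a far-apart background of 34 chlorins
  set.seed(44)
  bg <- lapply(1:34, function(i) {
    make_chlorin(c(20 * (i %% 6), 20 * (i %/% 6), 40), rnorm(3), rnorm(3),
                 chain_id = "B", residue_number = 600 + i)
  })
  planted <- c(mk_pair(8, 10, c(100, 0, 0), "C", 601),
               mk_pair(7, 5, c(100, 50, 0), "C", 611),
               mk_pair(9, 20, c(100, 100, 0), "C", 621))
  allp <- structure(c(bg, planted), class = "pigment_set")
  found <- detect_red_pairs(allp, d_max = 10, angle_max = 35)
  expect_equal(nrow(found), 3)
  expect_true(all(grepl("^C:", found$id_a)))
})
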