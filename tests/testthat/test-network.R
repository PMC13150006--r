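test_that("contact occupancy counts frames below the cutoff, excluding neighbours", {
  # residues 1 and 3: within 4.5 A in 8 of 10 frames
  mk_frames <- function(n_close, n_total = 10, apart = 10) {
    lapply(seq_len(n_total), function(f) {
      d <- if (f <= n_close) 4.0 else apart
      rbind(c(0, 0, 0), c(d, 0, 0))
    })
  }
  traj <- beads_trajectory(mk_frames(8), resno = c(1L, 3L))
  net <- contact_network(traj)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$occupancy, 0.8)
  # 7 of 10 misses the 0.75 occupancy gate
  net7 <- contact_network(beads_trajectory(mk_frames(7), resno = c(1L, 3L)))
  expect_equal(nrow(net7$edges), 0L)
  # sequence-adjacent residues never form an edge
  adj <- contact_network(beads_trajectory(mk_frames(10), resno = c(1L, 2L)))
  expect_equal(nrow(adj$edges), 0L)
  # single frame: correlation is degenerate
  expect_error(contact_network(beads_trajectory(mk_frames(1, n_total = 1), resno = c(1L, 3L))),
               class = "selexp_degenerate_statistics")
})

test_that("edge sets are monotone in cutoff and anti-monotone in occupancy", {
  sim <- simulate_trajectory(n_residues = 8, n_frames = 60,
                             contacts = data.frame(i = c(1L, 4L), j = c(3L, 6L),
                                                   occupancy = c(0.9, 0.78)),
                             seed = 9)
  key <- function(net) paste(net$edges$from, net$edges$to)
  e1 <- key(contact_network(sim$trajectory, cutoff = 4.5))
  e2 <- key(contact_network(sim$trajectory, cutoff = 6.0))
  expect_true(all(e1 %in% e2))
  o1 <- key(contact_network(sim$trajectory, occupancy_min = 0.75))
  o2 <- key(contact_network(sim$trajectory, occupancy_min = 0.85))
  expect_true(all(o2 %in% o1))
})

test_that("perfectly co-moving residues reach unit correlation and zero weight", {
  set.seed(3)
  base <- rbind(c(0, 0, 0), c(4, 0, 0), c(50, 0, 0), c(70, 0, 0))
  frames <- lapply(1:50, function(f) {
    shift <- rnorm(3)
    rbind(base[1, ] + shift, base[2, ] + shift,
          base[3, ] + rnorm(3), base[4, ] + rnorm(3))
  })
  traj <- beads_trajectory(frames, resno = c(1L, 3L, 10L, 20L))
  net <- contact_network(traj, superpose = FALSE)
  e <- net$edges[net$edges$from == "A:1" & net$edges$to == "A:3", ]
  expect_equal(e$correlation, 1, tolerance = 1e-9)
  expect_equal(e$weight, 0, tolerance = 1e-9)
})

test_that("community detection recovers planted cliques and components", {
  clique_edges <- function(ids) {
    p <- t(utils::combn(ids, 2))
    data.frame(from = p[, 1], to = p[, 2])
  }
  # two 4-cliques joined by a single bridge
  edges <- rbind(clique_edges(paste0("a", 1:4)), clique_edges(paste0("b", 1:4)),
                 data.frame(from = "a1", to = "b1"))
  net <- make_network(edges)
  part <- network_communities(net)
  split_a <- unname(part$membership[paste0("a", 1:4)])
  split_b <- unname(part$membership[paste0("b", 1:4)])
  expect_length(unique(split_a), 1L)
  expect_length(unique(split_b), 1L)
  expect_false(split_a[1] == split_b[1])
  # brute-force: the best bipartition by modularity is exactly the two cliques
  bb <- best_bipartition(edges, net$nodes$id)
  expect_setequal(net$nodes$id[bb$side], paste0(substr(net$nodes$id[bb$side][1], 1, 1), 1:4))
  expect_equal(part$modularity, bb$q, tolerance = 1e-9)

  # disconnected components are separate communities
  disc <- make_network(rbind(clique_edges(paste0("a", 1:3)), clique_edges(paste0("b", 1:3))))
  pd <- network_communities(disc)
  expect_equal(length(unique(pd$membership)), 2L)
  # a single triangle is one community
  tri <- network_communities(make_network(clique_edges(c("x", "y", "z"))))
  expect_equal(length(unique(tri$membership)), 1L)
  empty <- make_network(data.frame(from = character(), to = character(),
                                   weight = numeric()), nodes = c("a", "b"))
  expect_error(network_communities(empty), class = "selexp_domain")
})

test_that("communication paths minimise summed edge weights", {
  # path graph a-b-c
  net <- make_network(data.frame(from = c("a", "b"), to = c("b", "c"), weight = c(1, 1)))
  p <- communication_paths(net, "a", "c")
  expect_equal(p$path[[1]], c("a", "b", "c"))
  expect_equal(p$total_weight, 2)
  # triangle: direct edge 5 loses to the 1+1 detour
  tri <- make_network(data.frame(from = c("a", "a", "b"), to = c("c", "b", "c"),
                                 weight = c(5, 1, 1)))
  pt <- communication_paths(tri, "a", "c")
  expect_equal(pt$path[[1]], c("a", "b", "c"))
  expect_equal(pt$total_weight, 2)
  # unreachable sink reported with infinite weight
  disc <- make_network(data.frame(from = "a", to = "b", weight = 1),
                       nodes = c("a", "b", "z"))
  pu <- communication_paths(disc, "a", "z")
  expect_equal(pu$total_weight, Inf)
  expect_length(pu$path[[1]], 0L)
  expect_error(communication_paths(net, "a", "nope"), class = "selexp_unknown_node")
})

test_that("all-pairs paths agree with an independent single-source oracle", {
  set.seed(99)
  for (case in 1:100) {
    n <- 8
    ids <- paste0("n", 1:n)
    pairs <- t(utils::combn(ids, 2))
    keep <- runif(nrow(pairs)) < 0.4
    if (!any(keep)) next
    edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                        weight = runif(sum(keep), 0.1, 2))
    net <- make_network(edges, nodes = ids)
    got <- communication_paths(net, ids, ids)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = ids)
    ref <- igraph::distances(g, weights = igraph::E(g)$weight, algorithm = "dijkstra")
    for (r in seq_len(nrow(got))) {
      expect_equal(got$total_weight[r], ref[got$source[r], got$sink[r]],
                   tolerance = 1e-9)
      # returned paths are walkable and have the stated weight
      pth <- got$path[[r]]
      if (length(pth) > 1) {
        w <- sum(vapply(seq_len(length(pth) - 1), function(k) {
          hit <- (edges$from == pth[k] & edges$to == pth[k + 1]) |
                 (edges$to == pth[k] & edges$from == pth[k + 1])
          min(edges$weight[hit])
        }, 0))
        expect_equal(w, got$total_weight[r], tolerance = 1e-9)
      }
    }
  }
})

test_that("hydrogen bonds require both the distance and the angle gate", {
  mk <- function(acceptor_xyz) {
    at <- data.frame(chain = "A", resno = c(1, 1, 2), resid = c("SER", "SER", "HOH"),
                     elety = c("OG", "HG", "O"), element = c("O", "H", "O"),
                     x = c(0, 1, acceptor_xyz[1]), y = c(0, 0, acceptor_xyz[2]),
                     z = c(0, 0, acceptor_xyz[3]))
    trajectory_ensemble(structure_model(at), list(as.matrix(at[, c("x", "y", "z")])))
  }
  # linear D-H...A at D-A 3.4 A, angle 180 deg: detected
  expect_equal(hbond_occupancy(mk(c(3.4, 0, 0)), donors = 1L, acceptors = 3L)$occupancy, 1)
  # D-A 3.6 A: missed on distance
  expect_equal(hbond_occupancy(mk(c(3.6, 0, 0)), donors = 1L, acceptors = 3L)$occupancy, 0)
  # D-A 3.0 A but D-H-A angle 100 deg: missed on geometry
  u <- c(cos(80 * pi / 180), sin(80 * pi / 180), 0)  # 100 deg from the H->D direction
  r <- (-2 * sum(c(1, 0, 0) * u) + sqrt(4 * sum(c(1, 0, 0) * u)^2 + 4 * (9 - 1))) / 2
  A <- c(1, 0, 0) + r * u
  expect_equal(sqrt(sum(A^2)), 3.0, tolerance = 1e-9)
  expect_equal(hbond_occupancy(mk(A), donors = 1L, acceptors = 3L)$occupancy, 0)
  # donor without an attached hydrogen names the residue
  bare <- data.frame(chain = "A", resno = c(1, 2), resid = c("SER", "HOH"),
                     elety = c("OG", "O"), element = c("O", "O"),
                     x = c(0, 3), y = 0, z = 0)
  traj <- trajectory_ensemble(structure_model(bare), list(as.matrix(bare[, c("x", "y", "z")])))
  expect_error(hbond_occupancy(traj, donors = 1L, acceptors = 2L),
               class = "selexp_no_donor_hydrogen")
})

test_that("chi1 dihedrals follow the IUPAC sign and range conventions", {
  mk_res <- function(cg) {
    at <- data.frame(chain = "A", resno = 1, resid = "LEU",
                     elety = c("N", "CA", "CB", "CG"), element = c("N", "C", "C", "C"),
                     x = c(0, 0, 1, cg[1]), y = c(1, 0, 0, cg[2]), z = c(0, 0, 0, cg[3]))
    trajectory_ensemble(structure_model(at), list(as.matrix(at[, c("x", "y", "z")])))
  }
  plus60 <- c(1.5, cos(pi / 3), sin(pi / 3))
  expect_equal(chi1_series(mk_res(plus60), 1)$chi1, 60, tolerance = 1e-6)
  # mirror reflection (z -> -z) flips the sign
  minus60 <- c(1.5, cos(pi / 3), -sin(pi / 3))
  expect_equal(chi1_series(mk_res(minus60), 1)$chi1, -60, tolerance = 1e-6)
  # the trans rotamer reports +180, never -180
  expect_equal(chi1_series(mk_res(c(1.5, -1, 0)), 1)$chi1, 180, tolerance = 1e-6)
  # agreement with an independent torsion implementation on random geometry
  set.seed(12)
  for (i in 1:20) {
    co <- matrix(rnorm(12), 4, 3)
    at <- data.frame(chain = "A", resno = 1, resid = "LEU",
                     elety = c("N", "CA", "CB", "CG"), element = c("N", "C", "C", "C"),
                     x = co[, 1], y = co[, 2], z = co[, 3])
    traj <- trajectory_ensemble(structure_model(at), list(co))
    ref <- bio3d::torsion.xyz(as.vector(t(co)), atm.inc = 4)
    expect_equal(chi1_series(traj, 1)$chi1, as.numeric(ref), tolerance = 1e-6)
  }
  # missing gamma atom is a named error
  noCG <- data.frame(chain = "A", resno = 1, resid = "ALA",
                     elety = c("N", "CA", "CB"), element = c("N", "C", "C"),
                     x = 0:2, y = 0, z = 0)
  traj <- trajectory_ensemble(structure_model(noCG), list(as.matrix(noCG[, c("x", "y", "z")])))
  expect_error(chi1_series(traj, 1), class = "selexp_missing_atom")
})

test_that("Welch's test matches closed-form values and degenerate conventions", {
  w <- welch_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(w$t, -sqrt(3 / 2), tolerance = 1e-9)    # closed form: -1/sqrt(2/3)
  expect_equal(w$df, 4, tolerance = 1e-9)              # equal n, equal variance
  expect_equal(w$p, 2 * stats::pt(-sqrt(3 / 2), 4), tolerance = 1e-9)
  ident <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  both_const <- welch_test(c(2, 2), c(2, 2))
  expect_equal(both_const$p, 1)
  expect_error(welch_test(1, c(1, 2)), class = "selexp_domain")
  # planted-effect simulation: small occupancy shift at n = 5 is highly significant
  set.seed(8)
  pvals <- replicate(20, {
    a <- pmin(pmax(rnorm(5, 0.9, 0.03), 0), 1)
    b <- pmin(pmax(rnorm(5, 0.2, 0.03), 0), 1)
    welch_test(a, b)$p
  })
  expect_true(all(pvals < 1e-3))
})
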