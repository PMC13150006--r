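test_that("structure parsing partitions receptor and ligand atoms", {
  pdb <- system.file("extdata", "toy_receptor_synthetic.pdb", package = "selexp")
  model <- parse_structure(pdb, ligand_selector = "ALE")
  expect_s3_class(model, "structure_model")
  expect_equal(sum(model$atoms$is_ligand), 2L)
  expect_equal(sum(!model$atoms$is_ligand), 7L)
  expect_setequal(model$atoms$resid[model$atoms$is_ligand], "ALE")
  expect_error(parse_structure(pdb, ligand_selector = "XXX"),
               class = "selexp_ligand_not_found")
  expect_error(parse_structure("no/such/file.pdb"), class = "selexp_io")
})

test_that("binding-site detection respects the distance cutoff exactly", {
  model <- toy_complex()
  # planted: residue 1 at 3.9 A (in), residue 3 at 4.1 A (out), residue 2 remote
  site <- binding_site_residues(model, cutoff = 4.0)
  expect_equal(as.character(site), "A:1")
  expect_equal(attr(site, "details")$min_distance, 3.9)
  # 4.1 A residue enters once the cutoff passes it
  site2 <- binding_site_residues(model, cutoff = 4.2)
  expect_setequal(as.character(site2), c("A:1", "A:3"))
  # monotone in cutoff
  for (cut in c(3, 3.95, 4.2, 6, 20)) {
    expect_true(all(as.character(binding_site_residues(model, cutoff = 3)) %in%
                    as.character(binding_site_residues(model, cutoff = cut))))
  }
  # generic-number relabelling, with a warning for unmapped residues
  numbering <- data.frame(resno = 1, generic_number = "3x36")
  expect_warning(site3 <- binding_site_residues(model, 4.2, numbering), "A:3")
  expect_setequal(as.character(site3), c("3x36", "A:3"))
  # a far-away ligand has no contacts
  far <- model
  far$atoms$x[far$atoms$is_ligand] <- 1000
  expect_length(as.character(binding_site_residues(far, 4.0)), 0L)
})

test_that("region classification follows the packaged table", {
  calls <- structure(
    data.frame(generic_number = c("3x41", "2x60", "3x36", "9x99"),
               consensus_a = "A", conservation_a = 1, consensus_b = "S",
               conservation_b = 1, blosum62 = 1L, is_hotspot = FALSE,
               region = "unassigned", priority = "unset"),
    class = c("hotspot_calls", "data.frame"))
  out <- classify_regions(calls)
  expect_equal(out$region, c("TM3-TM4-TM5", "TM2-TM7", "orthosteric", "unassigned"))
  expect_length(binding_site_positions(), 13L)
  expect_true(all(binding_site_positions() %in%
                  default_region_table()$generic_number[default_region_table()$region == "orthosteric"]))
})

test_that("superposition recovers rigid transforms and is transform-invariant", {
  set.seed(5)
  P <- matrix(rnorm(30), 10, 3)
  expect_equal(superpose_ca(P, P)$rmsd, 0, tolerance = 1e-12)
  expect_equal(superpose_ca(P, sweep(P, 2, c(5, 0, 0), "+"))$rmsd, 0, tolerance = 1e-12)
  for (i in 1:10) {
    # random proper rotation via QR
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    R <- qr.Q(qr_); R <- R * sign(diag(qr.R(qr_))); if (det(R) < 0) R[, 1] <- -R[, 1]
    Q <- P %*% R + matrix(rep(rnorm(3, sd = 10), each = 10), 10, 3)
    s <- superpose_ca(P, Q)
    expect_equal(s$rmsd, 0, tolerance = 1e-8)
    expect_equal(det(s$rotation), 1, tolerance = 1e-8)
    # perturb one atom of Q: rmsd is invariant to extra rigid motion of either input
    Q2 <- Q; Q2[4, ] <- Q2[4, ] + c(1, 0, 0)
    base <- superpose_ca(P, Q2)$rmsd
    expect_equal(superpose_ca(P %*% R, Q2)$rmsd, base, tolerance = 1e-8)
  }
  # cross-check a non-trivial rmsd against bio3d's least-squares fit
  Q3 <- P + matrix(rnorm(30, sd = 0.5), 10, 3)
  ours <- superpose_ca(P, Q3)
  fitted <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(Q3)), mobile = as.vector(t(P))))
  ref_rmsd <- sqrt(mean(colSums(matrix((fitted - as.vector(t(Q3)))^2, nrow = 3))))
  expect_equal(ours$rmsd, ref_rmsd, tolerance = 1e-6)
  expect_error(superpose_ca(P[1:2, ], P[1:2, ]), class = "selexp_domain")
})

test_that("sampled solvent accessibility matches closed forms on toy spheres", {
  lone <- structure_model(data.frame(chain = "A", resno = 1, resid = "ALA",
                                     elety = "CA", element = "C", x = 0, y = 0, z = 0))
  s <- residue_sasa(lone)
  expect_equal(s$asa, 4 * pi * (1.7 + 1.4)^2, tolerance = 1e-9)  # fully exposed
  expect_equal(s$rel_exposure, s$asa / 129, tolerance = 1e-9)
  # an atom caged inside a shell of neighbours is fully buried
  dirs <- rbind(diag(3), -diag(3), sphere_points_for_test(20) * 1)
  cage <- data.frame(chain = "A", resno = c(1, rep(2, nrow(dirs))),
                     resid = c("GLY", rep("ALA", nrow(dirs))),
                     elety = "C", element = "C",
                     x = c(0, dirs[, 1] * 2), y = c(0, dirs[, 2] * 2), z = c(0, dirs[, 3] * 2))
  sb <- residue_sasa(structure_model(cage))
  expect_equal(sb$asa[sb$resno == 1], 0, tolerance = 1e-9)
})

test_that("prioritization combines explicit lists and structural heuristics", {
  calls <- structure(
    data.frame(generic_number = c("3x36", "2x41", "7x38"),
               consensus_a = "V", conservation_a = 1, consensus_b = "S",
               conservation_b = 1, blosum62 = -2L, is_hotspot = TRUE,
               region = "orthosteric", priority = "unset"),
    class = c("hotspot_calls", "data.frame"))
  out <- prioritize(calls, deprioritize = "2x41", exposure_threshold = NA)
  expect_equal(out$priority, c("prioritized", "deprioritized", "prioritized"))
  # heuristics without a structure are an error
  expect_error(prioritize(calls), class = "selexp_needs_structure")

  # toy sphere: residue 1 buried at the centre of a residue-2 cage stays
  # prioritized under the exposure heuristic; the cage itself is exposed
  dirs <- rbind(diag(3), -diag(3), sphere_points_for_test(30))
  cage <- data.frame(chain = "A", resno = c(1, rep(2, nrow(dirs)), 3),
                     resid = c("ALA", rep("GLY", nrow(dirs)), "ALA"),
                     elety = "CA",
                     element = "C",
                     x = c(0, dirs[, 1] * 2.5, 40), y = c(0, dirs[, 2] * 2.5, 0),
                     z = c(0, dirs[, 3] * 2.5, 0))
  model <- structure_model(cage)
  numbering <- data.frame(resno = c(1, 3), generic_number = c("3x36", "2x41"))
  out2 <- prioritize(calls[1:2, ], model, numbering = numbering,
                     exposure_threshold = 0.4)
  expect_equal(out2$priority, c("prioritized", "deprioritized"))  # buried vs lone exposed

  # proximity to a marked intracellular set deprioritizes
  out3 <- prioritize(calls[1:2, ], model, numbering = numbering,
                     exposure_threshold = NA,
                     intracellular = 2, proximity_cutoff = 8)
  expect_equal(out3$priority[1], "deprioritized")  # residue 1 is 2.5 A from the cage
  expect_equal(out3$priority[2], "prioritized")    # residue 3 is 40 A away
})
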