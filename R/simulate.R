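#' Default planted hotspot pairs
#'
#' The five prioritized divergent residue pairs between the beta-adrenergic
#' and D1-like dopaminergic consensus sequences, at their generic positions.
#' Every pair scores below zero under BLOSUM62.
#'
#' @return data.frame with columns \code{generic_number}, \code{residue_a},
#'   \code{residue_b}.
#' @export
default_planted_hotspots <- function() {
  data.frame(
    generic_number = c("3x36", "45x52", "7x38", "2x60", "3x41"),
    residue_a = c("V", "F", "N", "G", "E"),   # beta-adrenergic consensus
    residue_b = c("S", "S", "V", "K", "L")    # D1-like dopaminergic consensus
  )
}

# Generic-number labels for a simulated alignment: the planted labels plus
# background labels spread across TM segments 1-7, in segment order.
generic_label_pool <- function(planted, n_positions) {
  pool <- as.vector(t(outer(1:7, 30:55, function(s, p) paste0(s, "x", p))))
  bg <- setdiff(pool, planted)
  n_bg <- n_positions - length(planted)
  bg <- bg[round(seq(1, length(bg), length.out = n_bg))]
  labels <- c(planted, bg)
  labels[order_generic(labels)]
}

#' Simulate a pair of subfamily alignments with planted hotspots
#'
#' Generates two gapless alignments sharing a column space, where a set of
#' planted positions carries divergent consensus residues (one per group) at
#' a controlled conservation level, and all remaining (background) positions
#' carry a residue identical in both groups. Conservation is enforced exactly
#' by count (\code{floor(conservation * n)} consensus copies), so threshold
#' behaviour is sharp; minority residues are drawn from residues other than
#' either group's consensus so the column consensus stays unambiguous. The
#' default sizes mirror a two-subfamily comparison of 515 and 401 sequences
#' over 100 candidate positions.
#'
#' @param n_a,n_b sequences per group (defaults 515 and 401).
#' @param n_positions alignment length (default 100).
#' @param planted data.frame with columns \code{generic_number},
#'   \code{residue_a}, \code{residue_b}; every pair must score < 0 under
#'   BLOSUM62. Default [default_planted_hotspots()].
#' @param conservation conservation level of planted positions, scalar or
#'   one value per planted row (default 1.0).
#' @param noise_rate per-cell substitution probability at background
#'   positions (default 0).
#' @param seed integer seed; identical seeds give identical output.
#' @return list with \code{alignment_a}, \code{alignment_b}
#'   (\code{"aa_alignment"}), \code{map} (a \code{"generic_number_map"}
#'   valid for both alignments) and \code{truth} (data.frame of the planted
#'   positions).
#' @export
simulate_alignments <- function(n_a = 515L, n_b = 401L, n_positions = 100L,
                                planted = default_planted_hotspots(),
                                conservation = 1.0, noise_rate = 0,
                                seed = 1L) {
  if (nrow(planted) > n_positions) {
    sx_error("selexp_domain", "more planted positions than alignment columns")
  }
  scores <- substitution_score(planted$residue_a, planted$residue_b)
  if (any(is.na(scores) | scores >= 0)) {
    sx_error("selexp_domain",
             sprintf("planted pair(s) not negative-scoring under BLOSUM62: %s",
                     paste(planted$generic_number[is.na(scores) | scores >= 0], collapse = ", ")))
  }
  conservation <- rep_len(conservation, nrow(planted))
  if (any(conservation <= 0 | conservation > 1)) {
    sx_error("selexp_domain", "conservation levels must be in (0, 1]")
  }
  set.seed(seed)
  labels <- generic_label_pool(planted$generic_number, n_positions)
  planted_cols <- match(planted$generic_number, labels)

  # shared background residues: draw once, reuse for both groups
  bg_state <- sample(AA20, n_positions, replace = TRUE)
  mk <- function(n, residues, cons, prefix) {
    m <- matrix(rep(bg_state, each = n), n, n_positions)
    for (k in seq_along(planted_cols)) {
      p <- planted_cols[k]
      n_cons <- floor(cons[k] * n)
      others <- setdiff(AA20, c(planted$residue_a[k], planted$residue_b[k]))
      m[, p] <- c(rep(residues[k], n_cons), rep_len(others, n - n_cons))
    }
    if (noise_rate > 0) {
      bg_cols <- setdiff(seq_len(n_positions), planted_cols)
      for (p in bg_cols) {
        flip <- stats::runif(n) < noise_rate
        if (any(flip)) m[flip, p] <- sample(AA20, sum(flip), replace = TRUE)
      }
    }
    alignment(apply(m, 1L, paste, collapse = ""),
              ids = sprintf("%s%04d", prefix, seq_len(n)))
  }
  aln_a <- mk(n_a, planted$residue_a, conservation, "grpA_")
  aln_b <- mk(n_b, planted$residue_b, conservation, "grpB_")

  annotation <- data.frame(position = seq_len(n_positions), generic_number = labels)
  map <- attach_numbering(aln_a, annotation, reference_id = rownames(aln_a)[1L])
  truth <- data.frame(generic_number = planted$generic_number,
                      column = planted_cols,
                      residue_a = planted$residue_a,
                      residue_b = planted$residue_b,
                      conservation = conservation,
                      blosum62 = scores)
  list(alignment_a = aln_a, alignment_b = aln_b, map = map, truth = truth)
}

#' Simulate a coordinate ensemble with planted contacts and correlated blocks
#'
#' Residues are single C-alpha pseudo-atoms spaced far apart along a line so
#' that no accidental contacts occur. Planted contact pairs are placed within
#' contact distance in a seeded random subset of frames sized to the target
#' occupancy. Correlated blocks share a common per-frame displacement mode
#' whose amplitude is scaled to reach the target cross-correlation; all
#' residues additionally fluctuate with isotropic Gaussian noise.
#'
#' @param n_residues number of residues (default 20).
#' @param n_frames number of frames (default 1000).
#' @param contacts data.frame with columns \code{i}, \code{j},
#'   \code{occupancy}; residue indices must be non-adjacent and appear in at
#'   most one contact.
#' @param blocks list of \code{list(members = <indices>, rho = <target
#'   correlation>)}; block members must not overlap contact residues.
#' @param noise isotropic fluctuation amplitude, Angstrom (default 0.3).
#' @param spacing inter-residue spacing of the reference geometry, Angstrom
#'   (default 20; must exceed twice the contact distance).
#' @param contact_distance distance at which planted contacts sit (default
#'   3.5, inside the 4.5 network cutoff).
#' @param seed integer seed.
#' @return list with \code{trajectory} (a \code{"trajectory_ensemble"}) and
#'   \code{truth} (the contacts and blocks as given).
#' @export
simulate_trajectory <- function(n_residues = 20L, n_frames = 1000L,
                                contacts = NULL, blocks = NULL,
                                noise = 0.3, spacing = 20,
                                contact_distance = 3.5, seed = 1L) {
  if (spacing <= 2 * contact_distance) {
    sx_error("selexp_domain", "spacing must exceed twice the contact distance (overlapping residues)")
  }
  involved <- integer()
  if (!is.null(contacts)) {
    if (any(contacts$i < 1 | contacts$j > n_residues | contacts$i >= contacts$j)) {
      sx_error("selexp_domain", "contact indices out of range or unordered (need i < j)")
    }
    if (any(abs(contacts$i - contacts$j) <= 1L)) {
      sx_error("selexp_domain", "contact pairs must not be sequence-adjacent")
    }
    if (any(contacts$occupancy < 0 | contacts$occupancy > 1)) {
      sx_error("selexp_domain", "occupancies must be in [0, 1]")
    }
    involved <- c(contacts$i, contacts$j)
    if (anyDuplicated(involved)) {
      sx_error("selexp_domain", "each residue may appear in at most one planted contact")
    }
  }
  if (!is.null(blocks)) {
    members <- unlist(lapply(blocks, `[[`, "members"))
    if (any(members %in% involved)) {
      sx_error("selexp_domain", "correlated-block members must not overlap contact residues")
    }
    rhos <- vapply(blocks, `[[`, 0, "rho")
    if (any(rhos < 0 | rhos > 1)) sx_error("selexp_domain", "target correlations must be in [0, 1]")
  }
  set.seed(seed)
  atoms <- data.frame(chain = "A", resno = seq_len(n_residues), insert = "",
                      resid = "ALA", elety = "CA", element = "C",
                      x = spacing * seq_len(n_residues), y = 0, z = 0)
  topo <- structure_model(atoms)
  base <- as.matrix(atoms[, c("x", "y", "z")])
  xyz <- array(0, c(n_frames, n_residues, 3L))
  for (f in seq_len(n_frames)) xyz[f, , ] <- base
  # isotropic noise everywhere
  xyz <- xyz + array(stats::rnorm(n_frames * n_residues * 3L, 0, noise),
                     c(n_frames, n_residues, 3L))
  # correlated blocks: shared mode per frame
  if (!is.null(blocks)) {
    for (b in blocks) {
      rho <- b$rho
      mode <- matrix(stats::rnorm(n_frames * 3L), n_frames, 3L)
      if (rho >= 0.999) {
        for (m in b$members) xyz[, m, ] <- array(rep(base[m, ], each = n_frames),
                                                 c(n_frames, 3L)) + mode
      } else if (rho > 0) {
        s <- noise * sqrt(rho / (1 - rho))
        for (m in b$members) xyz[, m, ] <- xyz[, m, ] + s * mode
      }
    }
  }
  # planted contacts: move residue j next to residue i in selected frames
  truth_contacts <- NULL
  if (!is.null(contacts)) {
    for (k in seq_len(nrow(contacts))) {
      i <- contacts$i[k]; j <- contacts$j[k]
      n_on <- round(contacts$occupancy[k] * n_frames)
      on <- sample.int(n_frames, n_on)
      target <- base[i, ] + c(contact_distance, 0, 0)
      for (f in on) xyz[f, j, ] <- target + stats::rnorm(3L, 0, noise / 3)
    }
    truth_contacts <- contacts
  }
  list(trajectory = trajectory_ensemble(topo, xyz),
       truth = list(contacts = truth_contacts, blocks = blocks))
}

#' Simulate concentration-response tables
#'
#' Responses are three-parameter-logistic truth plus Gaussian noise, over a
#' log-spaced concentration grid, with replicates. Defaults emulate a cAMP
#' concentration-response experiment normalised to percent of wild-type
#' maximum: basal 0, emax 100, triplicates, noise 5 percent of emax.
#'
#' @param truth data.frame with columns \code{receptor}, \code{ligand},
#'   \code{pec50}; optional \code{basal} (default 0) and \code{emax}
#'   (default 100).
#' @param concentrations molar grid; default \code{10^seq(-11, -4)} (8
#'   points spanning 7 log units).
#' @param noise_sd Gaussian response noise, same units as the response
#'   (default 5, i.e. 5 percent of the default emax).
#' @param replicates replicates per curve (default 3).
#' @param seed integer seed.
#' @return data.frame with columns \code{receptor}, \code{ligand},
#'   \code{replicate}, \code{concentration_M}, \code{response}.
#' @export
simulate_curves <- function(truth,
                            concentrations = 10^seq(-11, -4),
                            noise_sd = 5, replicates = 3L, seed = 1L) {
  if (diff(range(log10(concentrations))) < 3) {
    sx_error("selexp_domain", "concentration grid must span at least 3 log units")
  }
  if (noise_sd < 0) sx_error("selexp_domain", "noise_sd must be >= 0")
  if (is.null(truth$basal)) truth$basal <- 0
  if (is.null(truth$emax)) truth$emax <- 100
  set.seed(seed)
  rows <- list()
  for (k in seq_len(nrow(truth))) {
    mu <- logistic_response(concentrations, truth$basal[k], truth$emax[k], truth$pec50[k])
    for (r in seq_len(replicates)) {
      resp <- mu + stats::rnorm(length(mu), 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        receptor = truth$receptor[k], ligand = truth$ligand[k], replicate = r,
        concentration_M = concentrations, response = resp)
    }
  }
  do.call(rbind, rows)
}
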