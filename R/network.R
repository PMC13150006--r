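#' Construct a trajectory ensemble
#'
#' Couples a topology (a \code{"structure_model"}) with per-frame coordinates.
#'
#' @param topology a \code{"structure_model"}.
#' @param frames list of n_atoms x 3 coordinate matrices (Angstrom), or a
#'   3-dimensional array \code{[frame, atom, xyz]}.
#' @return object of class \code{"trajectory_ensemble"}: list with
#'   \code{topology} and \code{xyz} (array \code{[frame, atom, 3]}).
#' @export
trajectory_ensemble <- function(topology, frames) {
  stopifnot(inherits(topology, "structure_model"))
  n_atoms <- nrow(topology$atoms)
  if (is.list(frames)) {
    bad <- which(vapply(frames, nrow, 0L) != n_atoms)
    if (length(bad)) {
      sx_error("selexp_domain",
               sprintf("frame %d has %d atoms, topology has %d",
                       bad[1L], nrow(frames[[bad[1L]]]), n_atoms))
    }
    xyz <- array(0, c(length(frames), n_atoms, 3L))
    for (i in seq_along(frames)) xyz[i, , ] <- as.matrix(frames[[i]])
  } else {
    xyz <- frames
    if (length(dim(xyz)) != 3L || dim(xyz)[2L] != n_atoms || dim(xyz)[3L] != 3L) {
      sx_error("selexp_domain", "frames array must be [frame, atom, 3] matching the topology")
    }
  }
  if (dim(xyz)[1L] < 1L) sx_error("selexp_domain", "need at least one frame")
  if (any(!is.finite(xyz))) sx_error("selexp_domain", "non-finite coordinates in trajectory")
  structure(list(topology = topology, xyz = xyz), class = "trajectory_ensemble")
}

#' Read a multi-model PDB as a trajectory
#'
#' Each MODEL record becomes one frame; the first model provides the
#' topology.
#'
#' @param path multi-model PDB file.
#' @param ligand_selector passed to the topology (see [parse_structure()]).
#' @return a \code{"trajectory_ensemble"}.
#' @export
read_trajectory_pdb <- function(path, ligand_selector = NULL) {
  if (!file.exists(path)) sx_error("selexp_io", sprintf("file not found: %s", path))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  topo <- parse_structure(path, ligand_selector = ligand_selector, format = "pdb")
  xyz_mat <- pdb$xyz  # n_frames x 3N
  n_frames <- nrow(xyz_mat)
  n_atoms <- ncol(xyz_mat) / 3L
  xyz <- array(0, c(n_frames, n_atoms, 3L))
  for (f in seq_len(n_frames)) {
    xyz[f, , ] <- matrix(xyz_mat[f, ], ncol = 3L, byrow = TRUE)
  }
  trajectory_ensemble(topo, xyz)
}

#' Read a plain-text per-frame coordinate table
#'
#' Tab- or whitespace-separated table with a header and columns
#' \code{frame}, \code{atom}, \code{x}, \code{y}, \code{z}; \code{atom} is the
#' 1-based atom index into the topology and every frame must list every atom.
#'
#' @param path table file.
#' @param topology a \code{"structure_model"} matching the atom indices.
#' @return a \code{"trajectory_ensemble"}.
#' @export
read_trajectory_xyz <- function(path, topology) {
  if (!file.exists(path)) sx_error("selexp_io", sprintf("file not found: %s", path))
  df <- utils::read.table(path, header = TRUE)
  req <- c("frame", "atom", "x", "y", "z")
  if (!all(req %in% names(df))) {
    sx_error("selexp_parse", sprintf("coordinate table needs columns: %s", paste(req, collapse = ", ")))
  }
  n_atoms <- nrow(topology$atoms)
  frames <- sort(unique(df$frame))
  xyz <- array(NA_real_, c(length(frames), n_atoms, 3L))
  for (k in seq_along(frames)) {
    sub <- df[df$frame == frames[k], , drop = FALSE]
    if (nrow(sub) != n_atoms || !setequal(sub$atom, seq_len(n_atoms))) {
      sx_error("selexp_parse", sprintf("frame %s does not list every topology atom exactly once", frames[k]))
    }
    sub <- sub[order(sub$atom), ]
    xyz[k, , ] <- as.matrix(sub[, c("x", "y", "z")])
  }
  trajectory_ensemble(topology, xyz)
}

# Residue bookkeeping for a trajectory: list of atom-index vectors per residue.
residue_index <- function(topology, heavy_only = TRUE, receptor_only = TRUE) {
  a <- topology$atoms
  sel <- rep(TRUE, nrow(a))
  if (heavy_only) sel <- sel & a$element != "H"
  if (receptor_only) sel <- sel & !a$is_ligand
  idx <- which(sel)
  key <- res_key(a)[idx]
  split(idx, factor(key, levels = unique(key)))
}

#' Dynamic residue-interaction network from a trajectory
#'
#' Residues are nodes. An edge joins two residues when any heavy-atom pair is
#' within \code{cutoff} in at least \code{occupancy_min} of the frames;
#' sequence-adjacent residues are excluded (trivial backbone contacts). Each
#' retained edge carries the equal-time cross-correlation of the two
#' residues' C-alpha displacement vectors and the communication weight
#' \code{-log(|C|)}, clamped at \code{w_max} for vanishing correlation.
#' Frames are superposed onto the first frame (C-alpha Kabsch fit) before
#' computing displacements so that global tumbling does not masquerade as
#' correlated motion.
#'
#' @param traj a \code{"trajectory_ensemble"} with at least 2 frames and 2
#'   residues.
#' @param cutoff heavy-atom contact distance, Angstrom (default 4.5).
#' @param occupancy_min minimum fraction of frames in contact (default 0.75).
#' @param exclude_adjacent exclude residue pairs within this sequence
#'   separation on the same chain (default 1, i.e. direct neighbours).
#' @param superpose remove global rotation/translation first (default TRUE).
#' @param w_max weight assigned when \code{|C| < exp(-w_max)} (default 20).
#' @return object of class \code{"contact_network"}: list with \code{nodes}
#'   (data.frame: id, chain, resno, resid) and \code{edges} (data.frame:
#'   from, to, occupancy, correlation, weight).
#' @export
contact_network <- function(traj, cutoff = 4.5, occupancy_min = 0.75,
                            exclude_adjacent = 1L, superpose = TRUE,
                            w_max = 20) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  xyz <- traj$xyz
  n_frames <- dim(xyz)[1L]
  res <- residue_index(traj$topology)
  if (length(res) < 2L) sx_error("selexp_domain", "need at least two residues")
  a <- traj$topology$atoms
  ids <- names(res)
  firsts <- vapply(res, `[`, 0L, 1L)
  nodes <- data.frame(id = ids, chain = a$chain[firsts], resno = a$resno[firsts],
                      resid = a$resid[firsts], row.names = NULL)

  # contact occupancy over all residue pairs
  nres <- length(res)
  contact_frames <- matrix(0L, nres, nres)
  for (f in seq_len(n_frames)) {
    co <- xyz[f, , , drop = TRUE]
    for (i in seq_len(nres - 1L)) {
      pi <- co[res[[i]], , drop = FALSE]
      for (j in seq((i + 1L), nres)) {
        pj <- co[res[[j]], , drop = FALSE]
        d2 <- outer(rowSums(pi^2), rowSums(pj^2), "+") - 2 * pi %*% t(pj)
        if (min(d2) < cutoff^2) contact_frames[i, j] <- contact_frames[i, j] + 1L
      }
    }
  }
  occ <- contact_frames / n_frames

  # C-alpha displacement correlations
  ca_idx <- vapply(res, function(ix) {
    ca <- ix[a$elety[ix] == "CA"]
    if (length(ca)) ca[1L] else ix[1L]
  }, 0L)
  if (n_frames < 2L) {
    sx_error("selexp_degenerate_statistics",
             "cross-correlation undefined for a single frame (zero variance)")
  }
  ca <- xyz[, ca_idx, , drop = FALSE]
  if (superpose && nres >= 3L) {
    ref <- ca[1L, , , drop = TRUE]
    for (f in seq(2L, n_frames)) {
      fit <- kabsch(ca[f, , , drop = TRUE], ref)
      moved <- sweep(xyz[f, , , drop = TRUE] %*% fit$rotation, 2L, fit$translation, "+")
      xyz[f, , ] <- moved
    }
    ca <- xyz[, ca_idx, , drop = FALSE]
  }
  mean_pos <- apply(ca, c(2L, 3L), mean)
  disp <- sweep(ca, c(2L, 3L), mean_pos)  # [frame, res, 3]
  # inner products <d_i . d_j> averaged over frames
  flat <- matrix(disp, n_frames, nres * 3L)
  ip <- matrix(0, nres, nres)
  for (k in 1:3) {
    comp <- flat[, ((k - 1L) * nres + 1L):(k * nres), drop = FALSE]
    ip <- ip + crossprod(comp) / n_frames
  }
  v <- diag(ip)
  denom <- sqrt(outer(v, v))
  C <- ifelse(denom > 0, ip / denom, 0)

  ut <- which(upper.tri(occ) & occ >= occupancy_min, arr.ind = TRUE)
  if (nrow(ut)) {
    same_chain <- nodes$chain[ut[, 1L]] == nodes$chain[ut[, 2L]]
    adjacent <- same_chain & abs(nodes$resno[ut[, 1L]] - nodes$resno[ut[, 2L]]) <= exclude_adjacent
    ut <- ut[!adjacent, , drop = FALSE]
  }
  cij <- C[ut]
  w <- ifelse(abs(cij) < exp(-w_max), w_max, -log(abs(cij)))
  w <- pmin(pmax(w, 0), w_max)
  edges <- data.frame(from = ids[ut[, 1L]], to = ids[ut[, 2L]],
                      occupancy = occ[ut], correlation = cij, weight = w,
                      row.names = NULL)
  structure(list(nodes = nodes, edges = edges), class = "contact_network")
}

#' @export
print.contact_network <- function(x, ...) {
  cat(sprintf("Residue-interaction network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes$id)
}

#' Girvan-Newman communities of a contact network
#'
#' Iteratively removes the edge with highest betweenness and returns the
#' partition of maximum modularity along the resulting dendrogram
#' (igraph's edge-betweenness clustering). Edge weights are treated as
#' distances, as appropriate for the \code{-log|C|} communication weights.
#'
#' @param net a \code{"contact_network"} with at least one edge.
#' @return list of class \code{"community_partition"}: \code{membership}
#'   (named integer vector) and \code{modularity}.
#' @export
network_communities <- function(net) {
  stopifnot(inherits(net, "contact_network"))
  if (nrow(net$edges) == 0L) sx_error("selexp_domain", "network has no edges")
  g <- as_igraph(net)
  w <- net$edges$weight
  # strictly positive weights required by weighted betweenness
  w <- pmax(w, 1e-12)
  cm <- suppressWarnings(
    igraph::cluster_edge_betweenness(g, weights = w, modularity = TRUE))
  structure(list(membership = igraph::membership(cm),
                 modularity = max(cm$modularity)),
            class = "community_partition")
}

# Floyd-Warshall with path reconstruction on a weight matrix (Inf = absent).
floyd_warshall <- function(W) {
  n <- nrow(W)
  nxt <- matrix(NA_integer_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && is.finite(W[i, j])) nxt[i, j] <- j
  }
  D <- W
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      dk <- D[i, k]
      if (!is.finite(dk)) next
      upd <- dk + D[k, ] < D[i, ]
      upd[i] <- FALSE
      if (any(upd)) {
        D[i, upd] <- dk + D[k, upd]
        nxt[i, upd] <- nxt[i, k]
      }
    }
  }
  list(dist = D, nxt = nxt)
}

#' Shortest communication paths between source and sink residues
#'
#' All-pairs shortest paths over the edge weights (Floyd-Warshall), reported
#' for each (source, sink) combination. Unreachable pairs are returned with
#' infinite weight and an empty path.
#'
#' @param net a \code{"contact_network"}.
#' @param sources,sinks node identifiers (see \code{net$nodes$id}).
#' @return data.frame with columns \code{source}, \code{sink},
#'   \code{total_weight} and a list-column \code{path} of node vectors.
#' @export
communication_paths <- function(net, sources, sinks) {
  stopifnot(inherits(net, "contact_network"))
  ids <- net$nodes$id
  unknown <- setdiff(c(sources, sinks), ids)
  if (length(unknown)) {
    sx_error("selexp_unknown_node",
             sprintf("unknown node(s): %s", paste(unknown, collapse = ", ")))
  }
  n <- length(ids)
  W <- matrix(Inf, n, n, dimnames = list(ids, ids))
  ei <- match(net$edges$from, ids); ej <- match(net$edges$to, ids)
  for (k in seq_along(ei)) {
    w <- net$edges$weight[k]
    if (w < W[ei[k], ej[k]]) {
      W[ei[k], ej[k]] <- w
      W[ej[k], ei[k]] <- w
    }
  }
  fw <- floyd_warshall(W)
  out <- expand.grid(source = sources, sink = sinks,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out$total_weight <- NA_real_
  out$path <- vector("list", nrow(out))
  for (r in seq_len(nrow(out))) {
    i <- match(out$source[r], ids); j <- match(out$sink[r], ids)
    out$total_weight[r] <- fw$dist[i, j]
    if (is.finite(fw$dist[i, j])) {
      p <- i
      while (p[length(p)] != j) p <- c(p, fw$nxt[p[length(p)], j])
      out$path[[r]] <- ids[p]
    } else {
      out$path[[r]] <- character()
    }
  }
  out
}

vnorm <- function(v) sqrt(sum(v^2))

# Signed dihedral angle (degrees, (-180, 180]) for points p1-p2-p3-p4.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / vnorm(b2)
  ang <- atan2(-sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Hydrogen-bond occupancies over a trajectory
#'
#' Geometric criterion: a frame counts when the donor-acceptor heavy-atom
#' distance is below \code{dist_cutoff} and the donor-hydrogen-acceptor angle
#' is at least \code{angle_min} for any hydrogen covalently attached to the
#' donor (attachment inferred from a D-H distance of at most 1.2 Angstrom in
#' the first frame).
#'
#' @param traj a \code{"trajectory_ensemble"} whose topology includes
#'   explicit hydrogens.
#' @param donors,acceptors integer atom indices into the topology (donor and
#'   acceptor heavy atoms). All donor x acceptor combinations are evaluated,
#'   skipping pairs within the same residue.
#' @param dist_cutoff donor-acceptor distance cutoff, Angstrom (default 3.5).
#' @param angle_min minimum D-H-A angle in degrees, inclusive (default 120).
#' @return data.frame with columns \code{donor}, \code{acceptor} (atom
#'   labels \code{chain:resno:atom}), \code{occupancy}.
#' @export
hbond_occupancy <- function(traj, donors, acceptors,
                            dist_cutoff = 3.5, angle_min = 120) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  a <- traj$topology$atoms
  xyz <- traj$xyz
  n_frames <- dim(xyz)[1L]
  h_idx <- which(a$element == "H")
  frame1 <- xyz[1L, , , drop = TRUE]
  attached <- lapply(donors, function(d) {
    if (length(h_idx) == 0L) return(integer())
    dd <- sqrt(rowSums(sweep(frame1[h_idx, , drop = FALSE], 2L, frame1[d, ])^2))
    h_idx[dd <= 1.2]
  })
  no_h <- vapply(attached, length, 0L) == 0L
  if (any(no_h)) {
    bad <- unique(paste0(a$chain[donors[no_h]], ":", a$resno[donors[no_h]]))
    sx_error("selexp_no_donor_hydrogen",
             sprintf("donor(s) without attached hydrogen in residue(s): %s",
                     paste(bad, collapse = ", ")))
  }
  lab <- function(i) paste0(a$chain[i], ":", a$resno[i], ":", a$elety[i])
  out <- expand.grid(di = seq_along(donors), ai = seq_along(acceptors),
                     KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  for (r in seq_len(nrow(out))) {
    d <- donors[out$di[r]]; acc <- acceptors[out$ai[r]]
    if (d == acc) next
    if (a$chain[d] == a$chain[acc] && a$resno[d] == a$resno[acc]) next
    hs <- attached[[out$di[r]]]
    hits <- 0L
    for (f in seq_len(n_frames)) {
      co <- xyz[f, , , drop = TRUE]
      if (vnorm(co[acc, ] - co[d, ]) >= dist_cutoff) next
      for (h in hs) {
        v1 <- co[d, ] - co[h, ]; v2 <- co[acc, ] - co[h, ]
        ang <- acos(pmin(pmax(sum(v1 * v2) / (vnorm(v1) * vnorm(v2)), -1), 1)) * 180 / pi
        if (ang >= angle_min) { hits <- hits + 1L; break }
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(donor = lab(d), acceptor = lab(acc),
                                            occupancy = hits / n_frames)
  }
  if (length(rows) == 0L) {
    return(data.frame(donor = character(), acceptor = character(), occupancy = numeric()))
  }
  do.call(rbind, rows)
}

# Gamma-analog atom defining chi1 for branched/short side chains.
CHI1_GAMMA <- c(VAL = "CG1", ILE = "CG1", THR = "OG1", SER = "OG", CYS = "SG")

#' Chi1 side-chain dihedral series
#'
#' The first side-chain torsion N-CA-CB-CG per frame, signed by the IUPAC
#' convention with range (-180, 180]. For VAL/ILE the gamma atom is CG1, for
#' THR OG1, SER OG and CYS SG.
#'
#' @param traj a \code{"trajectory_ensemble"}.
#' @param residues residue numbers (resno) to evaluate.
#' @param chain chain identifier (default first chain in the topology).
#' @return data.frame with columns \code{resno}, \code{frame}, \code{chi1}
#'   (degrees).
#' @export
chi1_series <- function(traj, residues, chain = NULL) {
  stopifnot(inherits(traj, "trajectory_ensemble"))
  a <- traj$topology$atoms
  if (is.null(chain)) chain <- a$chain[1L]
  xyz <- traj$xyz
  n_frames <- dim(xyz)[1L]
  rows <- list()
  for (rn in residues) {
    sel <- which(a$chain == chain & a$resno == rn & !a$is_ligand)
    if (!length(sel)) sx_error("selexp_unknown_node", sprintf("residue %s:%d not found", chain, rn))
    resid <- a$resid[sel[1L]]
    gname <- if (resid %in% names(CHI1_GAMMA)) CHI1_GAMMA[[resid]] else "CG"
    need <- c("N", "CA", "CB", gname)
    idx <- sel[match(need, a$elety[sel])]
    if (any(is.na(idx))) {
      sx_error("selexp_missing_atom",
               sprintf("residue %s:%d (%s) lacks atom(s): %s", chain, rn, resid,
                       paste(need[is.na(match(need, a$elety[sel]))], collapse = ", ")))
    }
    chi <- vapply(seq_len(n_frames), function(f) {
      co <- xyz[f, , , drop = TRUE]
      dihedral_angle(co[idx[1L], ], co[idx[2L], ], co[idx[3L], ], co[idx[4L], ])
    }, 0)
    rows[[length(rows) + 1L]] <- data.frame(resno = rn, frame = seq_len(n_frames), chi1 = chi)
  }
  do.call(rbind, rows)
}

#' Welch's two-sample t-test on occupancy samples
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-tailed p-value (delegates to \code{stats::t.test}). When both
#' samples are constant, the test is degenerate: equal means give p = 1 by
#' convention, unequal means p = 0.
#'
#' @param sample_a,sample_b numeric vectors, each of length at least 2.
#' @return list with elements \code{t}, \code{df}, \code{p}.
#' @export
welch_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    sx_error("selexp_domain", "each sample needs at least 2 observations")
  }
  va <- stats::var(sample_a); vb <- stats::var(sample_b)
  if (va == 0 && vb == 0) {
    if (isTRUE(all.equal(mean(sample_a), mean(sample_b)))) {
      return(list(t = 0, df = NA_real_, p = 1))
    }
    return(list(t = sign(mean(sample_a) - mean(sample_b)) * Inf, df = NA_real_, p = 0))
  }
  tt <- stats::t.test(sample_a, sample_b, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Export a contact network as versioned JSON
#'
#' @param net a \code{"contact_network"}.
#' @param path output file.
#' @param communities optional \code{"community_partition"}.
#' @param paths optional data.frame from [communication_paths()].
#' @return \code{path}, invisibly.
#' @export
write_network_json <- function(net, path, communities = NULL, paths = NULL) {
  obj <- list(schema = "selexp-network/1",
              nodes = net$nodes, edges = net$edges)
  if (!is.null(communities)) {
    obj$communities <- list(membership = as.list(communities$membership),
                            modularity = communities$modularity)
  }
  if (!is.null(paths)) {
    paths$path <- vapply(paths$path, paste, "", collapse = "->")
    obj$paths <- paths
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
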