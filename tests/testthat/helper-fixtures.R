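# Shared fixture builders and independent oracles.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal fixed-width PDB writer for synthetic structures.
write_min_pdb <- function(atoms, path, hetero = atoms$is_ligand %||% rep(FALSE, nrow(atoms))) {
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            if (hetero[i]) "HETATM" else "ATOM", i,
            substr(atoms$elety[i], 1, 4), " ", atoms$resid[i],
            atoms$chain[i], atoms$resno[i], " ",
            atoms$x[i], atoms$y[i], atoms$z[i], 1.00, 0.00,
            atoms$element[i])
  }, "")
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# A synthetic receptor-ligand complex with planted contact distances:
# residue 1 has an atom 3.9 A from the ligand, residue 3 sits at 4.1 A,
# residue 2 is remote. Ligand residue name "ALE".
toy_complex <- function() {
  atoms <- data.frame(
    chain = "A",
    resno = c(1, 1, 1, 2, 2, 3, 3, 100, 100),
    resid = c("SER", "SER", "SER", "ALA", "ALA", "VAL", "VAL", "ALE", "ALE"),
    elety = c("N", "CA", "OG", "N", "CA", "CA", "CB", "C1", "O1"),
    element = c("N", "C", "O", "N", "C", "C", "C", "C", "O"),
    x = c(-6, -5, -3.9, 15, 16, 5.1, 4.1, 0, 0),
    y = c(0, 0, 0, 0, 0, 0, 0, 0, 0.5),
    z = c(0, 0, 0, 0, 0, 0, 0, 0, 0)
  )
  structure_model(atoms, ligand_selector = "ALE")
}

# Independent brute-force hotspot oracle: recounts residues from the raw
# character matrices and looks scores up in the Biostrings copy of BLOSUM62.
oracle_hotspots <- function(mat_a, mat_b, theta = 0.8) {
  B <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  col_cons <- function(col) {
    cnt <- table(factor(col[col != "-"], levels = aas))
    if (sum(cnt) == 0) return(list(res = NA, frac = 0))
    top <- names(cnt)[cnt == max(cnt)]
    res <- sort(top)[1]
    list(res = res, frac = as.numeric(cnt[res]) / length(col))
  }
  vapply(seq_len(ncol(mat_a)), function(j) {
    ca <- col_cons(mat_a[, j]); cb <- col_cons(mat_b[, j])
    if (is.na(ca$res) || is.na(cb$res)) return(FALSE)
    ca$frac >= theta && cb$frac >= theta && B[ca$res, cb$res] < 0
  }, logical(1))
}

# Map assigning sequential generic numbers to every column (test plumbing).
full_map <- function(aln) {
  L <- ncol(aln)
  structure(data.frame(column = seq_len(L),
                       generic_number = paste0("1x", 29L + seq_len(L))),
            class = c("generic_number_map", "data.frame"),
            reference_id = rownames(aln)[1L], alignment_length = L)
}

# Build a contact_network object directly from an edge list (equal weights
# unless given), for graph-algorithm tests decoupled from trajectories.
make_network <- function(edges, nodes = NULL, weight = 1) {
  ids <- nodes %||% sort(unique(c(edges$from, edges$to)))
  if (is.null(edges$weight)) edges$weight <- rep_len(weight, nrow(edges))
  if (is.null(edges$occupancy)) edges$occupancy <- rep_len(1, nrow(edges))
  if (is.null(edges$correlation)) edges$correlation <- exp(-edges$weight)
  structure(list(
    nodes = data.frame(id = ids, chain = rep("A", length(ids)),
                       resno = seq_along(ids), resid = rep("ALA", length(ids))),
    edges = edges
  ), class = "contact_network")
}

# Brute-force best-bipartition Newman modularity (unweighted).
best_bipartition <- function(edges, ids) {
  m <- nrow(edges)
  deg <- table(factor(c(edges$from, edges$to), levels = ids))
  best <- list(q = -Inf, side = NULL)
  n <- length(ids)
  for (code in 1:(2^(n - 1) - 1)) {
    side <- as.logical(bitwAnd(code, 2^(seq_len(n) - 1)))
    q <- 0
    for (grp in c(TRUE, FALSE)) {
      members <- ids[side == grp]
      e_in <- sum(edges$from %in% members & edges$to %in% members)
      d <- sum(deg[members])
      q <- q + e_in / m - (d / (2 * m))^2
    }
    if (q > best$q) best <- list(q = q, side = side)
  }
  best
}

# Deterministic unit-sphere directions (golden spiral), for cage fixtures.
sphere_points_for_test <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Single-atom-per-residue trajectory from a list of coordinate matrices.
beads_trajectory <- function(frames, resno = NULL) {
  n <- nrow(frames[[1L]])
  resno <- resno %||% seq_len(n)
  atoms <- data.frame(chain = "A", resno = resno, resid = "ALA",
                      elety = "CA", element = "C",
                      x = frames[[1L]][, 1L], y = frames[[1L]][, 2L],
                      z = frames[[1L]][, 3L])
  trajectory_ensemble(structure_model(atoms), frames)
}
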