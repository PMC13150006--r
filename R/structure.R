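#' Parse a receptor-ligand structure
#'
#' Reads coordinates from PDB or mmCIF (via bio3d) and partitions atoms into
#' receptor and ligand by residue name. Only the first model of a multi-model
#' file is used. When alternate locations are present, the highest-occupancy
#' copy of each atom is kept. Hydrogens are retained if present.
#'
#' @param path structure file.
#' @param ligand_selector residue name(s) designating the bound ligand
#'   (e.g. \code{"ALE"} for adrenaline in some deposited structures). May be
#'   \code{NULL} when no ligand operations are needed.
#' @param format \code{"auto"} (by extension), \code{"pdb"} or \code{"mmcif"}.
#' @return An object of class \code{"structure_model"}: list with
#'   \code{atoms} (data.frame: chain, resno, insert, resid, elety, element,
#'   x, y, z, is_ligand) and \code{ligand_selector}.
#' @export
parse_structure <- function(path, ligand_selector = NULL,
                            format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) sx_error("selexp_io", sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) sx_error("selexp_parse", sprintf("cannot read %s: %s", path, conditionMessage(e)))
  )
  at <- pdb$atom
  # highest-occupancy alternate location per atom
  if (!is.null(at$alt) && any(!is.na(at$alt) & at$alt != "")) {
    key <- paste(at$chain, at$resno, at$insert, at$elety)
    occ <- if (is.null(at$o)) rep(1, nrow(at)) else ifelse(is.na(at$o), 1, at$o)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(i) i[which.max(occ[i])]))
    at <- at[sort(keep), , drop = FALSE]
  }
  element <- at$elesy
  if (is.null(element) || all(is.na(element) | element == "")) {
    element <- toupper(substr(gsub("[0-9]", "", at$elety), 1L, 1L))
  }
  insert <- at$insert
  insert[is.na(insert)] <- ""
  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = at$resno,
    insert = insert,
    resid = at$resid,
    elety = at$elety,
    element = toupper(trimws(element)),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    sx_error("selexp_parse", "non-finite coordinates in structure")
  }
  atoms$is_ligand <- atoms$resid %in% ligand_selector
  if (!is.null(ligand_selector) && !any(atoms$is_ligand)) {
    sx_error("selexp_ligand_not_found",
             sprintf("ligand selector '%s' matches no residue in %s",
                     paste(ligand_selector, collapse = ","), path))
  }
  structure(list(atoms = atoms, ligand_selector = ligand_selector),
            class = "structure_model")
}

#' Build a structure model from an atom table
#'
#' Programmatic constructor used by the simulators and tests; same contract
#' as [parse_structure()].
#'
#' @param atoms data.frame with columns chain, resno, resid, elety, element,
#'   x, y, z (insert optional).
#' @param ligand_selector residue name(s) of the ligand, or \code{NULL}.
#' @return a \code{"structure_model"}.
#' @export
structure_model <- function(atoms, ligand_selector = NULL) {
  req <- c("chain", "resno", "resid", "elety", "element", "x", "y", "z")
  if (!all(req %in% names(atoms))) {
    sx_error("selexp_domain", sprintf("atom table needs columns: %s", paste(req, collapse = ", ")))
  }
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    sx_error("selexp_domain", "non-finite coordinates")
  }
  atoms$is_ligand <- atoms$resid %in% ligand_selector
  if (!is.null(ligand_selector) && !any(atoms$is_ligand)) {
    sx_error("selexp_ligand_not_found", "ligand selector matches no residue")
  }
  structure(list(atoms = atoms, ligand_selector = ligand_selector),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("Structure model: %d atoms, %d receptor residues, %d ligand atoms\n",
              nrow(a),
              length(unique(paste(a$chain, a$resno, a$insert)[!a$is_ligand])),
              sum(a$is_ligand)))
  invisible(x)
}

res_key <- function(atoms) paste0(atoms$chain, ":", atoms$resno, atoms$insert)

#' Binding-site residues by ligand proximity
#'
#' A receptor residue belongs to the binding site when any of its heavy
#' (non-hydrogen) atoms lies within \code{cutoff} of any ligand heavy atom.
#' The default 4 Angstrom cutoff is the conventional contact definition for
#' native agonist binding sites.
#'
#' @param model a \code{"structure_model"} with a non-empty ligand partition.
#' @param cutoff contact distance in Angstrom (default 4.0).
#' @param numbering optional map from residue sequence number to generic
#'   number: a data.frame with columns \code{resno}, \code{generic_number}
#'   (optionally \code{chain}). Residues lacking a generic number are
#'   reported as \code{"chain:resno"} with a warning.
#' @return character vector of binding-site labels (generic numbers where
#'   available), sorted; attribute \code{"details"} holds a data.frame with
#'   chain, resno, resid and the minimum heavy-atom distance to the ligand.
#' @export
binding_site_residues <- function(model, cutoff = 4.0, numbering = NULL) {
  stopifnot(inherits(model, "structure_model"))
  if (cutoff <= 0) sx_error("selexp_domain", "cutoff must be positive")
  a <- model$atoms
  lig <- a[a$is_ligand & a$element != "H", , drop = FALSE]
  rec <- a[!a$is_ligand & a$element != "H", , drop = FALSE]
  if (nrow(lig) == 0L) sx_error("selexp_ligand_not_found", "no ligand heavy atoms")
  if (nrow(rec) == 0L) sx_error("selexp_domain", "empty receptor")
  lm <- as.matrix(lig[, c("x", "y", "z")])
  rm_ <- as.matrix(rec[, c("x", "y", "z")])
  # min distance from each receptor atom to any ligand heavy atom
  d2 <- outer(rowSums(rm_^2), rowSums(lm^2), "+") - 2 * rm_ %*% t(lm)
  mind <- sqrt(pmax(apply(d2, 1L, min), 0))
  key <- res_key(rec)
  per_res <- tapply(mind, key, min)
  hit <- per_res[per_res <= cutoff]
  if (length(hit) == 0L) {
    out <- character()
    attr(out, "details") <- data.frame(chain = character(), resno = integer(),
                                       resid = character(), min_distance = numeric())
    return(out)
  }
  first <- rec[match(names(hit), key), c("chain", "resno", "resid")]
  details <- data.frame(first, min_distance = as.numeric(hit), row.names = NULL)
  details <- details[order(details$chain, details$resno), , drop = FALSE]
  labels <- paste0(details$chain, ":", details$resno)
  if (!is.null(numbering)) {
    idx <- if ("chain" %in% names(numbering)) {
      match(paste(details$chain, details$resno), paste(numbering$chain, numbering$resno))
    } else {
      match(details$resno, numbering$resno)
    }
    gn <- numbering$generic_number[idx]
    if (any(is.na(gn))) {
      warning(sprintf("binding-site residue(s) without generic number: %s",
                      paste(labels[is.na(gn)], collapse = ", ")))
    }
    labels <- ifelse(is.na(gn), labels, gn)
  }
  details$label <- labels
  out <- labels
  attr(out, "details") <- details
  out
}

#' The packaged binding-site position list
#'
#' The 13 generic positions in ligand contact in the adrenaline- and
#' dopamine-bound reference structures. The position two residues after
#' 45x52 in extracellular loop 2 is denoted \code{45x54}.
#'
#' @return character vector of 13 generic numbers.
#' @export
binding_site_positions <- function() {
  c("3x28", "3x32", "3x33", "3x36", "45x52", "45x54",
    "5x43", "5x461", "6x51", "6x52", "6x55", "7x38", "7x42")
}

#' Default hotspot region table
#'
#' Maps generic numbers to the three hotspot regions: the orthosteric site
#' (ligand-contact positions), the TM2-TM7 interhelical interface and the
#' TM3-TM4-TM5 interface. User-overridable; the table is approximate where
#' segment boundaries are concerned.
#'
#' @return data.frame with columns \code{generic_number}, \code{region}.
#' @export
default_region_table <- function() {
  orth <- unique(c("3x36", "7x38", "45x52", binding_site_positions()))
  tm27 <- c("2x60", "2x64", "7x35", "7x39", "1x46", "7x43")
  tm345 <- c("3x41", "3x42", "4x53", "5x46")
  data.frame(
    generic_number = c(orth, tm27, tm345),
    region = c(rep("orthosteric", length(orth)),
               rep("TM2-TM7", length(tm27)),
               rep("TM3-TM4-TM5", length(tm345)))
  )
}

#' Classify hotspot calls into structural regions
#'
#' @param calls a \code{"hotspot_calls"} data.frame.
#' @param table region table (default [default_region_table()]).
#' @return the calls with \code{region} filled in; positions absent from the
#'   table are \code{"unassigned"}.
#' @export
classify_regions <- function(calls, table = default_region_table()) {
  stopifnot(inherits(calls, "hotspot_calls"))
  idx <- match(calls$generic_number, table$generic_number)
  calls$region <- ifelse(is.na(idx), "unassigned", table$region[idx])
  calls
}

# Kabsch least-squares rotation: returns proper rotation R and translation t
# such that P %*% R + t approximates Q (row vectors).
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2L, cp); Q0 <- sweep(Q, 2L, cq)
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t <- cq - as.numeric(cp %*% R)
  list(rotation = R, translation = t)
}

#' Rigid-body C-alpha superposition
#'
#' Least-squares (Kabsch) superposition of paired C-alpha atoms, with the
#' reflection case corrected to a proper rotation, reporting the post-fit
#' RMSD. Inputs may be \code{"structure_model"} objects (paired by residue
#' number, or by generic number when numbering maps are supplied) or plain
#' n x 3 coordinate matrices with rows already paired.
#'
#' @param model_a,model_b structures or n x 3 matrices.
#' @param pairing \code{"resno"} (default) or \code{"generic"}.
#' @param numbering_a,numbering_b when \code{pairing = "generic"}: data.frames
#'   with columns \code{resno}, \code{generic_number} for each model.
#' @return list of class \code{"superposition"}: \code{rotation} (3 x 3,
#'   determinant +1), \code{translation}, \code{rmsd} (Angstrom),
#'   \code{n_atoms_matched}.
#' @export
superpose_ca <- function(model_a, model_b, pairing = c("resno", "generic"),
                         numbering_a = NULL, numbering_b = NULL) {
  pairing <- match.arg(pairing)
  get_ca <- function(m) {
    a <- m$atoms
    ca <- a[!a$is_ligand & a$elety == "CA", , drop = FALSE]
    ca[!duplicated(paste(ca$chain, ca$resno, ca$insert)), , drop = FALSE]
  }
  if (is.matrix(model_a) && is.matrix(model_b)) {
    if (nrow(model_a) != nrow(model_b)) sx_error("selexp_domain", "coordinate sets differ in size")
    P <- model_a; Q <- model_b
  } else {
    ca_a <- get_ca(model_a); ca_b <- get_ca(model_b)
    if (pairing == "generic") {
      if (is.null(numbering_a) || is.null(numbering_b)) {
        sx_error("selexp_domain", "generic pairing needs numbering_a and numbering_b")
      }
      ga <- numbering_a$generic_number[match(ca_a$resno, numbering_a$resno)]
      gb <- numbering_b$generic_number[match(ca_b$resno, numbering_b$resno)]
      shared <- intersect(ga[!is.na(ga)], gb[!is.na(gb)])
      P <- as.matrix(ca_a[match(shared, ga), c("x", "y", "z")])
      Q <- as.matrix(ca_b[match(shared, gb), c("x", "y", "z")])
    } else {
      shared <- intersect(paste(ca_a$chain, ca_a$resno), paste(ca_b$chain, ca_b$resno))
      P <- as.matrix(ca_a[match(shared, paste(ca_a$chain, ca_a$resno)), c("x", "y", "z")])
      Q <- as.matrix(ca_b[match(shared, paste(ca_b$chain, ca_b$resno)), c("x", "y", "z")])
    }
  }
  if (nrow(P) < 3L) sx_error("selexp_domain", "need at least 3 paired C-alpha atoms")
  fit <- kabsch(P, Q)
  Pf <- sweep(P %*% fit$rotation, 2L, fit$translation, "+")
  rmsd <- sqrt(mean(rowSums((Pf - Q)^2)))
  structure(list(rotation = fit$rotation, translation = fit$translation,
                 rmsd = rmsd, n_atoms_matched = nrow(P)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("C-alpha superposition: %d atoms matched, RMSD = %.3f A\n",
              x$n_atoms_matched, x$rmsd))
  invisible(x)
}

# van der Waals radii by element (Angstrom) for surface calculations.
vdw_radius <- function(element) {
  r <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
  out <- unname(r[element])
  out[is.na(out)] <- 1.70
  out
}

# Theoretical maximum accessible surface area per residue (Angstrom^2),
# Tien et al. 2013 theoretical values; used for relative exposure.
MAX_ASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
             GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
             LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
             SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

# Deterministic unit sphere points (golden-spiral lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Sampled solvent-accessible surface area
#'
#' Shrake-Rupley style calculation: each heavy atom's solvent-expanded sphere
#' is sampled with a deterministic point lattice and the accessible fraction
#' is the share of points not buried inside any neighbouring atom's expanded
#' sphere.
#'
#' @param model a \code{"structure_model"}; ligand atoms are ignored.
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points sample points per atom (default 192).
#' @return data.frame per residue: chain, resno, resid, \code{asa} (absolute,
#'   Angstrom^2) and \code{rel_exposure} (asa divided by the residue's
#'   theoretical maximum; NA for non-standard residues).
#' @export
residue_sasa <- function(model, probe = 1.4, n_points = 192L) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  a <- a[!a$is_ligand & a$element != "H", , drop = FALSE]
  if (nrow(a) == 0L) sx_error("selexp_domain", "empty receptor")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- vdw_radius(a$element) + probe
  sp <- sphere_points(n_points)
  n <- nrow(a)
  asa_atom <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(sp * rad[i], 2L, xyz[i, ], "+")
    d2 <- outer(rowSums(pts^2), rowSums(xyz^2), "+") - 2 * pts %*% t(xyz)
    d2[, i] <- Inf
    buried <- rowSums(sweep(d2, 2L, rad^2, "<")) > 0L
    asa_atom[i] <- 4 * pi * rad[i]^2 * mean(!buried)
  }
  key <- res_key(a)
  asa <- tapply(asa_atom, key, sum)
  first <- a[match(names(asa), key), c("chain", "resno", "resid")]
  out <- data.frame(first, asa = as.numeric(asa), row.names = NULL)
  out$rel_exposure <- out$asa / unname(MAX_ASA[out$resid])
  out[order(out$chain, out$resno), , drop = FALSE]
}

#' Prioritize hotspot calls for mutagenesis
#'
#' Deprioritizes candidate positions that are unlikely to affect ligand
#' recognition or that risk interfering with signalling readouts: positions
#' named on an explicit list, positions whose residue is strongly
#' solvent-exposed, or positions close to a marked intracellular
#' (G-protein-facing) reference set. Exposure and proximity are explicit,
#' overridable proxies for what is ultimately a structural judgement call.
#'
#' @param calls a \code{"hotspot_calls"} data.frame.
#' @param model optional \code{"structure_model"} (required for the
#'   structural heuristics).
#' @param deprioritize character vector of generic numbers to deprioritize
#'   outright.
#' @param numbering data.frame with columns \code{resno},
#'   \code{generic_number} linking the structure to the calls (required for
#'   the heuristics).
#' @param exposure_threshold relative side-chain exposure above which a
#'   position is deprioritized (default 0.4); set \code{NA} to disable.
#' @param intracellular generic numbers (or residue numbers when no
#'   numbering is given) marking the G-protein-facing reference set;
#'   \code{NULL} disables the proximity heuristic.
#' @param proximity_cutoff C-alpha distance (Angstrom, default 8) to the
#'   intracellular set below which a position is deprioritized.
#' @return the calls with \code{priority} set to \code{"prioritized"} or
#'   \code{"deprioritized"}.
#' @export
prioritize <- function(calls, model = NULL, deprioritize = character(),
                       numbering = NULL, exposure_threshold = 0.4,
                       intracellular = NULL, proximity_cutoff = 8) {
  stopifnot(inherits(calls, "hotspot_calls"))
  depri <- calls$generic_number %in% deprioritize
  want_structural <- (!is.na(exposure_threshold) || !is.null(intracellular))
  if (is.null(model)) {
    if (length(deprioritize) == 0L && want_structural) {
      sx_error("selexp_needs_structure",
               "structural prioritization heuristics require a structure model")
    }
  } else {
    if (is.null(numbering)) {
      sx_error("selexp_domain", "prioritize() with a structure needs a resno/generic_number map")
    }
    resno_of <- function(gn) numbering$resno[match(gn, numbering$generic_number)]
    rn <- resno_of(calls$generic_number)
    if (!is.na(exposure_threshold)) {
      sasa <- residue_sasa(model)
      rel <- sasa$rel_exposure[match(rn, sasa$resno)]
      depri <- depri | (!is.na(rel) & rel > exposure_threshold)
    }
    if (!is.null(intracellular)) {
      ic_resno <- if (all(grepl("x", intracellular))) resno_of(intracellular) else as.integer(intracellular)
      a <- model$atoms
      ca <- a[!a$is_ligand & a$elety == "CA", , drop = FALSE]
      ic <- as.matrix(ca[ca$resno %in% ic_resno, c("x", "y", "z"), drop = FALSE])
      if (nrow(ic) == 0L) sx_error("selexp_domain", "intracellular reference set matches no C-alpha")
      for (k in seq_along(rn)) {
        p <- as.matrix(ca[ca$resno %in% rn[k], c("x", "y", "z"), drop = FALSE])
        if (nrow(p) && min(sqrt(rowSums(sweep(ic, 2L, p[1L, ])^2))) <= proximity_cutoff) {
          depri[k] <- TRUE
        }
      }
    }
  }
  calls$priority <- ifelse(depri, "deprioritized", "prioritized")
  calls
}
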