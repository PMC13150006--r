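#' Hotspot-calling configuration
#'
#' @param conservation_threshold minimum within-group conservation for a
#'   position to be considered (fraction of sequences carrying the consensus
#'   residue). Default 0.80.
#' @param inclusive treat the conservation threshold as \code{>=} (default)
#'   rather than strict \code{>}; the two readings only differ exactly at the
#'   threshold.
#' @param score_threshold substitution score must be strictly below this value
#'   for a position to be divergent. Default 0.
#' @param eligible_positions optional character vector of generic numbers to
#'   which calling is restricted (e.g. transmembrane segments plus the
#'   binding site); \code{NULL} considers every annotated position.
#' @return list of class \code{"hotspot_config"}.
#' @export
hotspot_config <- function(conservation_threshold = 0.80,
                           inclusive = TRUE,
                           score_threshold = 0L,
                           eligible_positions = NULL) {
  if (!(conservation_threshold > 0 && conservation_threshold <= 1)) {
    sx_error("selexp_domain", "conservation_threshold must be in (0, 1]")
  }
  structure(list(conservation_threshold = conservation_threshold,
                 inclusive = inclusive,
                 score_threshold = score_threshold,
                 eligible_positions = eligible_positions),
            class = "hotspot_config")
}

#' Consensus residue and conservation per annotated position
#'
#' For every column carrying a generic number, the consensus is the most
#' frequent non-gap residue (ties broken alphabetically) and conservation is
#' its count divided by the number of sequences. Gapped sequences count in the
#' denominator by default: a gap is evidence against conservation.
#'
#' @param aln an \code{"aa_alignment"}.
#' @param map a \code{"generic_number_map"} for \code{aln}.
#' @param denominator \code{"all"} (default; gaps included) or
#'   \code{"nongap"}.
#' @return data.frame of class \code{"consensus_profile"} with columns
#'   \code{generic_number}, \code{column}, \code{consensus} (NA for all-gap
#'   columns), \code{conservation}, \code{gap_count}, \code{n_sequences}.
#' @export
compute_consensus <- function(aln, map, denominator = c("all", "nongap")) {
  stopifnot(inherits(aln, "aa_alignment"), inherits(map, "generic_number_map"))
  denominator <- match.arg(denominator)
  if (any(map$column > ncol(aln))) {
    sx_error("selexp_position_out_of_range", "map references columns beyond the alignment")
  }
  prof <- column_profiles(aln)
  counts <- unclass(prof)[, map$column, drop = FALSE]
  res <- lapply(seq_len(ncol(counts)), function(j) {
    cnt <- counts[AA20, j]
    gap <- counts[GAP, j]
    n <- nrow(aln)
    if (all(cnt == 0L)) {
      return(list(consensus = NA_character_, conservation = 0, gap = gap))
    }
    top <- max(cnt)
    cons <- sort(names(cnt)[cnt == top])[1L]  # alphabetical tie-break
    denom <- if (denominator == "all") n else n - gap
    list(consensus = cons, conservation = top / denom, gap = gap)
  })
  out <- data.frame(
    generic_number = map$generic_number,
    column = map$column,
    consensus = vapply(res, `[[`, "", "consensus"),
    conservation = vapply(res, `[[`, 0, "conservation"),
    gap_count = vapply(res, function(r) as.integer(r$gap), 0L),
    n_sequences = nrow(aln)
  )
  rownames(out) <- NULL
  structure(out, class = c("consensus_profile", "data.frame"))
}

#' Call selectivity hotspots between two receptor groups
#'
#' A shared annotated position is a hotspot when it is conserved within each
#' group (conservation at or above the threshold) while the two groups'
#' consensus residues are chemically dissimilar, i.e. their BLOSUM62
#' substitution score is negative. Group order does not matter (the matrix is
#' symmetric).
#'
#' @param prof_a,prof_b \code{"consensus_profile"} objects for the two groups.
#' @param matrix substitution matrix, default [blosum62()].
#' @param cfg a [hotspot_config()].
#' @return data.frame of class \code{"hotspot_calls"}, sorted by generic
#'   number (segment, then position), with columns \code{generic_number},
#'   \code{consensus_a}, \code{conservation_a}, \code{consensus_b},
#'   \code{conservation_b}, \code{blosum62}, \code{is_hotspot}, \code{region}
#'   (\code{"unassigned"} until [classify_regions()]), \code{priority}
#'   (\code{"unset"} until [prioritize()]).
#' @export
call_hotspots <- function(prof_a, prof_b, matrix = blosum62(), cfg = hotspot_config()) {
  stopifnot(inherits(prof_a, "consensus_profile"), inherits(prof_b, "consensus_profile"))
  shared <- intersect(prof_a$generic_number, prof_b$generic_number)
  if (!is.null(cfg$eligible_positions)) shared <- intersect(shared, cfg$eligible_positions)
  if (length(shared) == 0L) {
    sx_error("selexp_no_shared_positions",
             "the two consensus profiles share no (eligible) generic numbers")
  }
  a <- prof_a[match(shared, prof_a$generic_number), ]
  b <- prof_b[match(shared, prof_b$generic_number), ]
  score <- substitution_score(a$consensus, b$consensus, matrix)
  theta <- cfg$conservation_threshold
  conserved <- if (cfg$inclusive) {
    a$conservation >= theta & b$conservation >= theta
  } else {
    a$conservation > theta & b$conservation > theta
  }
  hs <- conserved & !is.na(score) & score < cfg$score_threshold
  out <- data.frame(
    generic_number = shared,
    consensus_a = a$consensus, conservation_a = a$conservation,
    consensus_b = b$consensus, conservation_b = b$conservation,
    blosum62 = score,
    is_hotspot = hs,
    region = "unassigned",
    priority = "unset"
  )
  out <- out[order_generic(out$generic_number), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("hotspot_calls", "data.frame"))
}

#' @export
print.hotspot_calls <- function(x, ...) {
  cat(sprintf("Hotspot calls: %d position(s), %d hotspot(s)\n",
              nrow(x), sum(x$is_hotspot %||% logical())))
  print.data.frame(x, ...)
  invisible(x)
}

#' Exact binomial coefficient for the chance-selection argument
#'
#' How many ways are there to pick \code{k} specific positions out of
#' \code{n}? The reciprocal is the probability of hitting one particular set
#' by uniform chance. Computed as an exact integer by interleaved
#' multiplication and division (each intermediate is itself a binomial
#' coefficient, so no floating-point rounding occurs below 2^53).
#'
#' @param n_positions total number of candidate positions.
#' @param k_selected number of positions selected.
#' @return the exact value of choose(n, k) as a numeric scalar.
#' @seealso [format_one_in()]
#' @examples
#' chance_one_in(100, 7)  # 16007560800
#' @export
chance_one_in <- function(n_positions, k_selected) {
  n <- n_positions; k <- k_selected
  if (length(n) != 1L || length(k) != 1L || is.na(n) || is.na(k) ||
      n < 0 || k < 0 || k > n || n != floor(n) || k != floor(k)) {
    sx_error("selexp_domain", "need integers 0 <= k_selected <= n_positions")
  }
  k <- min(k, n - k)
  r <- 1
  for (i in seq_len(k)) {
    r <- r * (n - k + i) / i
    if (r > 2^53) sx_error("selexp_domain", "binomial coefficient exceeds exact double range")
  }
  round(r)
}

#' Format a chance count as "one in ~X billion"
#'
#' @param count a reciprocal probability, e.g. from [chance_one_in()].
#' @return character scalar, rounded to the nearest integer number of
#'   billions.
#' @examples
#' format_one_in(chance_one_in(100, 7))  # "one in ~16 billion"
#' @export
format_one_in <- function(count) {
  sprintf("one in ~%d billion", as.integer(round(count / 1e9)))
}

#' Hotspot counts across a conservation-threshold grid
#'
#' Sensitivity report: the number of called hotspots is non-increasing in the
#' conservation threshold.
#'
#' @inheritParams call_hotspots
#' @param theta_grid thresholds in (0, 1].
#' @return data.frame with columns \code{theta} and \code{n_hotspots}.
#' @export
sweep_thresholds <- function(prof_a, prof_b, matrix = blosum62(), theta_grid) {
  if (length(theta_grid) == 0L) sx_error("selexp_domain", "empty threshold grid")
  n <- vapply(theta_grid, function(th) {
    calls <- call_hotspots(prof_a, prof_b, matrix, hotspot_config(conservation_threshold = th))
    sum(calls$is_hotspot)
  }, 0L)
  data.frame(theta = theta_grid, n_hotspots = n)
}
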