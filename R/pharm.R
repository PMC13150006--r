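#' Three-parameter logistic concentration-response model
#'
#' Response at molar concentration \code{c} with Hill slope fixed at 1:
#' \deqn{y = basal + (emax - basal) / (1 + 10^{-(\log_{10} c + pEC_{50})})}
#' The midpoint lies at \code{c = 10^-pec50}.
#'
#' @param c concentration(s), molar, strictly positive.
#' @param basal response at zero stimulation.
#' @param emax maximal response.
#' @param pec50 negative log10 of the EC50 (molar).
#' @param hill Hill slope (default 1; the 3-parameter model).
#' @return response value(s).
#' @export
logistic_response <- function(c, basal, emax, pec50, hill = 1) {
  if (any(!is.finite(c)) || any(c <= 0)) {
    sx_error("selexp_domain", "concentrations must be finite and > 0")
  }
  basal + (emax - basal) / (1 + 10^(-hill * (log10(c) + pec50)))
}

#' Fit a three-parameter logistic to concentration-response data
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) with multi-start
#' initialisation over a pEC50 grid, the classic sigmoidal model with Hill
#' slope fixed at 1 (a variable-slope 4-parameter fit is available behind
#' \code{variable_slope}). Requires at least 4 points spanning at least 2
#' log units of concentration. A flat response profile is reported as
#' non-converged rather than fitted.
#'
#' @param concentration molar concentrations (> 0), length >= 4.
#' @param response responses (same length), typically percent of wild-type
#'   maximum; assumed pre-normalised, no normalisation is applied.
#' @param variable_slope also fit the Hill slope (default FALSE).
#' @param pec50_grid multi-start grid for the pEC50 initial value
#'   (default 4..10).
#' @param jitter_seed optional seed for small jitter on the starting values;
#'   the default is the deterministic grid.
#' @param flat_tolerance response range below which the curve is declared
#'   flat (default 1e-6).
#' @return object of class \code{"logistic_fit"} with elements
#'   \code{coefficients} (basal, emax, pec50, and hill when variable),
#'   \code{converged}, \code{reason} (when not converged),
#'   \code{residual_norm}, \code{fitted.values}, \code{residuals},
#'   \code{data}. Methods: \code{print}, \code{coef}, \code{summary},
#'   \code{predict}, \code{residuals}, \code{fitted}.
#' @export
fit_logistic <- function(concentration, response, variable_slope = FALSE,
                         pec50_grid = 4:10, jitter_seed = NULL,
                         flat_tolerance = 1e-6) {
  if (length(concentration) != length(response)) {
    sx_error("selexp_domain", "concentration and response lengths differ")
  }
  if (length(concentration) < 4L) {
    sx_error("selexp_domain", "need at least 4 concentration-response points")
  }
  if (any(concentration <= 0)) sx_error("selexp_domain", "concentrations must be > 0")
  span <- diff(range(log10(concentration)))
  if (span < 2) {
    sx_error("selexp_insufficient_span",
             sprintf("concentrations span %.2f log units; need >= 2", span))
  }
  dat <- data.frame(concentration = concentration, response = response)
  out <- structure(list(coefficients = c(basal = NA_real_, emax = NA_real_, pec50 = NA_real_),
                        converged = FALSE, reason = NULL,
                        residual_norm = NA_real_, data = dat),
                   class = "logistic_fit")
  if (diff(range(response)) < flat_tolerance) {
    out$reason <- "flat_response"
    return(out)
  }
  starts <- pec50_grid
  # data-driven guess: concentration closest to half-maximal response
  half <- (min(response) + max(response)) / 2
  guess <- -log10(concentration[which.min(abs(response - half))])
  starts <- c(guess, starts)
  if (!is.null(jitter_seed)) {
    set.seed(jitter_seed)
    starts <- starts + stats::runif(length(starts), -0.25, 0.25)
  }
  lo <- c(basal = -Inf, emax = -Inf, pec50 = 0)
  hi <- c(basal = Inf, emax = Inf, pec50 = 14)
  form <- response ~ basal + (emax - basal) / (1 + 10^(-(log10(concentration) + pec50)))
  if (variable_slope) {
    form <- response ~ basal + (emax - basal) / (1 + 10^(-hill * (log10(concentration) + pec50)))
    lo <- c(lo, hill = 0.1); hi <- c(hi, hill = 10)
  }
  best <- NULL
  for (s in starts) {
    st <- list(basal = min(response), emax = max(response), pec50 = s)
    if (variable_slope) st$hill <- 1
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = st, lower = lo, upper = hi,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      dev <- sum(stats::residuals(fit)^2)
      if (is.null(best) || dev < best$dev) best <- list(fit = fit, dev = dev)
    }
  }
  if (is.null(best)) {
    out$reason <- "optimisation_failed"
    return(out)
  }
  cf <- stats::coef(best$fit)
  out$coefficients <- cf
  out$converged <- TRUE
  out$residual_norm <- sqrt(best$dev)
  out$fitted.values <- stats::fitted(best$fit)
  out$residuals <- stats::residuals(best$fit)
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (x$converged) {
    cat("3-parameter logistic fit\n")
    cat(sprintf("  basal = %.3f, emax = %.3f, pEC50 = %.3f\n",
                x$coefficients[["basal"]], x$coefficients[["emax"]],
                x$coefficients[["pec50"]]))
    if ("hill" %in% names(x$coefficients)) {
      cat(sprintf("  hill = %.3f\n", x$coefficients[["hill"]]))
    }
    cat(sprintf("  residual norm = %.4g over %d points\n",
                x$residual_norm, nrow(x$data)))
  } else {
    cat(sprintf("3-parameter logistic fit: NOT converged (%s)\n", x$reason))
  }
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' @export
predict.logistic_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) sx_error("selexp_domain", "cannot predict from a non-converged fit")
  conc <- if (is.null(newdata)) object$data$concentration else {
    if (is.data.frame(newdata)) newdata$concentration else newdata
  }
  cf <- object$coefficients
  hill <- if ("hill" %in% names(cf)) cf[["hill"]] else 1
  logistic_response(conc, cf[["basal"]], cf[["emax"]], cf[["pec50"]], hill)
}

#' @export
residuals.logistic_fit <- function(object, ...) object$residuals

#' @export
fitted.logistic_fit <- function(object, ...) object$fitted.values

#' @export
summary.logistic_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Fold selectivity from a pair of pEC50 values
#'
#' \code{fold = 10^(pec50_a - pec50_b)}: the potency ratio of condition a
#' over condition b. Reported both at full precision and rounded to two
#' significant figures (the conventional reporting precision).
#'
#' @param pec50_a,pec50_b finite pEC50 values (vectorised).
#' @return list with \code{fold} and \code{fold_2sf}.
#' @examples
#' fold_selectivity(8.69, 5.29)$fold_2sf  # 2500
#' @export
fold_selectivity <- function(pec50_a, pec50_b) {
  if (any(!is.finite(pec50_a)) || any(!is.finite(pec50_b))) {
    sx_error("selexp_domain", "pEC50 values must be finite")
  }
  fold <- 10^(pec50_a - pec50_b)
  list(fold = fold, fold_2sf = signif2(fold))
}

#' Selectivity profile from a pEC50 table
#'
#' All pairwise ligand fold-selectivities per receptor, the preferred
#' ligand(s), and, when a wild-type receptor is named, per-ligand fold
#' changes of each variant relative to wild-type.
#'
#' @param pec50_table data.frame with columns \code{receptor}, \code{ligand},
#'   \code{pec50}.
#' @param wt optional receptor name to use as the wild-type reference.
#' @return list of class \code{"selectivity_profile"}: \code{folds}
#'   (receptor, ligand_a, ligand_b, delta_pec50, fold, fold_2sf),
#'   \code{preferred} (receptor, ligand; ties joined with "/"), and
#'   \code{vs_wt} (receptor, ligand, fold, fold_2sf; present when \code{wt}
#'   given).
#' @export
profile_report <- function(pec50_table, wt = NULL) {
  req <- c("receptor", "ligand", "pec50")
  if (!all(req %in% names(pec50_table))) {
    sx_error("selexp_domain", "pec50_table needs columns receptor, ligand, pec50")
  }
  folds <- list(); pref <- list()
  for (rec in unique(pec50_table$receptor)) {
    sub <- pec50_table[pec50_table$receptor == rec, , drop = FALSE]
    if (nrow(sub) < 2L) {
      warning(sprintf("receptor '%s' has fewer than 2 ligands; skipped from pairwise folds", rec))
      next
    }
    pairs <- expand.grid(a = seq_len(nrow(sub)), b = seq_len(nrow(sub)))
    pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
    fs <- fold_selectivity(sub$pec50[pairs$a], sub$pec50[pairs$b])
    folds[[rec]] <- data.frame(receptor = rec,
                               ligand_a = sub$ligand[pairs$a],
                               ligand_b = sub$ligand[pairs$b],
                               delta_pec50 = sub$pec50[pairs$a] - sub$pec50[pairs$b],
                               fold = fs$fold, fold_2sf = fs$fold_2sf)
    top <- sub$ligand[sub$pec50 == max(sub$pec50)]
    pref[[rec]] <- data.frame(receptor = rec, preferred = paste(sort(top), collapse = "/"),
                              tie = length(top) > 1L)
  }
  out <- list(folds = do.call(rbind, c(folds, list(make.row.names = FALSE))),
              preferred = do.call(rbind, c(pref, list(make.row.names = FALSE))))
  if (!is.null(wt)) {
    if (!wt %in% pec50_table$receptor) {
      warning(sprintf("wild-type receptor '%s' absent from the table; vs_wt omitted", wt))
    } else {
      wt_rows <- pec50_table[pec50_table$receptor == wt, , drop = FALSE]
      mut <- pec50_table[pec50_table$receptor != wt, , drop = FALSE]
      idx <- match(mut$ligand, wt_rows$ligand)
      if (any(is.na(idx))) {
        warning("some mutant ligands have no wild-type row; those folds omitted")
      }
      keep <- !is.na(idx)
      fs <- fold_selectivity(mut$pec50[keep], wt_rows$pec50[idx[keep]])
      out$vs_wt <- data.frame(receptor = mut$receptor[keep], ligand = mut$ligand[keep],
                              delta_pec50 = mut$pec50[keep] - wt_rows$pec50[idx[keep]],
                              fold = fs$fold, fold_2sf = fs$fold_2sf)
    }
  }
  structure(out, class = "selectivity_profile")
}

#' @export
print.selectivity_profile <- function(x, ...) {
  cat("Selectivity profile\n")
  cat("Preferred ligand per receptor:\n")
  print.data.frame(x$preferred, row.names = FALSE)
  cat("Pairwise fold selectivities:\n")
  print.data.frame(x$folds, row.names = FALSE, digits = 4)
  if (!is.null(x$vs_wt)) {
    cat("Fold change vs wild-type:\n")
    print.data.frame(x$vs_wt, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Read a concentration-response CSV
#'
#' Columns: \code{receptor}, \code{ligand}, \code{replicate},
#' \code{concentration_M}, \code{response}.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_curves <- function(path) {
  if (!file.exists(path)) sx_error("selexp_io", sprintf("file not found: %s", path))
  df <- utils::read.csv(path)
  req <- c("receptor", "ligand", "replicate", "concentration_M", "response")
  if (!all(req %in% names(df))) {
    sx_error("selexp_parse", sprintf("curves CSV needs columns: %s", paste(req, collapse = ", ")))
  }
  df
}

#' Fit every receptor-ligand curve in a table
#'
#' Groups a concentration-response table by receptor and ligand (pooling
#' replicates) and fits each group with [fit_logistic()].
#'
#' @param curves data.frame as from [read_curves()] or [simulate_curves()].
#' @param ... passed to [fit_logistic()].
#' @return data.frame with columns receptor, ligand, basal, emax, pec50,
#'   converged, residual_norm.
#' @export
fit_curve_table <- function(curves, ...) {
  groups <- unique(curves[, c("receptor", "ligand")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sub <- curves[curves$receptor == groups$receptor[i] &
                  curves$ligand == groups$ligand[i], , drop = FALSE]
    fit <- fit_logistic(sub$concentration_M, sub$response, ...)
    cf <- coef(fit)
    data.frame(receptor = groups$receptor[i], ligand = groups$ligand[i],
               basal = cf[["basal"]], emax = cf[["emax"]], pec50 = cf[["pec50"]],
               converged = fit$converged, residual_norm = fit$residual_norm)
  })
  do.call(rbind, rows)
}
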