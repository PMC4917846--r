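#' Flux bounds for FBA/FVA
#'
#' All reactions are irreversible, so fluxes live in `[lb, ub]`. The tiny
#' default lower bound keeps every reaction active (central-carbon
#' reactions are assumed expressed), and the upper bound is arbitrary
#' because only flux ratios are consumed downstream.
#'
#' @param net irreversible `reaction_network`.
#' @param biomass id of the biomass reaction in the model.
#' @param lb scalar or per-reaction lower bound; default `1e-16`.
#' @param ub scalar or per-reaction upper bound; default `1000`.
#' @return list of class `flux_bounds`.
#' @export
flux_bounds <- function(net, biomass, lb = 1e-16, ub = 1000) {
  ids <- net$reactions$id
  if (!biomass %in% ids) stop("biomass reaction not in network: ", biomass)
  lb <- rep_len(lb, length(ids)); ub <- rep_len(ub, length(ids))
  if (any(lb <= 0) || any(lb > ub)) stop("need 0 < lb <= ub")
  structure(list(lb = stats::setNames(lb, ids),
                 ub = stats::setNames(ub, ids), biomass = biomass),
            class = "flux_bounds")
}

#' Biomass-maximizing flux balance analysis
#'
#' Solves `maximize v_bm subject to S v = 0, lb <= v <= ub`. The optimum
#' scales linearly with the arbitrary upper bound; all downstream
#' quantities use only flux ratios, which are invariant to it.
#'
#' @param net irreversible `reaction_network`.
#' @param bounds a [flux_bounds()].
#' @return list with `v_max` (optimal biomass flux) and `flux` (a full
#'   optimal flux vector).
#' @export
maximize_biomass <- function(net, bounds) {
  ids <- net$reactions$id
  obj <- as.numeric(ids == bounds$biomass)
  res <- solve_lp(obj, Aeq = net$S, beq = rep(0, nrow(net$S)),
                  lb = bounds$lb, ub = bounds$ub, maximize = TRUE)
  if (res$status != 0)
    stop("FBA infeasible or unbounded (simplex status ", res$status,
         "); check exchange reactions and bounds")
  list(v_max = res$value, flux = stats::setNames(res$x, ids))
}

#' Flux variability analysis at optimal growth
#'
#' With the biomass flux fixed at its optimum, minimizes and maximizes each
#' reaction flux in turn. The largest log-fold change attributable to flux
#' rearrangement is `lfc_max = |log2(v_max_i / v_min_i)|`, with `v_min_i`
#' clamped below by the lower bound before the ratio.
#'
#' @param net irreversible `reaction_network`.
#' @param bounds a [flux_bounds()].
#' @param v_opt optimal biomass flux from [maximize_biomass()]; computed if
#'   missing.
#' @param relax relative relaxation of the fixed optimum retried on
#'   numerical infeasibility (reported via a warning).
#' @return data.frame of class `variability_result`: `reaction`, `v_min`,
#'   `v_max`, `lfc_max`.
#' @export
flux_variability <- function(net, bounds, v_opt = NULL, relax = 1e-9) {
  ids <- net$reactions$id
  if (is.null(v_opt)) v_opt <- maximize_biomass(net, bounds)$v_max
  bm <- as.numeric(ids == bounds$biomass)
  n <- length(ids)
  vmin <- vmax <- numeric(n)
  solve_one <- function(obj, maximize, vbm) {
    Aeq <- rbind(net$S, bm)
    beq <- c(rep(0, nrow(net$S)), vbm)
    solve_lp(obj, Aeq, beq, lb = bounds$lb, ub = bounds$ub,
             maximize = maximize)
  }
  for (i in seq_len(n)) {
    obj <- as.numeric(seq_len(n) == i)
    for (dir in c(FALSE, TRUE)) {
      res <- solve_one(obj, dir, v_opt)
      if (res$status != 0) {
        warning("FVA retry with relaxed optimum for ", ids[i])
        res <- solve_one(obj, dir, v_opt * (1 - relax))
        if (res$status != 0)
          stop("FVA infeasible for reaction ", ids[i])
      }
      if (dir) vmax[i] <- res$value else vmin[i] <- res$value
    }
  }
  vmin <- pmax(vmin, bounds$lb)
  vmax <- pmax(vmax, vmin)
  out <- data.frame(reaction = ids, v_min = vmin, v_max = vmax,
                    lfc_max = abs(log2(vmax / vmin)),
                    stringsAsFactors = FALSE)
  class(out) <- c("variability_result", "data.frame")
  out
}

#' Necessity-for-proliferation filter
#'
#' A differential activity is necessary for optimal growth when it is
#' statistically significant and even its worst-case (smallest-magnitude)
#' log-fold-change sample exceeds the bound explainable by flux
#' variability: `q < alpha` and `min_s |lfc_s| > lfc_max`.
#'
#' @param eda_samples reaction x sample matrix of log2-fold changes (from
#'   [eda_log_fold_changes()] or [combinatorial_lfc()]).
#' @param q per-reaction BH-adjusted p-values, aligned with the rows.
#' @param var a [flux_variability()] result (aligned or with matching
#'   reaction names).
#' @param alpha significance level; default 0.05.
#' @return logical vector (`NA` where lfc samples or `lfc_max` are
#'   missing); attribute `excluded` lists reactions without an FVA bound.
#' @export
necessity_filter <- function(eda_samples, q, var, alpha = 0.05) {
  ids <- rownames(eda_samples)
  lfc_max <- stats::setNames(var$lfc_max, var$reaction)[ids]
  worst <- apply(abs(eda_samples), 1, min)
  flag <- (q < alpha) & (worst > lfc_max)
  flag[is.na(worst) | is.na(lfc_max)] <- NA
  attr(flag, "excluded") <- ids[is.na(lfc_max)]
  stats::setNames(flag, ids)
}
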