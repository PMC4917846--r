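#' Construct a metabolome panel
#'
#' A panel holds metabolite concentrations (molar) per condition and
#' replicate, together with a provenance grid recording whether each value
#' was measured, imputed within a condition, copied across conditions,
#' filled from an external reference table, or is still missing.
#'
#' @param values numeric matrix, metabolites x samples; `NA` = missing.
#' @param conditions character vector, condition label per column.
#' @param replicates character/integer vector, replicate label per column.
#' @param provenance optional character matrix congruent with `values`;
#'   defaults to "measured" where a value is present, "missing" elsewhere.
#' @return object of class `metabolome_panel`.
#' @export
metabolome_panel <- function(values, conditions, replicates,
                             provenance = NULL) {
  values <- as.matrix(values)
  stopifnot(length(conditions) == ncol(values),
            length(replicates) == ncol(values))
  if (any(values <= 0, na.rm = TRUE))
    stop("concentrations must be strictly positive")
  if (is.null(provenance)) {
    provenance <- matrix(ifelse(is.na(values), "missing", "measured"),
                         nrow = nrow(values), dimnames = dimnames(values))
  }
  stopifnot(all(dim(provenance) == dim(values)))
  colnames(values) <- paste(conditions, replicates, sep = ".")
  dimnames(provenance) <- dimnames(values)
  structure(list(values = values,
                 conditions = as.character(conditions),
                 replicates = as.character(replicates),
                 provenance = provenance),
            class = "metabolome_panel")
}

#' @export
print.metabolome_panel <- function(x, ...) {
  cat("metabolome_panel:", nrow(x$values), "metabolites x",
      ncol(x$values), "samples (conditions:",
      paste(unique(x$conditions), collapse = ", "), ")\n")
  tab <- table(x$provenance)
  cat("  provenance:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Read a metabolome CSV
#'
#' Long format with columns `metabolite, condition, replicate, value` and an
#' optional `unit` column (`M`, `mM`, `uM`, `nM`; default `M`).
#'
#' @param path file path.
#' @return a [metabolome_panel()].
#' @export
read_metabolome <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("metabolite", "condition", "replicate", "value")
  if (!all(need %in% names(tab)))
    stop("metabolome file needs columns: ", paste(need, collapse = ", "))
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9)
  if ("unit" %in% names(tab)) {
    bad <- setdiff(unique(tab$unit), names(scale))
    if (length(bad)) stop("unknown unit(s): ", paste(bad, collapse = ", "))
    tab$value <- tab$value * scale[tab$unit]
  }
  mets <- unique(tab$metabolite)
  samp <- unique(tab[c("condition", "replicate")])
  samp <- samp[order(match(samp$condition, unique(tab$condition))), ]
  values <- matrix(NA_real_, length(mets), nrow(samp),
                   dimnames = list(mets, NULL))
  for (i in seq_len(nrow(tab))) {
    j <- which(samp$condition == tab$condition[i] &
                 samp$replicate == tab$replicate[i])
    values[tab$metabolite[i], j] <- tab$value[i]
  }
  metabolome_panel(values, samp$condition, samp$replicate)
}

#' Convert per-cell-batch abundances to molar concentrations
#'
#' Divides a measured abundance by the total intracellular volume of the
#' assayed cells. The default single-cell volume is 1.54 fl, a literature
#' value for adherent human cell lines.
#'
#' @param abundance moles in the cell batch (vectorized).
#' @param n_cells number of cells in the batch.
#' @param cell_volume single-cell volume in liters; default `1.54e-15`.
#' @return molar concentration(s).
#' @export
abundance_to_concentration <- function(abundance, n_cells,
                                       cell_volume = 1.54e-15) {
  if (any(abundance <= 0) || any(n_cells <= 0) || any(cell_volume <= 0))
    stop("abundance, n_cells and cell_volume must be > 0")
  abundance / (n_cells * cell_volume)
}

#' Impute missing metabolite concentrations
#'
#' Three-stage cascade: (1) replicate gaps are filled with the mean of the
#' observed replicates of the same condition (`imputed_within`); (2)
#' metabolites unobserved in one condition copy the other condition's
#' post-stage-1 values (`imputed_across`), which forces their downstream
#' log-fold changes to zero exactly; (3) metabolites absent everywhere are
#' filled from an external fallback table, identical in all cells
#' (`external_fallback`). Measured values are never overwritten; the cascade
#' is idempotent.
#'
#' @param panel a [metabolome_panel()].
#' @param fallback optional named numeric vector or data.frame
#'   (`metabolite`, `concentration`) of reference concentrations.
#' @return the imputed panel; attribute `report` lists metabolites that are
#'   still missing after the cascade.
#' @export
impute_concentrations <- function(panel, fallback = NULL) {
  if (length(unique(panel$conditions)) < 1) stop("panel has no conditions")
  if (is.data.frame(fallback))
    fallback <- stats::setNames(fallback$concentration, fallback$metabolite)
  v <- panel$values
  pr <- panel$provenance
  conds <- unique(panel$conditions)
  # stage 1: within-condition mean over observed replicates
  for (cond in conds) {
    cols <- which(panel$conditions == cond)
    for (m in seq_len(nrow(v))) {
      obs <- !is.na(v[m, cols])
      if (any(obs) && !all(obs)) {
        fill <- mean(v[m, cols][obs])
        v[m, cols[!obs]] <- fill
        pr[m, cols[!obs]] <- "imputed_within"
      }
    }
  }
  # stage 2: copy across conditions (replicate-wise; recycled if counts
  # differ between the conditions)
  for (cond in conds) {
    cols <- which(panel$conditions == cond)
    other <- setdiff(conds, cond)
    for (m in seq_len(nrow(v))) {
      if (all(is.na(v[m, cols]))) {
        for (oc in other) {
          src <- which(panel$conditions == oc)
          if (!all(is.na(v[m, src]))) {
            v[m, cols] <- rep_len(v[m, src], length(cols))
            pr[m, cols] <- "imputed_across"
            break
          }
        }
      }
    }
  }
  # stage 3: external fallback, constant everywhere
  still <- rownames(v)[apply(v, 1, function(r) all(is.na(r)))]
  for (m in still) {
    key <- match(tolower(m), tolower(names(fallback)))
    if (!is.na(key)) {
      v[m, ] <- fallback[[key]]
      pr[m, ] <- "external_fallback"
    }
  }
  missing <- rownames(v)[apply(v, 1, function(r) all(is.na(r)))]
  out <- panel
  out$values <- v
  out$provenance <- pr
  attr(out, "report") <- list(missing = missing)
  out
}

#' Log-normality diagnostics for a panel
#'
#' Advisory report on whether log2 concentrations per condition are
#' compatible with a normal distribution: quantile-quantile coordinates
#' against the normal and a Shapiro-Wilk statistic.
#'
#' @param panel a [metabolome_panel()].
#' @return per-condition list with `qq` (data.frame of theoretical/sample
#'   quantiles), `shapiro_W`, `p_value`, and a `note` for degenerate groups.
#' @export
log_normality_report <- function(panel) {
  out <- list()
  for (cond in unique(panel$conditions)) {
    cols <- which(panel$conditions == cond)
    z <- log2(as.vector(panel$values[, cols]))
    z <- z[is.finite(z)]
    if (length(z) < 3) {
      out[[cond]] <- list(note = "fewer than 3 observed values; skipped")
      next
    }
    if (stats::sd(z) == 0) {
      out[[cond]] <- list(note = "constant values; no statistic")
      next
    }
    zs <- sort(z)
    qq <- data.frame(
      theoretical = stats::qnorm(stats::ppoints(length(zs))),
      sample = zs)
    sw <- stats::shapiro.test(if (length(zs) > 5000) sample(zs, 5000) else zs)
    out[[cond]] <- list(qq = qq, shapiro_W = unname(sw$statistic),
                        p_value = sw$p.value)
  }
  out
}

# columns of a panel belonging to one condition
condition_columns <- function(panel, condition) {
  cols <- which(panel$conditions == condition)
  if (length(cols) == 0) stop("condition not in panel: ", condition)
  cols
}
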