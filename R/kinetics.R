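#' Mass-action terms for every reaction and sample
#'
#' Under mass-action kinetics each flux factorizes as
#' `v_i = k_i * m_i(x)` with `m_i(x) = prod_j x_j^{|s_ji|}` over the
#' substrates `j` of reaction `i`. Products never enter the term; a reaction
#' with no substrates (an import) has `m = 1` (empty product). External
#' (boundary) substrates contribute only if the panel carries a
#' concentration for them, otherwise they are excluded from the product.
#'
#' @param net a `reaction_network` (irreversible, i.e. after
#'   [split_reversible()]).
#' @param panel an imputed [metabolome_panel()].
#' @param on_missing what to do when an internal substrate has no
#'   concentration: `"undefined"` (default; the reaction's terms become `NA`
#'   and it is listed in the report) or `"error"`.
#' @return object of class `mass_action_profile`: list with `terms`
#'   (reaction x sample matrix), `conditions`, `replicates`,
#'   `imputed_flag` (per reaction, any contributing metabolite not
#'   "measured"), and `undefined` (reaction ids dropped for missing data).
#' @export
mass_action_terms <- function(net, panel, on_missing = c("undefined",
                                                         "error")) {
  on_missing <- match.arg(on_missing)
  ex <- substrate_exponents(net)        # species x reaction, |s_ji|
  nr <- ncol(ex)
  ns <- ncol(panel$values)
  terms <- matrix(1, nr, ns, dimnames = list(colnames(ex),
                                             colnames(panel$values)))
  imputed <- logical(nr)
  undefined <- character(0)
  internal <- net$metabolites$id[!net$metabolites$external &
                                   !net$metabolites$ignored]
  for (i in seq_len(nr)) {
    subs <- rownames(ex)[ex[, i] > 0]
    for (s in subs) {
      row <- match(s, rownames(panel$values))
      if (is.na(row) || all(is.na(panel$values[row, ]))) {
        if (s %in% internal) {
          if (on_missing == "error")
            stop("missing substrate concentration for ", s,
                 " in reaction ", colnames(ex)[i])
          terms[i, ] <- NA_real_
          undefined <- c(undefined, colnames(ex)[i])
          break
        }
        next  # external substrate without data: excluded from the product
      }
      terms[i, ] <- terms[i, ] * panel$values[row, ]^ex[s, i]
      if (any(panel$provenance[row, ] != "measured")) imputed[i] <- TRUE
    }
  }
  structure(list(terms = terms, conditions = panel$conditions,
                 replicates = panel$replicates, imputed_flag = imputed,
                 undefined = unique(undefined)),
            class = "mass_action_profile")
}

# aggregate a profile over replicates of one condition
# (geometric mean by default: arithmetic mean in log space)
aggregate_terms <- function(profile, condition,
                            aggregate = c("geometric", "arithmetic")) {
  aggregate <- match.arg(aggregate)
  cols <- which(profile$conditions == condition)
  if (length(cols) == 0) stop("condition not in profile: ", condition)
  m <- profile$terms[, cols, drop = FALSE]
  if (aggregate == "geometric") exp(rowMeans(log(m))) else rowMeans(m)
}

#' Diagonal transformation between two conditions' k-cones
#'
#' The diagonal matrix `T = M_n M_d^{-1}` maps the normal-condition k-cone
#' onto the disease-condition one (`K_d = T K_n`); its entries are the
#' expected differential activities (EDAs). Replicates are aggregated by
#' geometric mean before forming the ratio.
#'
#' @param m_n,m_d `mass_action_profile`s for the normal and disease
#'   condition (may be the same object holding both conditions; then pass
#'   the condition labels).
#' @param normal,disease condition labels inside the profiles.
#' @param aggregate replicate aggregation, `"geometric"` (default) or
#'   `"arithmetic"`.
#' @return object of class `transform_matrix`: list with `diag` (named,
#'   `NA` where a term was undefined) and `condition_pair`.
#' @export
transformation_matrix <- function(m_n, m_d = m_n, normal = "normal",
                                  disease = "disease",
                                  aggregate = c("geometric", "arithmetic")) {
  aggregate <- match.arg(aggregate)
  an <- aggregate_terms(m_n, normal, aggregate)
  ad <- aggregate_terms(m_d, disease, aggregate)
  stopifnot(length(an) == length(ad))
  structure(list(diag = an / ad, condition_pair = c(normal, disease)),
            class = "transform_matrix")
}

#' @export
print.transform_matrix <- function(x, ...) {
  cat("transform_matrix (", x$condition_pair[1], "->",
      x$condition_pair[2], "):", length(x$diag), "reactions;",
      sum(is.na(x$diag)), "undefined\n")
  invisible(x)
}

#' Per-reaction EDA log2-fold-change samples
#'
#' For every (disease, normal) replicate pair, the log2 difference of the
#' mass-action terms, `log2 m_n - log2 m_d`. Because the terms are
#' monomials, each lfc equals the stoichiometry-weighted sum of the
#' substrates' concentration log-fold changes.
#'
#' @inheritParams transformation_matrix
#' @return list with `samples` (reaction x (r_n * r_d) matrix), `mean_lfc`
#'   (equals `log2 diag(T)` under geometric aggregation).
#' @export
eda_log_fold_changes <- function(m_n, m_d = m_n, normal = "normal",
                                 disease = "disease") {
  cn <- which(m_n$conditions == normal)
  cd <- which(m_d$conditions == disease)
  if (length(cn) < 1 || length(cd) < 1)
    stop("need at least one replicate per condition")
  zn <- log2(m_n$terms[, cn, drop = FALSE])
  zd <- log2(m_d$terms[, cd, drop = FALSE])
  combos <- expand.grid(d = seq_along(cd), n = seq_along(cn))
  samples <- matrix(NA_real_, nrow(zn), nrow(combos),
                    dimnames = list(rownames(zn),
                                    paste0("n", combos$n, ".d", combos$d)))
  for (j in seq_len(nrow(combos)))
    samples[, j] <- zn[, combos$n[j]] - zd[, combos$d[j]]
  list(samples = samples, mean_lfc = rowMeans(zn) - rowMeans(zd))
}

#' Apply flux weights to pinpoint kinetic constants
#'
#' With known steady-state fluxes the exact kinetic point follows from
#' `k_d = T W k_n`, where `W = diag(v_d / v_n)` carries the flux ratios.
#'
#' @param k_n per-reaction kinetic constants in the normal condition.
#' @param t a `transform_matrix`.
#' @param w per-reaction flux ratios `v_d / v_n` (named or aligned).
#' @return per-reaction kinetic constants in the disease condition.
#' @export
apply_flux_weights <- function(k_n, t, w = rep(1, length(k_n))) {
  if (length(k_n) != length(t$diag) || length(w) != length(t$diag))
    stop("dimension mismatch between k_n, T and W")
  if (any(k_n < 0) || any(w <= 0)) stop("k_n must be >= 0 and w > 0")
  unname(t$diag) * unname(w) * unname(k_n)
}
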