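#' Full differential enzyme-activity analysis
#'
#' Runs the metabolome-driven differential pipeline on an irreversible
#' network and an imputed two-condition panel: mass-action terms, EDAs
#' (log2 diagonal of the transformation `T = M_n M_d^{-1}`), moderated
#' Welch tests with BH correction, combinatorial lfc samples with
#' Bayes-bootstrap credible intervals, the heterogeneity screen, and (when
#' a biomass reaction is named) the FBA/FVA necessity filter.
#'
#' @param net irreversible `reaction_network`.
#' @param panel an imputed [metabolome_panel()] holding both conditions.
#' @param normal,disease condition labels; EDA > 0 means higher activity in
#'   `disease`.
#' @param biomass optional biomass reaction id enabling the necessity
#'   filter.
#' @param alpha FDR level for significance and necessity; default 0.05.
#' @param ratio_threshold heterogeneity threshold on `sigma_d/sigma_c`;
#'   default 3.
#' @param draws Bayes-bootstrap draws; default 10000.
#' @param seed RNG seed for the bootstrap; default 42.
#' @param lb,ub flux bounds when `biomass` is given.
#' @return object of class `differential_activity_result`: data.frame
#'   `table` with per-reaction `reaction, pathway, mean_lfc, t, df, p, q,
#'   ci_low, ci_high, sigma_c, sigma_d, heterogeneous, lfc_max, necessary,
#'   imputed`, plus `transform`, `lfc` (combinatorial samples),
#'   `undefined` (reactions dropped for missing substrate data), and
#'   `variability` (FVA table or `NULL`).
#' @export
differential_activity <- function(net, panel, normal = "normal",
                                  disease = "disease", biomass = NULL,
                                  alpha = 0.05, ratio_threshold = 3,
                                  draws = 10000, seed = 42,
                                  lb = 1e-16, ub = 1000) {
  profile <- mass_action_terms(net, panel)
  tmat <- transformation_matrix(profile, normal = normal, disease = disease)
  cn <- which(profile$conditions == normal)
  cd <- which(profile$conditions == disease)
  zn <- log2(profile$terms[, cn, drop = FALSE])
  zd <- log2(profile$terms[, cd, drop = FALSE])
  ok <- stats::complete.cases(zn) & stats::complete.cases(zd)
  test <- moderated_welch_test(zn[ok, , drop = FALSE], zd[ok, , drop = FALSE])
  lfc <- combinatorial_lfc(zn[ok, , drop = FALSE], zd[ok, , drop = FALSE])
  ci <- bayes_bootstrap_ci(lfc$differential, draws = draws, seed = seed)
  het <- heterogeneity_screen(lfc$control, lfc$differential,
                              ratio_threshold = ratio_threshold)
  ids <- net$reactions$id
  idx <- match(ids, rownames(test))
  tab <- data.frame(
    reaction = ids,
    pathway = net$reactions$pathway,
    mean_lfc = log2(tmat$diag)[ids],
    t = test$t[idx], df = test$df[idx], p = test$p[idx],
    q = adjust_fdr(test$p)[idx],
    ci_low = ci$ci_low[idx], ci_high = ci$ci_high[idx],
    sigma_c = het$sigma_c[idx], sigma_d = het$sigma_d[idx],
    heterogeneous = het$heterogeneous[idx],
    lfc_max = NA_real_, necessary = NA,
    imputed = profile$imputed_flag,
    stringsAsFactors = FALSE)
  var <- NULL
  if (!is.null(biomass)) {
    bounds <- flux_bounds(net, biomass, lb = lb, ub = ub)
    var <- flux_variability(net, bounds)
    tab$lfc_max <- var$lfc_max[match(ids, var$reaction)]
    nec <- necessity_filter(lfc$differential, tab$q[match(rownames(
      lfc$differential), ids)], var, alpha = alpha)
    tab$necessary <- nec[ids]
  }
  structure(list(table = tab, transform = tmat, lfc = lfc,
                 undefined = profile$undefined, variability = var,
                 alpha = alpha, seed = seed),
            class = "differential_activity_result")
}

#' @export
print.differential_activity_result <- function(x, ...) {
  tab <- x$table
  cat("differential_activity_result:", nrow(tab), "reactions;",
      sum(tab$q < x$alpha, na.rm = TRUE), "significant at q <", x$alpha,
      "\n")
  if (any(!is.na(tab$necessary)))
    cat("  necessary for proliferation:",
        sum(tab$necessary, na.rm = TRUE), "\n")
  if (length(x$undefined))
    cat("  dropped (undefined mass-action terms):",
        paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Write a differential result table to CSV
#'
#' @param result a [differential_activity()] result.
#' @param path output file.
#' @param meta named character vector written as `# key: value` header
#'   comments (run metadata: seed, package version, options).
#' @export
write_differential_result <- function(result, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(meta, package = as.character(utils::packageVersion("kcone")),
            seed = as.character(result$seed),
            aggregation = "geometric_mean",
            lfc_dependence = "combinatorial lfc samples are interdependent")
  writeLines(paste0("# ", names(meta), ": ", meta), con)
  utils::write.csv(result$table, con, row.names = FALSE)
  invisible(path)
}
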