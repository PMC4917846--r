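#' Jacobian of the mass-action ODE system
#'
#' For `dx/dt = S v(x)` with `v_i = k_i prod_j x_j^{e_ji}`
#' (`e_ji = |s_ji|` over substrates), the analytic derivative is
#' `dv_i/dx_j = k_i e_ji x_j^{e_ji - 1} prod_{l != j} x_l^{e_li}` and the
#' Jacobian is `J = S dv/dx`, restricted to internal metabolites
#' (boundary species are held fixed).
#'
#' @param net irreversible `reaction_network`.
#' @param k per-reaction kinetic constants (>= 0).
#' @param x named concentrations for (at least) all internal metabolites
#'   that appear as substrates; external substrates without a concentration
#'   are treated as absorbed into `k`.
#' @return Jacobian matrix (internal metabolites x internal metabolites).
#' @export
jacobian <- function(net, k, x) {
  if (any(k < 0)) stop("kinetic constants must be >= 0")
  ex <- substrate_exponents(net)
  internal <- rownames(net$S)
  if (is.null(names(x))) {
    if (length(x) != length(internal))
      stop("unnamed x must have one entry per internal metabolite")
    names(x) <- internal
  }
  xi <- x[internal]
  if (any(is.na(xi))) stop("missing concentration for internal metabolite(s): ",
                           paste(internal[is.na(xi)], collapse = ", "))
  if (any(xi <= 0)) {
    zero <- internal[xi <= 0]
    needs <- ex[zero, , drop = FALSE] > 0 & ex[zero, , drop = FALSE] < 1
    if (any(xi < 0) || any(needs))
      stop("non-positive concentration with fractional exponent")
  }
  nr <- ncol(ex)
  nm <- length(internal)
  Dv <- matrix(0, nr, nm, dimnames = list(colnames(ex), internal))
  for (i in seq_len(nr)) {
    subs <- rownames(ex)[ex[, i] > 0]
    # constant factor from external substrates with known concentration
    const <- 1
    int_subs <- character(0)
    for (s in subs) {
      if (s %in% internal) int_subs <- c(int_subs, s)
      else if (!is.na(x[s])) const <- const * x[[s]]^ex[s, i]
    }
    if (length(int_subs) == 0) next
    for (s in int_subs) {
      e <- ex[s, i]
      others <- setdiff(int_subs, s)
      prod_others <- if (length(others))
        prod(xi[others]^ex[others, i]) else 1
      Dv[i, s] <- k[i] * const * e * xi[[s]]^(e - 1) * prod_others
    }
  }
  net$S %*% Dv
}

#' Stability of every ray of a k-cone basis
#'
#' Each ray is interpreted as a vector of kinetic constants; the Jacobian
#' is evaluated at the given concentrations and its eigenvalues classified:
#' stable if all real parts are below `-eps`, unstable if any real part
#' exceeds `+eps`, otherwise marginal. `eps` is double-precision machine
#' epsilon, so the classification is robust to roundoff only.
#'
#' Extreme rays have sparse support, so metabolites untouched by a ray's
#' active reactions are pure spectator directions with structurally zero
#' eigenvalues; by default the spectrum is taken on the submatrix of
#' metabolites that participate in at least one active reaction, so those
#' neutral directions do not mask genuine stability.
#'
#' @param net irreversible `reaction_network`.
#' @param basis a k-cone [cone_basis()].
#' @param x named concentrations (see [jacobian()]).
#' @param eps threshold on eigenvalue real parts; default
#'   `.Machine$double.eps`.
#' @param active_only restrict the spectrum to metabolites touched by the
#'   ray's active reactions (default `TRUE`).
#' @return object of class `stability_report`: data.frame `per_ray`
#'   (`ray`, `max_real_eigenvalue`, `label`), list `spectra`, and
#'   `stable_fraction`.
#' @export
assess_stability <- function(net, basis, x, eps = .Machine$double.eps,
                             active_only = TRUE) {
  if (basis$kind != "kcone")
    stop("stability is assessed on k-cone bases (rays = kinetic constants)")
  n <- ncol(basis$rays)
  labels <- character(n)
  maxre <- numeric(n)
  spectra <- vector("list", n)
  internal <- rownames(net$S)
  for (j in seq_len(n)) {
    k <- basis$rays[, j]
    J <- jacobian(net, k, x)
    if (active_only) {
      active <- abs(k) > 1e-12 * max(abs(k), 1)
      touched <- internal[rowSums(abs(
        net$stoich[internal, active, drop = FALSE])) > 0]
      J <- J[touched, touched, drop = FALSE]
    }
    if (nrow(J) == 0) {
      spectra[[j]] <- complex(0)
      maxre[j] <- 0
      labels[j] <- "marginal"
      next
    }
    ev <- eigen(J, only.values = TRUE)$values
    re <- Re(ev)
    spectra[[j]] <- ev
    maxre[j] <- max(re)
    labels[j] <- if (all(re < -eps)) "stable"
      else if (any(re > eps)) "unstable" else "marginal"
  }
  structure(list(
    per_ray = data.frame(ray = seq_len(n), max_real_eigenvalue = maxre,
                         label = labels, stringsAsFactors = FALSE),
    spectra = spectra,
    stable_fraction = if (n > 0) mean(labels == "stable") else NA_real_),
    class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("stability_report:", nrow(x$per_ray), "rays;",
      round(100 * x$stable_fraction, 1), "% stable\n")
  print(table(x$per_ray$label))
  invisible(x)
}
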