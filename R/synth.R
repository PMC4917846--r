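#' Built-in toy networks
#'
#' Four documented fixtures used throughout the tests and examples:
#' \describe{
#'   \item{chain}{import -> A -> B -> export; 3 reactions, one flux mode.}
#'   \item{branch}{import A; A -> B; A -> C; drains of B and C.}
#'   \item{cycle}{import/export around A <-> B plus a return reaction,
#'     giving a through path and a futile cycle.}
#'   \item{glycolysis_mini}{a ~15-reaction sketch of central carbon
#'     metabolism: glycolysis with a reversible isomerase, a pentose
#'     phosphate branch, lactate fermentation, a lumped TCA/respiration
#'     drain and a biomass reaction ("BM") consuming precursors.}
#' }
#' Each network carries a default kinetic-constant vector in attribute
#' `"k_default"` under which a strictly positive steady state exists.
#'
#' @param kind one of `"chain"`, `"branch"`, `"cycle"`,
#'   `"glycolysis_mini"`.
#' @return a `reaction_network` (irreversible fixtures are returned as-is;
#'   `glycolysis_mini` contains one reversible reaction and should be run
#'   through [split_reversible()] for cone analysis).
#' @export
make_toy_network <- function(kind = c("chain", "branch", "cycle",
                                      "glycolysis_mini")) {
  kind <- match.arg(kind)
  strings <- switch(kind,
    chain = c(R1 = "-> A", R2 = "A -> B", R3 = "B ->"),
    branch = c(IN = "-> A", AB = "A -> B", AC = "A -> C",
               BOUT = "B ->", COUT = "C ->"),
    cycle = c(IN = "-> A", AB = "A -> B", BA = "B -> A", OUT = "B ->"),
    glycolysis_mini = c(
      GLCup = "GLC_e -> GLC",
      HK    = "GLC -> G6P",
      PGI   = "G6P <=> F6P",
      PFK   = "F6P -> FBP",
      ALD   = "FBP -> 2 G3P",
      PYK   = "G3P -> PYR",
      LDH   = "PYR -> LAC",
      LACex = "LAC -> LAC_e",
      G6PDH = "G6P -> RU5P",
      PPPret = "RU5P -> G3P",
      PRPPS = "RU5P -> PRPP",
      PDH   = "PYR -> ACO",
      TCA   = "ACO -> CO2_e",
      BM    = "G3P + PRPP + PYR ->"))
  pathway <- switch(kind,
    glycolysis_mini = c("exchange", "glycolysis", "glycolysis", "glycolysis",
                        "glycolysis", "glycolysis", "fermentation",
                        "exchange", "ppp", "ppp", "ppp", "tca", "tca",
                        "biomass"),
    NA_character_)
  net <- network_from_strings(strings, pathway = pathway)
  attr(net, "k_default") <- switch(kind,
    chain = c(R1 = 1, R2 = 0.5, R3 = 0.25),
    branch = c(IN = 1, AB = 0.6, AC = 0.4, BOUT = 0.5, COUT = 0.5),
    cycle = c(IN = 1, AB = 1, BA = 0.5, OUT = 0.5),
    glycolysis_mini = c(GLCup = 1, HK = 0.8, PGI_f = 2, PGI_b = 1,
                        PFK = 1.2, ALD = 1, PYK = 1.5, LDH = 0.9,
                        LACex = 1, G6PDH = 0.3, PPPret = 0.8, PRPPS = 0.4,
                        PDH = 0.5, TCA = 1, BM = 0.6))
  net
}

# mass-action fluxes v = k * m(x) for internal concentrations x (named)
mass_action_flux <- function(net, k, x) {
  ex <- substrate_exponents(net)
  internal <- rownames(net$S)
  v <- k
  for (i in seq_along(v)) {
    subs <- rownames(ex)[ex[, i] > 0]
    for (s in subs) {
      if (s %in% internal) v[i] <- v[i] * x[[s]]^ex[s, i]
      else if (!is.null(names(x)) && s %in% names(x))
        v[i] <- v[i] * x[[s]]^ex[s, i]
    }
  }
  v
}

#' Simulate the steady state of a mass-action network
#'
#' Integrates `dx/dt = S v(x)` with `deSolve` in growing time windows until
#' the largest rate falls below `tol` (default `1e-10`).
#'
#' @param net irreversible `reaction_network`.
#' @param k per-reaction kinetic constants (> 0 where the reaction should
#'   carry flux).
#' @param x0 initial internal concentrations; default all 1.
#' @param tol convergence threshold on `max |dx/dt|`.
#' @param t_max give up beyond this integration time.
#' @return named vector of steady-state internal concentrations; attribute
#'   `residual` carries `max |S v|` at the solution.
#' @export
simulate_steady_state <- function(net, k, x0 = NULL, tol = 1e-10,
                                  t_max = 1e6) {
  internal <- rownames(net$S)
  if (is.null(x0)) x0 <- stats::setNames(rep(1, length(internal)), internal)
  if (is.null(names(x0))) names(x0) <- internal
  if (any(k < 0)) stop("kinetic constants must be >= 0")
  rhs <- function(t, x, parms) {
    x <- pmax(x, 1e-12)
    list(as.numeric(net$S %*% mass_action_flux(net, k, x)))
  }
  x <- x0
  t_end <- 10
  repeat {
    sol <- deSolve::ode(y = x, times = c(0, t_end), func = rhs,
                        parms = NULL, method = "lsoda")
    x <- sol[nrow(sol), internal]
    dx <- abs(as.numeric(net$S %*% mass_action_flux(net, k, x)))
    if (max(dx) < tol) break
    if (any(!is.finite(x)) || max(x) > 1e9)
      stop("trajectory diverged; max concentration ", max(x))
    if (t_end > t_max)
      stop("no steady state within t_max (residual ", max(dx), ")")
    t_end <- t_end * 4
  }
  res <- max(abs(net$S %*% mass_action_flux(net, k, x)))
  out <- stats::setNames(as.numeric(x), internal)
  attr(out, "residual") <- res
  out
}

#' Synthetic two-condition scenario with planted regulation
#'
#' Builds the study conditions the pipeline is validated on: a network with
#' known kinetic constants, a disease condition whose constants are the
#' normal ones times planted fold changes, steady states simulated for
#' both, and replicate metabolome panels drawn with multiplicative
#' log-normal noise (`x * exp(eps)`, `eps ~ N(0, sigma^2)` with `sigma`
#' set so the linear-scale coefficient of variation equals `noise_cv`).
#' Defaults mirror the measured data the method targets: 3 biological
#' replicates per condition and an 8-fold planted activity change.
#'
#' @param net irreversible `reaction_network`.
#' @param perturbed named numeric vector of fold changes (`k_d = fold *
#'   k_n`), e.g. `c(HK = 8)`. Default none.
#' @param k_n normal-condition kinetic constants; defaults to the
#'   network's `"k_default"` attribute.
#' @param noise_cv replicate coefficient of variation; default 0.2.
#' @param replicates replicates per condition; default 3.
#' @param seed RNG seed; default 42.
#' @return object of class `synthetic_scenario`: `network`, `k_n`, `k_d`,
#'   `x_n`, `x_d`, `panel` (a two-condition [metabolome_panel()] with
#'   conditions `"normal"` / `"disease"`), `truth` (per-reaction true
#'   `log2(k_d/k_n)`), `noise_cv`, `replicates`, `seed`.
#' @export
make_scenario <- function(net, perturbed = numeric(), k_n = NULL,
                          noise_cv = 0.2, replicates = 3, seed = 42) {
  if (any(perturbed <= 0)) stop("fold changes must be > 0")
  if (is.null(k_n)) k_n <- attr(net, "k_default")
  if (is.null(k_n)) stop("supply k_n (network has no default constants)")
  ids <- net$reactions$id
  k_n <- k_n[ids]
  if (any(is.na(k_n))) stop("k_n misses reactions")
  k_d <- k_n
  if (length(perturbed)) {
    bad <- setdiff(names(perturbed), ids)
    if (length(bad)) stop("perturbed reaction(s) not in network: ",
                          paste(bad, collapse = ", "))
    k_d[names(perturbed)] <- k_d[names(perturbed)] * perturbed
  }
  x_n <- simulate_steady_state(net, k_n)
  x_d <- tryCatch(simulate_steady_state(net, k_d, x0 = x_n),
                  error = function(e)
                    stop("perturbation destabilizes the steady state: ",
                         conditionMessage(e)))
  sigma <- sqrt(log(1 + noise_cv^2))
  internal <- rownames(net$S)
  nm <- length(internal)
  panel <- with_seed(seed, {
    draw <- function(x) vapply(seq_len(replicates), function(r)
      x * exp(stats::rnorm(nm, 0, sigma)), numeric(nm))
    vn <- draw(x_n); vd <- draw(x_d)
    metabolome_panel(cbind(vn, vd),
                     conditions = rep(c("normal", "disease"),
                                      each = replicates),
                     replicates = rep(seq_len(replicates), 2))
  })
  rownames(panel$values) <- internal
  rownames(panel$provenance) <- internal
  structure(list(network = net, k_n = k_n, k_d = k_d, x_n = x_n, x_d = x_d,
                 panel = panel,
                 truth = stats::setNames(log2(k_d / k_n), ids),
                 noise_cv = noise_cv, replicates = replicates, seed = seed),
            class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("synthetic_scenario:", length(x$k_n), "reactions,", x$replicates,
      "replicates/condition, noise_cv =", x$noise_cv, "\n")
  pl <- x$truth[x$truth != 0]
  if (length(pl)) cat("  planted log2 fold changes:",
                      paste(names(pl), round(pl, 3), sep = "=",
                            collapse = ", "), "\n")
  invisible(x)
}

#' Write a scenario as CSV fixtures
#'
#' Emits the standard network CSV, the long-format metabolome CSV and a
#' truth-table CSV (`reaction, true_log2_fold`), so the command-line
#' interface can be driven entirely from generated files.
#'
#' @param scenario a [make_scenario()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  npath <- file.path(dir, "network.csv")
  mpath <- file.path(dir, "metabolome.csv")
  tpath <- file.path(dir, "truth.csv")
  write_network(scenario$network, npath)
  p <- scenario$panel
  long <- data.frame(
    metabolite = rep(rownames(p$values), ncol(p$values)),
    condition = rep(p$conditions, each = nrow(p$values)),
    replicate = rep(p$replicates, each = nrow(p$values)),
    value = as.vector(p$values))
  utils::write.csv(long[!is.na(long$value), ], mpath, row.names = FALSE)
  utils::write.csv(data.frame(reaction = names(scenario$truth),
                              true_log2_fold = as.numeric(scenario$truth)),
                   tpath, row.names = FALSE)
  invisible(c(network = npath, metabolome = mpath, truth = tpath))
}
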