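# Newton inversion of the trigamma function (used by the moments estimator
# for the inverse-chi-square prior degrees of freedom).
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    x <- 0.5 + 1 / yi
    for (iter in 1:75) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, numeric(1))
}

#' Empirical-Bayes hyperparameters for variance moderation
#'
#' Fits a scaled inverse-chi-square prior `sigma^2 ~ s0^2 invchisq(d0)` to a
#' set of sample variances with common degrees of freedom, by the method of
#' moments on the log variances: the excess spread of `log s^2` beyond the
#' chi-square sampling noise identifies `d0`, and the location identifies
#' `s0^2`. `d0 = Inf` (all variances equal `s0^2` a posteriori) is returned
#' when no excess spread is found.
#'
#' @param s2 sample variances across features.
#' @param df their degrees of freedom (scalar).
#' @return list `d0`, `s02`.
#' @export
eb_variance_prior <- function(s2, df) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2) stop("need at least two positive variances")
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(d0 = d0, s02 = s02)
}

moderate_variance <- function(s2, df, prior) {
  if (!is.finite(prior$d0)) return(rep(prior$s02, length(s2)))
  (prior$d0 * prior$s02 + df * s2) / (prior$d0 + df)
}

#' Moderated Welch t-test on log mass-action terms
#'
#' Per-reaction Welch test of `log2 m_n` versus `log2 m_d` where each
#' condition's sample variance is shrunk toward an empirical-Bayes prior
#' fitted across all reactions (both conditions pooled). Degrees of freedom
#' follow Welch-Satterthwaite with each group's df inflated by the prior
#' df `d0`, so that `d0 -> Inf` recovers a z-like test at the prior
#' variance and `d0 = 0` recovers the ordinary Welch test.
#'
#' @param log_n,log_d reaction x replicate matrices of log2 terms.
#' @param prior optional list `d0`, `s02` overriding the fitted prior.
#' @return data.frame `mean_lfc` (`n - d`), `t`, `df`, `p`; attribute
#'   `prior` carries the hyperparameters used. Rows with zero variance in
#'   both groups and no prior spread get `NA` statistics.
#' @export
moderated_welch_test <- function(log_n, log_d, prior = NULL) {
  log_n <- as.matrix(log_n); log_d <- as.matrix(log_d)
  nn <- ncol(log_n); nd <- ncol(log_d)
  if (nn < 2 || nd < 2) stop("need >= 2 replicates per condition")
  mn <- rowMeans(log_n); md <- rowMeans(log_d)
  vn <- apply(log_n, 1, stats::var); vd <- apply(log_d, 1, stats::var)
  if (is.null(prior)) {
    pooled <- c(vn, vd)
    dfs <- rep(c(nn - 1, nd - 1), times = c(length(vn), length(vd)))
    # moments fit needs a common df; use the (typical) balanced case df,
    # falling back to the mean df if the design is unbalanced
    dfp <- if (nn == nd) nn - 1 else mean(c(nn, nd)) - 1
    prior <- eb_variance_prior(pooled[pooled > 0], dfp)
  }
  sv_n <- moderate_variance(vn, nn - 1, prior)
  sv_d <- moderate_variance(vd, nd - 1, prior)
  se2 <- sv_n / nn + sv_d / nd
  t <- (mn - md) / sqrt(se2)
  # Welch-Satterthwaite df on the moderated variances at the residual
  # group dfs, inflated additively by the prior df: reduces to the
  # ordinary Welch df at d0 = 0 and to the usual moderated total df
  # (d0 + d_total) in the balanced pooled limit.
  df <- se2^2 / ((sv_n / nn)^2 / (nn - 1) + (sv_d / nd)^2 / (nd - 1)) +
    min(prior$d0, 1e12)
  p <- 2 * stats::pt(-abs(t), df)
  bad <- !is.finite(t)
  t[bad] <- NA; df[bad] <- NA; p[bad] <- NA
  out <- data.frame(mean_lfc = mn - md, t = t, df = df, p = p)
  rownames(out) <- rownames(log_n)
  attr(out, "prior") <- prior
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH q-values with monotonicity enforced; thin wrapper over
#' [stats::p.adjust()].
#'
#' @param p p-values in `[0, 1]` (`NA` allowed).
#' @return q-values aligned with `p`.
#' @export
adjust_fdr <- function(p) stats::p.adjust(p, method = "BH")

#' Combinatorial control and differential log-fold changes
#'
#' Control lfcs are all ordered pairs of distinct normal replicates
#' (`r_n (r_n - 1)` values per reaction, mean exactly zero by
#' antisymmetry); differential lfcs are all (disease, normal) replicate
#' pairs (`r_n r_d` values, `log2 m_n - log2 m_d`).
#'
#' @param log_n,log_d reaction x replicate matrices of log2 terms.
#' @return list `control`, `differential` (matrices, reactions x pairs).
#' @export
combinatorial_lfc <- function(log_n, log_d) {
  log_n <- as.matrix(log_n); log_d <- as.matrix(log_d)
  rn <- ncol(log_n); rd <- ncol(log_d)
  if (rn < 2) stop("control log-fold changes need >= 2 normal replicates")
  pairs <- expand.grid(i = seq_len(rn), j = seq_len(rn))
  pairs <- pairs[pairs$i != pairs$j, ]
  control <- matrix(NA_real_, nrow(log_n), nrow(pairs),
                    dimnames = list(rownames(log_n),
                                    paste0("n", pairs$i, ".n", pairs$j)))
  for (kk in seq_len(nrow(pairs)))
    control[, kk] <- log_n[, pairs$i[kk]] - log_n[, pairs$j[kk]]
  combos <- expand.grid(d = seq_len(rd), n = seq_len(rn))
  differential <- matrix(NA_real_, nrow(log_n), nrow(combos),
                         dimnames = list(rownames(log_n),
                                         paste0("n", combos$n, ".d",
                                                combos$d)))
  for (kk in seq_len(nrow(combos)))
    differential[, kk] <- log_n[, combos$n[kk]] - log_d[, combos$d[kk]]
  list(control = control, differential = differential)
}

#' Bayes-bootstrap credible interval for a mean log-fold change
#'
#' Draws uniform-Dirichlet weights over the samples and records the
#' weighted mean; the 2.5th/97.5th percentiles of the draws form the 95%
#' credible interval. Seeded and reproducible. Note that when the samples
#' are the combinatorial replicate pairs they are interdependent, which
#' this posterior does not correct for.
#'
#' @param lfc_samples numeric vector (>= 2 values) or reaction x sample
#'   matrix (one interval per row).
#' @param draws number of Dirichlet draws; default 10000 (a warning is
#'   issued below 100).
#' @param seed RNG seed; default 42.
#' @param level credible level; default 0.95.
#' @return for a vector: `c(ci_low, ci_high)`; for a matrix: a data.frame
#'   with `ci_low`, `ci_high` per row.
#' @export
bayes_bootstrap_ci <- function(lfc_samples, draws = 10000, seed = 42,
                               level = 0.95) {
  if (draws < 100) warning("fewer than 100 bootstrap draws; intervals noisy")
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  one <- function(y) {
    y <- y[is.finite(y)]
    if (length(y) < 2) return(c(NA_real_, NA_real_))
    if (stats::sd(y) == 0) return(c(y[1], y[1]))
    W <- matrix(stats::rexp(draws * length(y)), nrow = draws)
    W <- W / rowSums(W)
    unname(stats::quantile(as.numeric(W %*% y), probs))
  }
  with_seed(seed, {
    if (is.matrix(lfc_samples)) {
      out <- t(apply(lfc_samples, 1, one))
      data.frame(ci_low = out[, 1], ci_high = out[, 2],
                 row.names = rownames(lfc_samples))
    } else {
      ci <- one(as.numeric(lfc_samples))
      stats::setNames(ci, c("ci_low", "ci_high"))
    }
  })
}

#' Differential-heterogeneity screen
#'
#' Compares the spread of the differential lfc samples to the spread of
#' the control lfc samples per reaction; a reaction is differentially
#' heterogeneous when `sigma_d / sigma_c` exceeds the threshold (default
#' 3-fold).
#'
#' @param control,differential matrices from [combinatorial_lfc()].
#' @param ratio_threshold flag threshold on `sigma_d / sigma_c`; default 3.
#' @return data.frame `sigma_c`, `sigma_d`, `ratio`, `heterogeneous`
#'   (`NA` where `sigma_c` is zero, reported via attribute `degenerate`).
#' @export
heterogeneity_screen <- function(control, differential,
                                 ratio_threshold = 3) {
  sc <- row_sds(control)
  sd_ <- row_sds(differential)
  ratio <- ifelse(sc > 0, sd_ / sc, NA_real_)
  out <- data.frame(sigma_c = sc, sigma_d = sd_, ratio = ratio,
                    heterogeneous = ratio > ratio_threshold,
                    row.names = rownames(control))
  attr(out, "degenerate") <- rownames(control)[!is.na(sc) & sc == 0]
  out
}

#' Co-regulation matrix of heterogeneous reactions
#'
#' Pearson correlations between the differential lfc sample vectors of the
#' selected (typically differentially heterogeneous) reactions.
#'
#' @param differential reaction x sample lfc matrix (rows already
#'   restricted to the reactions of interest; >= 3 samples).
#' @return symmetric correlation matrix with unit diagonal; `NA` entries
#'   where a vector is constant.
#' @export
coregulation_matrix <- function(differential) {
  if (ncol(differential) < 3) stop("need >= 3 lfc samples per reaction")
  suppressWarnings(stats::cor(t(differential), method = "pearson"))
}
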