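# Independent oracles the implementation is checked against. These stay
# deliberately naive: brute force over support patterns, central
# differences, direct textbook formulas.

# Extreme rays of {x >= 0 : A x = 0} by minimal-support enumeration:
# a support J carries an extreme ray iff null(A[, J]) is one-dimensional,
# can be signed positive on J, and no smaller support works.
oracle_extreme_rays <- function(A, tol = 1e-9) {
  n <- ncol(A)
  stopifnot(n <= 12)
  rays <- list()
  supports <- list()
  for (code in seq_len(2^n - 1)) {
    J <- which(bitwAnd(code, bitwShiftL(1, seq_len(n) - 1)) > 0)
    sub <- A[, J, drop = FALSE]
    ns <- svd(sub, nu = 0, nv = length(J))
    null_dim <- sum(c(ns$d, rep(0, length(J) - length(ns$d))) < tol)
    if (null_dim != 1) next
    v <- ns$v[, length(J)]
    if (all(v >= -tol)) v <- v else if (all(v <= tol)) v <- -v else next
    if (any(abs(v) < tol)) next  # support not tight -> smaller support exists
    full <- numeric(n)
    full[J] <- v
    rays[[length(rays) + 1]] <- full / sqrt(sum(full^2))
    supports[[length(supports) + 1]] <- J
  }
  if (length(rays) == 0) return(matrix(0, n, 0))
  # keep minimal supports only
  keep <- rep(TRUE, length(supports))
  for (i in seq_along(supports)) for (j in seq_along(supports)) {
    if (i != j && keep[i] && all(supports[[j]] %in% supports[[i]]) &&
        length(supports[[j]]) < length(supports[[i]])) keep[i] <- FALSE
  }
  R <- do.call(cbind, rays[keep])
  R[, !duplicated(apply(round(R, 8), 2, paste, collapse = ",")),
    drop = FALSE]
}

# canonical string form of a ray set for set comparison
ray_set_key <- function(R, digits = 6) {
  sort(apply(round(R, digits), 2, paste, collapse = ","))
}

expect_same_ray_set <- function(R1, R2, tol = 1e-6) {
  expect_equal(ncol(R1), ncol(R2))
  match_one <- function(r, B) any(apply(B, 2, function(b)
    max(abs(b - r)) < tol))
  expect_true(all(apply(R1, 2, match_one, B = R2)))
  expect_true(all(apply(R2, 2, match_one, B = R1)))
}

# central-difference Jacobian of dx/dt = S v(x)
numeric_jacobian <- function(net, k, x, h = 1e-6) {
  internal <- rownames(net$S)
  f <- function(xx) {
    names(xx) <- internal
    as.numeric(net$S %*% (k * kcone:::mass_action_flux(
      net, rep(1, length(k)), xx)))
  }
  J <- matrix(0, length(internal), length(internal))
  x0 <- as.numeric(x[internal])
  for (j in seq_along(x0)) {
    xp <- x0; xm <- x0
    xp[j] <- xp[j] + h; xm[j] <- xm[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  dimnames(J) <- list(internal, internal)
  J
}

# small random irreversible network with a guaranteed-nontrivial flux cone:
# a chain plus random extra first-order conversions and exchanges
random_small_network <- function(n_reactions = 6, n_mets = 3, seed = 1) {
  set.seed(seed)
  mets <- LETTERS[seq_len(n_mets)]
  strings <- c(IN = paste("->", mets[1]))
  for (i in seq_len(n_mets - 1))
    strings[paste0("C", i)] <- paste(mets[i], "->", mets[i + 1])
  strings[["OUT"]] <- paste(mets[n_mets], "->")
  extra <- n_reactions - length(strings)
  i <- 0
  while (i < extra) {
    pair <- sample(mets, 2)
    id <- paste0("X", i + 1)
    strings[[id]] <- paste(pair[1], "->", pair[2])
    i <- i + 1
  }
  network_from_strings(strings)
}

# balanced two-group log-normal null data, mimicking log2 mass-action terms
null_log_terms <- function(n_reactions, reps = 3, sd = 0.3, seed = 1) {
  set.seed(seed)
  list(n = matrix(rnorm(n_reactions * reps, 0, sd), n_reactions),
       d = matrix(rnorm(n_reactions * reps, 0, sd), n_reactions))
}
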