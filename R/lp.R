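# Small dense linear-programming solver used for the FBA/FVA programs and
# cone-membership feasibility checks. Networks here are tiny (tens of
# reactions), so a two-phase tableau simplex with Bland's anti-cycling rule
# is robust and fully deterministic.

# minimize c'x subject to A x = b, x >= 0  (b is made non-negative by row
# negation). Returns list(status, x, value); status 0 optimal, 1 infeasible,
# 2 unbounded/stalled.
simplex_standard <- function(A, b, cc, tol = 1e-9, max_iter = 10000) {
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  # phase 1 tableau: [A | I_art | b]
  tab <- cbind(A, diag(m), b)
  basis <- n + seq_len(m)
  run <- function(tab, basis, cost, allowed) {
    for (iter in seq_len(max_iter)) {
      cb <- cost[basis]
      red <- cost[allowed] - as.numeric(cb %*% tab[, allowed, drop = FALSE])
      ent <- allowed[which(red < -tol)]
      if (length(ent) == 0) return(list(tab = tab, basis = basis, ok = TRUE))
      j <- min(ent)  # Bland
      col <- tab[, j]
      rows <- which(col > tol)
      if (length(rows) == 0)
        return(list(tab = tab, basis = basis, ok = FALSE, unbounded = TRUE))
      ratios <- tab[rows, ncol(tab)] / col[rows]
      best <- rows[ratios <= min(ratios) + tol]
      i <- best[which.min(basis[best])]  # Bland tie-break
      piv <- tab[i, j]
      tab[i, ] <- tab[i, ] / piv
      for (r in seq_len(nrow(tab))) if (r != i && abs(tab[r, j]) > 0)
        tab[r, ] <- tab[r, ] - tab[r, j] * tab[i, ]
      basis[i] <- j
      tab <- tab
    }
    list(tab = tab, basis = basis, ok = FALSE, unbounded = FALSE)
  }
  cost1 <- c(rep(0, n), rep(1, m))
  res <- run(tab, basis, cost1, seq_len(n + m))
  if (!res$ok) return(list(status = 2L, x = NULL, value = NA_real_))
  obj1 <- sum(cost1[res$basis] * res$tab[, ncol(res$tab)])
  if (obj1 > 1e-7) return(list(status = 1L, x = NULL, value = NA_real_))
  tab <- res$tab; basis <- res$basis
  # drive leftover artificials out of the (degenerate) basis
  drop_rows <- integer(0)
  for (i in which(basis > n)) {
    cand <- which(abs(tab[i, seq_len(n)]) > tol)
    if (length(cand) > 0) {
      j <- min(cand)
      piv <- tab[i, j]
      tab[i, ] <- tab[i, ] / piv
      for (r in seq_len(nrow(tab))) if (r != i && abs(tab[r, j]) > 0)
        tab[r, ] <- tab[r, ] - tab[r, j] * tab[i, ]
      basis[i] <- j
    } else drop_rows <- c(drop_rows, i)  # redundant constraint row
  }
  if (length(drop_rows)) {
    tab <- tab[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }
  cost2 <- c(cc, rep(0, m))
  res <- run(tab, basis, cost2, seq_len(n))
  if (!res$ok)
    return(list(status = if (isTRUE(res$unbounded)) 2L else 2L,
                x = NULL, value = NA_real_))
  x <- numeric(n)
  vals <- res$tab[, ncol(res$tab)]
  inb <- res$basis <= n
  x[res$basis[inb]] <- vals[inb]
  list(status = 0L, x = x, value = sum(cc * x))
}

# minimize / maximize  obj' v  subject to  Aeq v = beq, lb <= v <= ub
# (lb defaults to 0; ub optional). Bounded variables are shifted to
# y = v - lb >= 0 and upper bounds become slack rows.
solve_lp <- function(obj, Aeq, beq, lb = NULL, ub = NULL, maximize = FALSE,
                     tol = 1e-9) {
  n <- length(obj)
  if (is.null(lb)) lb <- rep(0, n) else lb <- rep_len(lb, n)
  A <- Aeq
  b <- beq - as.numeric(Aeq %*% lb)
  nslack <- 0
  if (!is.null(ub)) {
    ub <- rep_len(ub, n)
    A <- rbind(cbind(A, matrix(0, nrow(A), n)),
               cbind(diag(n), diag(n)))
    b <- c(b, ub - lb)
    nslack <- n
  }
  cc <- c(if (maximize) -obj else obj, rep(0, nslack))
  res <- simplex_standard(as.matrix(A), b, cc, tol = tol)
  if (res$status != 0)
    return(list(status = res$status, x = NULL, value = NA_real_))
  v <- res$x[seq_len(n)] + lb
  list(status = 0L, x = v, value = sum(obj * v))
}

#' Test whether a ray lies in the cone spanned by a basis
#'
#' Feasibility linear program: does there exist `lambda >= 0` with
#' `B lambda = ray`? Both the basis columns and the ray are scaled to unit
#' norm first; feasibility is decided by an elastic phase-1 formulation
#' whose optimal slack must not exceed `tol`.
#'
#' @param basis matrix whose columns span the cone (or a `cone_basis`).
#' @param ray numeric vector.
#' @param tol feasibility tolerance on the residual.
#' @return `TRUE` if the ray is a non-negative combination of the columns.
#' @export
in_cone <- function(basis, ray, tol = 1e-7) {
  B <- if (inherits(basis, "cone_basis")) basis$rays else as.matrix(basis)
  r <- ray / sqrt(sum(ray^2))
  m <- nrow(B); n <- ncol(B)
  # minimize sum of elastic slacks: B lambda + s+ - s- = r
  obj <- c(rep(0, n), rep(1, 2 * m))
  Aeq <- cbind(B, diag(m), -diag(m))
  res <- solve_lp(obj, Aeq, r, maximize = FALSE)
  res$status == 0 && res$value <= tol
}
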