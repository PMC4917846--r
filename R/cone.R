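#' Cone basis container
#'
#' Columns of `rays` are the extreme rays of a polyhedral cone (flux cone or
#' k-cone), non-negative and normalized to unit Euclidean length, in a
#' deterministic lexicographic order.
#'
#' @param rays non-negative matrix, reactions x rays.
#' @param kind `"flux"` or `"kcone"`.
#' @param reaction_ids row labels.
#' @param constraints_applied character vector describing extra constraints.
#' @return object of class `cone_basis`.
#' @export
cone_basis <- function(rays, kind = c("flux", "kcone"),
                       reaction_ids = rownames(rays),
                       constraints_applied = character()) {
  kind <- match.arg(kind)
  rays <- as.matrix(rays)
  if (!is.null(reaction_ids)) rownames(rays) <- reaction_ids
  structure(list(rays = rays, kind = kind, reaction_ids = reaction_ids,
                 constraints_applied = constraints_applied),
            class = "cone_basis")
}

#' @export
print.cone_basis <- function(x, ...) {
  cat("cone_basis (", x$kind, "):", nrow(x$rays), "reactions x",
      ncol(x$rays), "extreme rays\n")
  if (length(x$constraints_applied))
    cat("  constraints:", paste(x$constraints_applied, collapse = "; "), "\n")
  invisible(x)
}

normalize_columns <- function(R) {
  nrm <- sqrt(colSums(R^2))
  keep <- nrm > 0
  sweep(R[, keep, drop = FALSE], 2, nrm[keep], "/")
}

# deterministic lexicographic order on rounded coordinates
order_rays <- function(R, digits = 10) {
  if (ncol(R) <= 1) return(R)
  key <- apply(round(R, digits), 2, paste, collapse = ",")
  R[, order(key), drop = FALSE]
}

# drop linearly dependent (redundant) rows of the H-representation
independent_rows <- function(A, tol = 1e-10) {
  if (nrow(A) == 0) return(A)
  qrA <- qr(t(A), tol = tol)
  A[sort(qrA$pivot[seq_len(qrA$rank)]), , drop = FALSE]
}

#' Extreme rays of \{x >= 0 : A x = 0\} by double description
#'
#' Incremental double description: starting from the non-negative orthant
#' (rays = unit vectors) each equality hyperplane is intersected in turn;
#' surviving rays plus adjacent positive/negative combinations form the new
#' generating set. Adjacency uses the combinatorial test on zero patterns,
#' valid because the cone is pointed.
#'
#' @param A equality-constraint matrix (rows are constraints).
#' @param tol degeneracy tolerance for classifying `A x` signs.
#' @param max_rays abort if the intermediate ray count exceeds this guard
#'   (large models blow up combinatorially; equilibrium-constant
#'   constraints reduce the cone first).
#' @return matrix of extreme rays (columns, unit norm, lexicographic order).
#' @export
double_description <- function(A, tol = 1e-10, max_rays = 2e5) {
  n <- ncol(A)
  A <- independent_rows(A, tol)
  R <- diag(n)
  Z <- !diag(n)  # zero patterns over the n non-negativity constraints
  for (row in seq_len(nrow(A))) {
    a <- A[row, ]
    d <- as.numeric(a %*% R)
    scale <- max(abs(d), 1)
    zero <- abs(d) <= tol * scale
    pos <- which(d > tol * scale)
    neg <- which(d < -tol * scale)
    keepR <- R[, zero, drop = FALSE]
    keepZ <- Z[, zero, drop = FALSE]
    newR <- list(); newZ <- list()
    if (length(pos) && length(neg)) {
      for (p in pos) for (q in neg) {
        zz <- Z[, p] & Z[, q]
        # combinatorial adjacency: no third ray's zero set contains zz
        others <- setdiff(seq_len(ncol(R)), c(p, q))
        adjacent <- TRUE
        if (length(others)) {
          contains <- colSums(Z[zz, others, drop = FALSE]) == sum(zz)
          if (any(contains)) adjacent <- FALSE
        }
        if (adjacent) {
          v <- d[p] * R[, q] - d[q] * R[, p]
          v <- v / sqrt(sum(v^2))
          v[abs(v) <= tol] <- 0
          newR[[length(newR) + 1]] <- v
          newZ[[length(newZ) + 1]] <- v == 0
        }
      }
    }
    R <- cbind(keepR, if (length(newR)) do.call(cbind, newR))
    Z <- cbind(keepZ, if (length(newZ)) do.call(cbind, newZ))
    if (is.null(R) || ncol(R) == 0) {
      R <- matrix(0, n, 0); Z <- matrix(FALSE, n, 0)
      break
    }
    if (ncol(R) > max_rays)
      stop("ray count guard exceeded (", ncol(R), " > ", max_rays,
           "); consider equilibrium-constant constraints to reduce the cone")
  }
  if (ncol(R) == 0) return(matrix(0, n, 0))
  R <- normalize_columns(R)
  # dedupe numerically identical rays
  key <- apply(round(R, 9), 2, paste, collapse = ",")
  R <- R[, !duplicated(key), drop = FALSE]
  order_rays(R)
}

#' Enumerate the flux cone of an irreversible network
#'
#' Extreme rays of `{v >= 0 : S v = 0}`. Redundant rows of the
#' H-representation are removed first and the basis columns are normalized
#' to unit length.
#'
#' @param net a `reaction_network` with no reversible reactions
#'   (apply [split_reversible()] first).
#' @param tol degeneracy tolerance.
#' @param max_rays combinatorial guard (default 2e5).
#' @return a [cone_basis()] of kind `"flux"`. A trivial cone `{0}` gives an
#'   empty basis with a warning.
#' @export
enumerate_flux_cone <- function(net, tol = 1e-10, max_rays = 2e5) {
  if (any(net$reactions$reversible))
    stop("network has reversible reactions; apply split_reversible() first")
  R <- double_description(net$S, tol = tol, max_rays = max_rays)
  if (ncol(R) == 0) warning("flux cone is trivial ({0}); empty basis")
  cone_basis(R, "flux", reaction_ids = net$reactions$id)
}

#' k-cone from a flux-cone basis and mass-action terms
#'
#' Each flux ray `v` maps to the kinetic ray `normalize(M^{-1} v)` where `M`
#' is the diagonal matrix of mass-action terms, so that `S M k = 0`.
#'
#' @param flux_basis a flux [cone_basis()].
#' @param m per-reaction mass-action terms: a named/aligned positive vector,
#'   or a `mass_action_profile` together with `condition`.
#' @param condition condition label when `m` is a profile (replicates are
#'   aggregated by geometric mean).
#' @return a [cone_basis()] of kind `"kcone"`.
#' @export
compute_kcone <- function(flux_basis, m, condition = NULL) {
  if (inherits(m, "mass_action_profile"))
    m <- aggregate_terms(m, condition)
  m <- as.numeric(m)
  if (length(m) != nrow(flux_basis$rays))
    stop("mass-action term vector does not match reaction count")
  if (any(!is.finite(m)) || any(m <= 0)) {
    bad <- flux_basis$reaction_ids[!is.finite(m) | m <= 0]
    stop("non-positive or undefined mass-action term for reaction(s): ",
         paste(bad, collapse = ", "))
  }
  K <- order_rays(normalize_columns(flux_basis$rays / m))
  cone_basis(K, "kcone", reaction_ids = flux_basis$reaction_ids,
             constraints_applied = flux_basis$constraints_applied)
}

#' k-cone constrained by equilibrium constants
#'
#' Enumerates `{k >= 0 : S M k = 0, k_f - K_eq k_b = 0}` directly, one
#' equality per constrained forward/backward pair from
#' [split_reversible()]. The constrained basis is typically much smaller
#' than the unconstrained one.
#'
#' @param net irreversible `reaction_network`.
#' @param m per-reaction mass-action terms (vector or profile, see
#'   [compute_kcone()]).
#' @param keq data.frame with columns `forward`, `backward`, `keq`
#'   (all `keq > 0`), or `NULL` for no constraints.
#' @param condition condition label when `m` is a profile.
#' @inheritParams enumerate_flux_cone
#' @return a [cone_basis()] of kind `"kcone"`.
#' @export
constrain_by_keq <- function(net, m, keq = NULL, condition = NULL,
                             tol = 1e-10, max_rays = 2e5) {
  if (inherits(m, "mass_action_profile"))
    m <- aggregate_terms(m, condition)
  m <- as.numeric(m)
  if (any(!is.finite(m)) || any(m <= 0))
    stop("mass-action terms must be positive and finite")
  A <- net$S %*% diag(m, nrow = length(m))
  labels <- character()
  if (!is.null(keq) && nrow(keq) > 0) {
    if (any(keq$keq <= 0)) stop("equilibrium constants must be > 0")
    ids <- net$reactions$id
    extra <- matrix(0, nrow(keq), length(ids))
    for (i in seq_len(nrow(keq))) {
      f <- match(keq$forward[i], ids); b <- match(keq$backward[i], ids)
      if (is.na(f) || is.na(b))
        stop("keq table refers to unknown reaction pair: ",
             keq$forward[i], "/", keq$backward[i])
      extra[i, f] <- 1
      extra[i, b] <- -keq$keq[i]
    }
    A <- rbind(A, extra)
    labels <- paste0("keq:", keq$forward, "/", keq$backward, "=", keq$keq)
  }
  R <- double_description(A, tol = tol, max_rays = max_rays)
  cone_basis(R, "kcone", reaction_ids = net$reactions$id,
             constraints_applied = labels)
}

#' Restrict a basis to reactions with changed mass-action terms
#'
#' Keeps only the rows whose transformation entry changed by at least the
#' given fold (`|log2 diag(T)| >= log2 threshold`), renormalizes the rays
#' and drops all-zero columns. Used to visualize the subspace where two
#' conditions' k-cones actually differ.
#'
#' @param basis a [cone_basis()].
#' @param t a `transform_matrix`.
#' @param threshold fold-change threshold (>= 1); default 2.
#' @return restricted [cone_basis()]; empty (with a warning) if no reaction
#'   passes.
#' @export
filter_changed_reactions <- function(basis, t, threshold = 2) {
  if (threshold < 1) stop("threshold must be >= 1")
  lfc <- log2(t$diag)
  keep <- which(!is.na(lfc) & abs(lfc) >= log2(threshold))
  if (length(keep) == 0) {
    warning("no reaction passes the fold-change threshold; empty basis")
    return(cone_basis(matrix(0, 0, 0), basis$kind,
                      reaction_ids = character()))
  }
  R <- basis$rays[keep, , drop = FALSE]
  R <- normalize_columns(R)
  cone_basis(R, basis$kind, reaction_ids = basis$reaction_ids[keep],
             constraints_applied = c(basis$constraints_applied,
                                     paste0("filter_changed>=", threshold)))
}

#' Project cone bases into two dimensions
#'
#' Joint PCA over all supplied bases (so all conditions share axes),
#' followed by per-basis k-means of the reduced rays (fixed seed, 10
#' restarts) and the convex hull of all reduced points — the shadow the
#' cone casts in the plane. The relative projection error is the fraction
#' of variance not explained by the first two components.
#'
#' @param bases a [cone_basis()] or list of them (e.g. one per condition).
#' @param k_clusters clusters per basis; clamped to the ray count.
#' @param seed k-means seed.
#' @param n_loadings how many top-loading reactions to report per axis.
#' @return list of class `cone_projection` with `coordinates` (data.frame:
#'   basis label + 2 PCs), `cluster_centers`, `hull_vertices` (row indices
#'   into `coordinates`), `relative_error`, `loadings`.
#' @export
project_cone <- function(bases, k_clusters = 5, seed = 42, n_loadings = 3) {
  if (inherits(bases, "cone_basis")) bases <- list(bases)
  if (is.null(names(bases)))
    names(bases) <- paste0("basis", seq_along(bases))
  X <- t(do.call(cbind, lapply(bases, `[[`, "rays")))
  if (nrow(X) < 3) stop("need at least 3 rays in total for a projection")
  labels <- rep(names(bases), vapply(bases, function(b) ncol(b$rays),
                                     integer(1)))
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  npc <- min(2, ncol(pca$x))
  coords <- matrix(0, nrow(X), 2)
  coords[, seq_len(npc)] <- pca$x[, seq_len(npc)]
  vars <- pca$sdev^2
  relative_error <- 1 - sum(vars[seq_len(npc)]) / sum(vars)
  centers <- list()
  for (b in names(bases)) {
    pts <- coords[labels == b, , drop = FALSE]
    distinct <- unique(round(pts, 9))
    if (k_clusters >= nrow(distinct)) {
      if (k_clusters > nrow(distinct))
        warning("k_clusters clamped to distinct ray count (",
                nrow(distinct), ") for basis ", b)
      centers[[b]] <- distinct
    } else {
      km <- with_seed(seed, stats::kmeans(pts, centers = k_clusters,
                                          nstart = 10))
      centers[[b]] <- km$centers
    }
  }
  hull <- grDevices::chull(coords)
  ids <- unlist(lapply(bases, function(b) b$reaction_ids), use.names = FALSE)
  loadings <- lapply(seq_len(npc), function(j) {
    rot <- pca$rotation[, j]
    bases[[1]]$reaction_ids[order(-abs(rot))][seq_len(
      min(n_loadings, length(rot)))]
  })
  structure(list(
    coordinates = data.frame(basis = labels, pc1 = coords[, 1],
                             pc2 = coords[, 2]),
    cluster_centers = centers, hull_vertices = hull,
    relative_error = relative_error, loadings = loadings),
    class = "cone_projection")
}

#' Write a cone basis as wide CSV (reaction x ray)
#' @param basis a [cone_basis()].
#' @param path output file.
#' @export
write_cone_basis <- function(basis, path) {
  df <- as.data.frame(basis$rays)
  names(df) <- paste0("ray", seq_len(ncol(df)))
  utils::write.csv(cbind(reaction = basis$reaction_ids, df), path,
                   row.names = FALSE)
  invisible(path)
}
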