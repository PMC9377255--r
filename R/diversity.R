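#' Shannon diversity index
#'
#' \eqn{H = -\sum_i p_i \log_b p_i} over the non-zero relative abundances,
#' after internal renormalization. Base 2 by default (bits), matching the
#' convention of the common amplicon-analysis toolkits.
#'
#' @param props non-negative abundances (need not sum to 1).
#' @param base logarithm base, default 2.
#' @return the diversity value.
#' @export
shannon_index <- function(props, base = 2) {
  if (any(props < 0)) stop("negative abundance")
  s <- sum(props)
  if (s <= 0) stop("abundances sum to zero")
  p <- props[props > 0] / s
  -sum(p * log(p, base = base))
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' \eqn{BC(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}, in `[0, 1]`:
#' 0 for identical vectors, 1 for disjoint supports.
#'
#' @param x,y non-negative numeric vectors of equal length.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (any(x < 0) || any(y < 0)) stop("negative abundance")
  denom <- sum(x + y)
  if (denom == 0) stop("both vectors all-zero")
  sum(abs(x - y)) / denom
}

#' Bray-Curtis distance matrix over samples
#'
#' @param mat abundance matrix, samples in columns.
#' @return symmetric distance matrix with zero diagonal.
#' @export
bray_curtis_matrix <- function(mat) {
  n <- ncol(mat)
  d <- matrix(0, n, n, dimnames = list(colnames(mat), colnames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- bray_curtis(mat[, i], mat[, j])
    }
  }
  d
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers the squared distance matrix to the Gram matrix
#' \eqn{-\frac{1}{2} J D^2 J} and eigendecomposes it. Coordinates are
#' returned for axes with positive eigenvalues, ordered by eigenvalue;
#' negative eigenvalues are reported but contribute no coordinates. Sign
#' convention: the first non-zero loading of each axis is positive. An
#' unconstrained distance-based ordination (e.g. `capscale` with no
#' constraints) reduces to this analysis.
#'
#' @param dist square symmetric distance matrix with zero diagonal.
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all,
#'   including negative), `prop_explained` (per positive axis, relative to
#'   the sum of positive eigenvalues).
#' @export
pcoa <- function(dist) {
  dist <- as.matrix(dist)
  if (nrow(dist) != ncol(dist)) stop("distance matrix not square")
  if (max(abs(dist - t(dist))) > 1e-8) stop("distance matrix not symmetric")
  if (any(abs(diag(dist)) > 1e-12)) stop("distance matrix diagonal not zero")
  n <- nrow(dist)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (dist^2) %*% J
  G <- (G + t(G)) / 2
  eig <- eigen(G, symmetric = TRUE)
  tol <- 1e-9 * max(1, abs(eig$values[1]))
  pos <- which(eig$values > tol)
  coords <- matrix(0, n, length(pos), dimnames = list(rownames(dist), NULL))
  if (length(pos) > 0) colnames(coords) <- paste0("PCo", seq_along(pos))
  for (a in seq_along(pos)) {
    v <- eig$vectors[, pos[a]] * sqrt(eig$values[pos[a]])
    nz <- which(abs(v) > tol)
    if (length(nz) > 0 && v[nz[1]] < 0) v <- -v
    coords[, a] <- v
  }
  prop <- if (length(pos) > 0) eig$values[pos] / sum(eig$values[pos]) else numeric(0)
  list(coordinates = coords, eigenvalues = eig$values, prop_explained = prop)
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Pseudo-F from among/within sums of squared distances: with total
#' \eqn{SS_T = \frac{1}{n}\sum_{i<j} d_{ij}^2} and within-group
#' \eqn{SS_W = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2},
#' \eqn{F = \frac{(SS_T - SS_W)/(a-1)}{SS_W/(n-a)}}. The p-value uses the
#' add-one convention \eqn{p = (1 + \#\{F^* \ge F\}) / (1 + n_{perm})} over
#' seeded label permutations, so p is never exactly 0.
#'
#' @param dist square symmetric distance matrix.
#' @param groups group labels, length `nrow(dist)`; at least 2 groups.
#' @param n_perm number of permutations, at least 99 (default 999).
#' @param seed integer seed for the permutation stream.
#' @return list with `F`, `p`, `n_perm`, `df_among`, `df_within`.
#' @export
permanova <- function(dist, groups, n_perm = 999, seed = 1) {
  dist <- as.matrix(dist)
  groups <- as.character(groups)
  n <- nrow(dist)
  stopifnot(length(groups) == n, n_perm >= 99)
  if (length(unique(groups)) < 2) stop("need at least 2 groups")
  d2 <- dist^2
  a <- length(unique(groups))
  pseudo_f <- function(g) {
    ss_t <- sum(d2[upper.tri(d2)]) / n
    ss_w <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      if (length(idx) > 1) {
        sub <- d2[idx, idx]
        ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
      }
    }
    ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
  }
  f_obs <- pseudo_f(groups)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      pseudo_f(groups[sample.int(n)]) >= f_obs
    }, logical(1)))
  })
  list(F = f_obs, p = (1 + exceed) / (1 + n_perm), n_perm = n_perm,
       df_among = a - 1, df_within = n - a)
}
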