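# Gaussian-copula information-theoretic connectivity and weighted graph
# metrics.
#
# All information quantities are in nats. The Gaussian-copula estimator
# rank-normalises each ROI's margin to standard-normal scores, after which
# mutual information reduces to the Gaussian closed form -0.5 ln(1 - rho^2).

#' Copula (rank-normal) transform
#'
#' Per row: ranks mapped through the standard-normal quantile function,
#' Phi^-1((r - 0.5) / n). Output margins are standard normal up to the rank
#' discretisation, and invariant to monotone transforms of the input.
#'
#' @param series Numeric matrix, ROIs x samples; each row needs >= 16
#'   distinct values.
#' @return Matrix of normal scores, same shape; heavy ties (> 50% duplicated
#'   samples in a row) set attribute `ties_flagged`.
#' @export
copula_transform <- function(series) {
  series <- as.matrix(series)
  n <- ncol(series)
  distinct <- apply(series, 1, function(v) length(unique(v)))
  if (any(distinct < 16)) {
    stop("each row needs at least 16 distinct values")
  }
  heavy <- distinct < n / 2
  z <- t(apply(series, 1, function(v) {
    stats::qnorm((rank(v, ties.method = "average") - 0.5) / n)
  }))
  dimnames(z) <- dimnames(series)
  if (any(heavy)) attr(z, "ties_flagged") <- unname(which(heavy))
  z
}

mi_from_rho <- function(rho, cap = -0.5 * log(1e-12)) {
  mi <- -0.5 * log(pmax(1 - rho^2, 1e-12))
  pmin(mi, cap)
}

#' Gaussian-copula mutual information matrix
#'
#' Pairwise MI = -0.5 ln(1 - rho_ij^2) on the normal scores, nats. Perfectly
#' correlated pairs are capped at -0.5 ln(1e-12) and flagged.
#'
#' @param z Normal-scores matrix from [copula_transform()].
#' @return Symmetric non-negative matrix, zero diagonal; attribute
#'   `capped = TRUE` when the cap was applied.
#' @export
mi_matrix <- function(z) {
  rho <- stats::cor(t(z))
  capped <- any(abs(rho[upper.tri(rho)]) >= 1 - 1e-12)
  w <- mi_from_rho(rho)
  diag(w) <- 0
  if (capped) attr(w, "capped") <- TRUE
  w
}

# Schafer-Strimmer shrinkage of a correlation matrix towards the identity.
shrink_cor <- function(z) {
  n <- ncol(z)
  zc <- t(scale(t(z)))
  r <- stats::cor(t(z))
  p <- nrow(z)
  # var of r_ij estimated from the cross-product terms
  num <- 0
  den <- 0
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      w_ij <- zc[i, ] * zc[j, ]
      num <- num + n / (n - 1)^3 * sum((w_ij - mean(w_ij))^2)
      den <- den + r[i, j]^2
    }
  }
  lambda <- if (den > 0) min(max(num / den, 0), 1) else 1
  list(r = (1 - lambda) * r + lambda * diag(p), lambda = lambda)
}

#' Gaussian-copula conditional mutual information matrix
#'
#' CMI of each ROI pair conditioned on all remaining ROIs (full
#' partialisation), via partial correlations from the inverse of the
#' shrinkage-regularised correlation matrix:
#' CMI_ij = -0.5 ln(1 - rho^2_(ij.rest)). For two ROIs the conditioning set
#' is empty and CMI equals MI exactly.
#'
#' @param z Normal-scores matrix (samples > 5 x ROIs required).
#' @return Symmetric non-negative matrix, zero diagonal; attribute `lambda`
#'   carries the shrinkage intensity.
#' @export
cmi_matrix <- function(z) {
  p <- nrow(z)
  if (ncol(z) <= 5 * p) stop("need more than 5 samples per ROI")
  if (p == 2) return(mi_matrix(z))
  sh <- shrink_cor(z)
  prec <- tryCatch(solve(sh$r), error = function(e)
    stop("singular correlation matrix even after shrinkage"))
  d <- sqrt(diag(prec))
  pcor <- -prec / tcrossprod(d)
  diag(pcor) <- 0
  w <- mi_from_rho(pcor)
  diag(w) <- 0
  dimnames(w) <- dimnames(sh$r)
  attr(w, "lambda") <- sh$lambda
  w
}

# Gaussian entropy (nats) from a correlation (sub)matrix.
gauss_entropy <- function(r) {
  d <- nrow(r)
  0.5 * (d * log(2 * pi * exp(1)) + determinant(r, logarithm = TRUE)$modulus[1])
}

# O-information of the variables indexed by `idx` under correlation matrix r.
o_info_from_cor <- function(r, idx = seq_len(nrow(r))) {
  k <- length(idx)
  rs <- r[idx, idx, drop = FALSE]
  h_all <- gauss_entropy(rs)
  h_terms <- vapply(seq_len(k), function(i) {
    gauss_entropy(rs[i, i, drop = FALSE]) -
      gauss_entropy(rs[-i, -i, drop = FALSE])
  }, numeric(1))
  (k - 2) * h_all + sum(h_terms)
}

#' Gaussian O-information
#'
#' Omega = (k - 2) H(X) + sum_i (H(X_i) - H(X_-i)), with entropies from
#' log-determinants of correlation submatrices of the normal scores. Positive
#' values indicate redundancy-dominated systems, negative synergy-dominated.
#' The per-edge matrix averages Omega over all triplets containing each pair,
#' enabling graph analysis on an O-information matrix.
#'
#' @param z Normal-scores matrix.
#' @param subset ROI indices (>= 3) over which the system-wide Omega is
#'   computed; defaults to all.
#' @param edge_matrix Also compute the triplet-averaged per-edge matrix.
#' @return List: `omega` (system scalar, nats) and `edges` (matrix or NULL).
#' @export
o_information <- function(z, subset = seq_len(nrow(z)), edge_matrix = FALSE) {
  if (length(subset) < 3) stop("spec error: need at least 3 ROIs")
  r <- stats::cor(t(z))
  omega <- o_info_from_cor(r, subset)
  edges <- NULL
  if (edge_matrix) {
    p <- nrow(z)
    edges <- matrix(0, p, p, dimnames = dimnames(r))
    counts <- matrix(0, p, p)
    trips <- utils::combn(subset, 3)
    for (t_i in seq_len(ncol(trips))) {
      tri <- trips[, t_i]
      om <- o_info_from_cor(r, tri)
      for (pair in utils::combn(tri, 2, simplify = FALSE)) {
        edges[pair[1], pair[2]] <- edges[pair[1], pair[2]] + om
        counts[pair[1], pair[2]] <- counts[pair[1], pair[2]] + 1
      }
    }
    edges <- edges + t(edges)
    counts <- counts + t(counts)
    edges[counts > 0] <- edges[counts > 0] / counts[counts > 0]
  }
  list(omega = omega, edges = edges)
}

#' Connectivity graphs for one recording
#'
#' Copula-transforms the ROI series and assembles the MI, CMI and
#' (triplet-averaged) O-information weight matrices. Negative O-information
#' edge weights are clipped to zero before graph analysis and flagged.
#'
#' @param rec A standardised [recording()] with >= 3 ROI rows.
#' @return A `connectivity_graph`: `labels`, `w_mi`, `w_cmi`, `w_oinfo`,
#'   `omega` (system O-information), `oinfo_clipped`.
#' @export
connectivity_graph <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  z <- copula_transform(rec$data)
  w_mi <- mi_matrix(z)
  w_cmi <- cmi_matrix(z)
  oi <- o_information(z, edge_matrix = TRUE)
  clipped <- any(oi$edges < 0)
  w_oinfo <- pmax(oi$edges, 0)
  structure(list(labels = rec$labels, w_mi = w_mi, w_cmi = w_cmi,
                 w_oinfo = w_oinfo, omega = oi$omega,
                 oinfo_clipped = clipped),
            class = "connectivity_graph")
}

#' Weighted graph metrics
#'
#' Weights are rescaled to \[0, 1\] by the maximum. Global efficiency is the
#' mean over node pairs of inverse shortest-path length with edge lengths
#' 1/weight (Dijkstra); transitivity is the weighted geometric-mean-triangle
#' form; density the mean off-diagonal rescaled weight. Small-worldness
#' sigma = (C/C_rand) / (L/L_rand) is computed on the graph binarised at
#' `sw_density` proportional density against `n_null` degree-preserving
#' rewired null graphs (seeded).
#'
#' @param w Symmetric non-negative weight matrix, zero diagonal.
#' @param sw_density Proportional density for binarisation.
#' @param n_null Number of rewired null graphs.
#' @param seed Seed for the null ensemble.
#' @return A `graph_metrics` list: `global_efficiency`, `transitivity`,
#'   `density`, `small_worldness`.
#' @export
graph_metrics <- function(w, sw_density = 0.3, n_null = 10, seed = 1) {
  w <- as.matrix(w)
  if (any(w < 0)) stop("weights must be non-negative")
  if (max(w) == 0) stop("degenerate error: all-zero weight matrix")
  if (max(abs(w - t(w))) > 1e-10) stop("weight matrix must be symmetric")
  p <- nrow(w)
  ws <- (w + t(w)) / 2          # remove floating-point asymmetry
  ws <- ws / max(ws)
  diag(ws) <- 0
  g <- igraph::graph_from_adjacency_matrix(ws, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv_d <- 1 / d[upper.tri(d)]
  inv_d[!is.finite(inv_d)] <- 0
  geff <- mean(inv_d)
  # geometric-mean triangle transitivity
  w3 <- ws^(1 / 3)
  tri <- diag(w3 %*% w3 %*% w3)
  k <- rowSums(ws > 0)
  denom <- sum(k * (k - 1))
  trans <- if (denom > 0) sum(tri) / denom else NA_real_
  dens <- mean(ws[row(ws) != col(ws)])
  # small-worldness on the proportionally thresholded binary graph
  uv <- ws[upper.tri(ws)]
  n_keep <- max(1, round(sw_density * length(uv)))
  thr <- sort(uv, decreasing = TRUE)[n_keep]
  if (thr <= 0) thr <- min(uv[uv > 0])   # never admit absent edges
  a <- (ws >= thr) & upper.tri(ws)
  a <- a | t(a)
  gb <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  cc <- igraph::transitivity(gb, type = "global")
  ll <- igraph::mean_distance(gb)
  sw <- with_seed(seed, {
    cr <- lr <- numeric(n_null)
    for (i in seq_len(n_null)) {
      gn <- igraph::rewire(gb, igraph::keeping_degseq(
        niter = max(10 * igraph::ecount(gb), 100)))
      cr[i] <- igraph::transitivity(gn, type = "global")
      lr[i] <- igraph::mean_distance(gn)
    }
    cbar <- mean(cr, na.rm = TRUE)
    lbar <- mean(lr, na.rm = TRUE)
    if (!is.finite(cbar) || cbar == 0 || !is.finite(ll) || ll == 0 ||
        !is.finite(cc)) {
      NA_real_
    } else {
      (cc / cbar) / (ll / lbar)
    }
  })
  structure(list(global_efficiency = geff, transitivity = trans,
                 density = dens, small_worldness = sw),
            class = "graph_metrics")
}
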