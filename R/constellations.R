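## Progression graph, self-tuning spectral clustering into constellations,
## hub identification, Kamada-Kawai layout, and ARI-based stability.

#' Build the thresholded progression graph
#'
#' Directed edges are the pairs classed `increasing` with psi above the
#' effect threshold (weight = psi); unordered pairs with both directions
#' present are flagged bi-directional. Diseases with no qualifying edge are
#' listed separately as isolated.
#'
#' @param em An `effect_matrix`.
#' @param min_effect Threshold, default 0.01.
#' @param chapters Chapter map for node annotation.
#' @return A `progress_graph` list: `graph` (directed weighted igraph),
#'   `isolated` (codes), `edges` (data.frame from, to, weight, bi).
#' @export
build_progress_graph <- function(em, min_effect = 0.01, chapters = chapter_map()) {
  sel <- em$class == "increasing" & !is.na(em$psi) & em$psi > min_effect
  ed <- em[sel, c("a", "b", "psi"), drop = FALSE]
  names(ed) <- c("from", "to", "weight")
  diseases <- sort(unique(c(em$a, em$b)))
  key <- paste(ed$from, ed$to)
  rev_key <- paste(ed$to, ed$from)
  ed$bi <- rev_key %in% key
  g <- igraph::graph_from_data_frame(ed, directed = TRUE,
                                     vertices = data.frame(name = diseases))
  igraph::V(g)$chapter <- map_chapter(diseases, chapters)
  deg <- igraph::degree(g, mode = "all")
  isolated <- names(deg)[deg == 0]
  g2 <- igraph::delete_vertices(g, isolated)
  structure(list(graph = g2, isolated = isolated, edges = ed,
                 min_effect = min_effect),
            class = "progress_graph")
}

## symmetric weight matrix (max of the two directions) for a progress graph
symmetric_weights <- function(pg) {
  g <- pg$graph
  A <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  pmax(A, t(A))
}

## locally scaled affinity from shortest-path dissimilarities
local_affinity <- function(pg, K_local = 7) {
  W <- symmetric_weights(pg)
  n <- nrow(W)
  gu <- igraph::graph_from_adjacency_matrix(W, mode = "max", weighted = TRUE)
  dmat <- igraph::distances(gu, weights = 1 / igraph::E(gu)$weight)
  sigma <- vapply(seq_len(n), function(i) {
    dd <- sort(dmat[i, -i][is.finite(dmat[i, -i])])
    if (length(dd) == 0L) return(1)
    dd[min(K_local, length(dd))]
  }, numeric(1))
  sigma[sigma <= 0] <- min(sigma[sigma > 0], 1)
  aff <- exp(-dmat^2 / tcrossprod(sigma))
  aff[!is.finite(dmat)] <- 0   # across components
  diag(aff) <- 0
  dimnames(aff) <- dimnames(W)
  list(affinity = aff, dissimilarity = dmat, sigma = sigma)
}

## spectral embedding of an affinity matrix: top-k eigenvectors of the
## normalized affinity D^{-1/2} A D^{-1/2}, rows normalized to unit length
spectral_embedding <- function(aff, kmax) {
  d <- rowSums(aff)
  d[d <= 0] <- 1e-12
  s <- 1 / sqrt(d)
  L <- aff * tcrossprod(s)
  e <- eigen(L, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors[, seq_len(min(kmax, ncol(e$vectors))), drop = FALSE])
}

row_normalize <- function(X) {
  nr <- sqrt(rowSums(X^2))
  nr[nr == 0] <- 1
  X / nr
}

## eigengap choice of k: largest gap lambda_k - lambda_{k+1} within k_range
eigengap_k <- function(values, k_range) {
  kmax <- min(max(k_range), length(values) - 1L)
  ks <- k_range[k_range <= kmax]
  if (length(ks) == 0L) return(1L)
  gaps <- values[ks] - values[ks + 1L]
  ks[which.max(gaps)]
}

#' Self-tuning spectral clustering of the progression graph
#'
#' Node dissimilarity is the shortest-path length with edge length 1/weight
#' on the symmetrized graph (weights = max of the two directions). The
#' affinity uses local scaling, `a_ij = exp(-d_ij^2 / (sigma_i sigma_j))`
#' with `sigma_i` the distance to the `K_local`-th nearest neighbour. Nodes
#' are embedded with the normalized-affinity spectral decomposition; k is
#' selected by the largest eigengap within `k_range`; k-means with `n_init`
#' restarts clusters the row-normalized embedding. Connected components are
#' clustered independently (flagged when more than one).
#'
#' @param pg A `progress_graph`.
#' @param K_local Local-scaling neighbour, default 7.
#' @param k_range Candidate cluster counts per component, default 1:10.
#' @param n_init k-means restarts, default 20.
#' @param seed Integer seed (k-means initialization).
#' @return A `constellation_set`: `membership` (named integer vector over
#'   non-isolated nodes), `k`, `components` (per-component detail incl.
#'   embedding, for stability reuse), `mean_within`, `mean_between` edge
#'   weights.
#' @export
self_tuning_cluster <- function(pg, K_local = 7, k_range = 1:10, n_init = 20, seed = 1) {
  g <- pg$graph
  n <- igraph::vcount(g)
  if (n < 2L) stop("need at least 2 non-isolated nodes")
  la <- local_affinity(pg, K_local = K_local)
  comp <- igraph::components(igraph::as_undirected(g, mode = "collapse"))
  membership <- setNames(integer(n), igraph::V(g)$name)
  comps <- list()
  next_id <- 0L
  set.seed(seed)
  for (ci in seq_len(comp$no)) {
    nodes <- names(comp$membership)[comp$membership == ci]
    idx <- match(nodes, rownames(la$affinity))
    if (length(nodes) == 1L) {
      membership[nodes] <- next_id + 1L
      next_id <- next_id + 1L
      comps[[ci]] <- list(nodes = nodes, k = 1L, embedding = NULL)
      next
    }
    aff <- la$affinity[idx, idx, drop = FALSE]
    se <- spectral_embedding(aff, kmax = min(max(k_range) + 1L, length(nodes)))
    ks <- k_range[k_range <= length(nodes) - 1L]
    if (length(ks) == 0L) ks <- 1L
    k <- eigengap_k(se$values, ks)
    if (k == 1L) {
      cl <- rep(1L, length(nodes))
      X <- NULL
    } else {
      X <- row_normalize(se$vectors[, seq_len(k), drop = FALSE])
      cl <- kmeans(X, centers = k, nstart = n_init, iter.max = 100)$cluster
    }
    membership[nodes] <- next_id + cl
    next_id <- next_id + k
    comps[[ci]] <- list(nodes = nodes, k = k, embedding = X,
                        eigenvalues = se$values, affinity = aff)
  }
  W <- symmetric_weights(pg)
  same <- outer(membership, membership, "==")
  ut <- upper.tri(W) & W > 0
  mean_within <- if (any(ut & same)) mean(W[ut & same]) else NA_real_
  mean_between <- if (any(ut & !same)) mean(W[ut & !same]) else NA_real_
  structure(list(membership = membership, k = next_id, components = comps,
                 mean_within = mean_within, mean_between = mean_between,
                 multiple_components = comp$no > 1L,
                 K_local = K_local, k_range = k_range, n_init = n_init, seed = seed),
            class = "constellation_set")
}

#' Identify the hub disease of each constellation
#'
#' The hub maximizes within-constellation weighted strength (sum of in- and
#' out-edge weights to members of the same constellation) — the node with the
#' best combination of link quality (weights) and quantity. Ties are broken
#' by total degree, then code order. A singleton constellation's sole node is
#' its hub.
#'
#' @param pg A `progress_graph`.
#' @param cs A `constellation_set` (or any named membership vector).
#' @param chapters Chapter map for annotation.
#' @return data.frame `(constellation, hub, chapter, strength, size)`.
#' @export
identify_hubs <- function(pg, cs, chapters = chapter_map()) {
  mem <- if (inherits(cs, "constellation_set")) cs$membership else cs
  g <- pg$graph
  el <- igraph::as_data_frame(g, what = "edges")
  out <- lapply(sort(unique(mem)), function(ci) {
    members <- names(mem)[mem == ci]
    strength <- vapply(members, function(v) {
      sum(el$weight[(el$from == v & el$to %in% members) |
                    (el$to == v & el$from %in% members)])
    }, numeric(1))
    degree <- vapply(members, function(v) sum(el$from == v | el$to == v), numeric(1))
    o <- order(-strength, -degree, members)
    hub <- members[o[1]]
    data.frame(constellation = ci, hub = hub,
               chapter = map_chapter(hub, chapters),
               strength = strength[o[1]], size = length(members),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## Kamada-Kawai energy for coordinates P given ideal lengths l and springs k
kk_energy <- function(P, l, kmat) {
  dx <- outer(P[, 1], P[, 1], "-")
  dy <- outer(P[, 2], P[, 2], "-")
  dd <- sqrt(dx^2 + dy^2)
  ut <- upper.tri(dd)
  sum(kmat[ut] * (dd[ut] - l[ut])^2) / 2
}

#' Kamada-Kawai graph layout
#'
#' Minimizes the spring energy
#' `E = sum_{i<j} k_ij (||p_i - p_j|| - l_ij)^2 / 2`
#' with ideal lengths l_ij = shortest-path distance (edge length 1/weight)
#' and spring constants k_ij = 1/l_ij^2, by iterative node-wise 2x2 Newton
#' updates (the node with the largest gradient moves first), with step
#' halving so accepted steps never increase the energy. Deterministic:
#' nodes start on a circle in vertex order.
#'
#' @param pg A `progress_graph` (must be connected; lay out components
#'   separately otherwise, see [layout_components()]).
#' @param max_iter Maximum node updates, default 1000.
#' @param tol Gradient-norm convergence tolerance, default 1e-4.
#' @return List with `coords` (n x 2 matrix, row names = codes), `energy`,
#'   `initial_energy`, `converged`.
#' @export
kamada_kawai_layout <- function(pg, max_iter = 1000, tol = 1e-4) {
  W <- symmetric_weights(pg)
  gu <- igraph::graph_from_adjacency_matrix(W, mode = "max", weighted = TRUE)
  l <- igraph::distances(gu, weights = 1 / igraph::E(gu)$weight)
  if (any(!is.finite(l))) stop("graph is disconnected; use layout_components()")
  n <- nrow(l)
  kmat <- 1 / l^2
  diag(kmat) <- 0
  theta <- 2 * pi * (seq_len(n) - 1) / n
  r0 <- max(l) / 2
  P <- cbind(r0 * cos(theta), r0 * sin(theta))
  rownames(P) <- rownames(l)
  if (n == 1L) return(list(coords = P, energy = 0, initial_energy = 0, converged = TRUE))
  E0 <- kk_energy(P, l, kmat)
  E <- E0
  grad_norm <- function(i) {
    dx <- P[i, 1] - P[, 1]; dy <- P[i, 2] - P[, 2]
    dd <- sqrt(dx^2 + dy^2); dd[i] <- 1
    gx <- sum(kmat[i, ] * (dx - l[i, ] * dx / dd))
    gy <- sum(kmat[i, ] * (dy - l[i, ] * dy / dd))
    c(gx, gy)
  }
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    gn <- vapply(seq_len(n), function(i) sqrt(sum(grad_norm(i)^2)), numeric(1))
    i <- which.max(gn)
    if (gn[i] < tol) { converged <- TRUE; break }
    dx <- P[i, 1] - P[, 1]; dy <- P[i, 2] - P[, 2]
    dd <- sqrt(dx^2 + dy^2); dd[i] <- 1
    ki <- kmat[i, ]; li <- l[i, ]
    g <- grad_norm(i)
    ## 2x2 Hessian of E in p_i
    hxx <- sum(ki * (1 - li * dy^2 / dd^3))
    hyy <- sum(ki * (1 - li * dx^2 / dd^3))
    hxy <- sum(ki * li * dx * dy / dd^3)
    det <- hxx * hyy - hxy^2
    if (!is.finite(det) || abs(det) < 1e-12) {
      step <- -g * 1e-2
    } else {
      step <- -c(hyy * g[1] - hxy * g[2], -hxy * g[1] + hxx * g[2]) / det
    }
    ## backtracking: never accept an energy increase
    accepted <- FALSE
    for (h in 0:8) {
      cand <- P
      cand[i, ] <- P[i, ] + step / 2^h
      Ec <- kk_energy(cand, l, kmat)
      if (Ec <= E) { P <- cand; E <- Ec; accepted <- TRUE; break }
    }
    if (!accepted) { converged <- TRUE; break }  # local stationary point
  }
  list(coords = P, energy = E, initial_energy = E0, converged = converged)
}

#' Lay out a possibly disconnected progression graph
#'
#' Runs [kamada_kawai_layout()] on each connected component and arranges the
#' components on a grid.
#' @inheritParams kamada_kawai_layout
#' @return n x 2 coordinate matrix.
#' @export
layout_components <- function(pg, max_iter = 1000, tol = 1e-4) {
  g <- pg$graph
  comp <- igraph::components(igraph::as_undirected(g, mode = "collapse"))
  coords <- matrix(0, igraph::vcount(g), 2,
                   dimnames = list(igraph::V(g)$name, c("x", "y")))
  ncomp <- comp$no
  grid <- ceiling(sqrt(ncomp))
  for (ci in seq_len(ncomp)) {
    nodes <- names(comp$membership)[comp$membership == ci]
    sub <- igraph::induced_subgraph(g, nodes)
    spg <- structure(list(graph = sub, isolated = character(0)),
                     class = "progress_graph")
    if (length(nodes) == 1L) {
      cc <- matrix(0, 1, 2, dimnames = list(nodes, NULL))
    } else {
      cc <- kamada_kawai_layout(spg, max_iter = max_iter, tol = tol)$coords
      cc <- scale(cc, center = TRUE, scale = FALSE)
      span <- max(abs(cc), 1e-9)
      cc <- cc / span
    }
    off <- 2.5 * c((ci - 1) %% grid, (ci - 1) %/% grid)
    coords[nodes, ] <- sweep(cc, 2, off, "+")
  }
  coords
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement computed from the contingency
#' table: `ARI = (sum_ij C(n_ij,2) - E) / (M - E)` with
#' `E = sum_i C(a_i,2) * sum_j C(b_j,2) / C(n,2)` and
#' `M = (sum_i C(a_i,2) + sum_j C(b_j,2)) / 2`. 1 = identical partitions,
#' ~0 = independent.
#'
#' @param p1,p2 Partition label vectors over the same node set. If named,
#'   they are aligned by name (mismatched name sets raise an error).
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(p1, p2) {
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    if (!setequal(names(p1), names(p2))) stop("mismatched node sets")
    p2 <- p2[names(p1)]
  }
  if (length(p1) != length(p2)) stop("mismatched node sets")
  n <- length(p1)
  tab <- table(p1, p2)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  Eexp <- ai * bj / choose(n, 2)
  M <- (ai + bj) / 2
  if (M == Eexp) return(1)   # both partitions trivial (all-singletons or single block)
  (nij - Eexp) / (M - Eexp)
}

## Zelnik-Manor alignment cost of a spectral embedding under the best
## rotation, used for rotation-based k selection. Optimized over Givens
## angles with Nelder-Mead/BFGS (small k only).
rotation_cost <- function(X) {
  k <- ncol(X)
  if (k == 1L) return(1)
  n <- nrow(X)
  pairs <- t(utils::combn(k, 2))
  cost_of <- function(theta) {
    R <- diag(k)
    for (p in seq_len(nrow(pairs))) {
      i <- pairs[p, 1]; j <- pairs[p, 2]
      G <- diag(k)
      G[i, i] <- cos(theta[p]); G[j, j] <- cos(theta[p])
      G[i, j] <- -sin(theta[p]); G[j, i] <- sin(theta[p])
      R <- R %*% G
    }
    Z <- X %*% R
    Mx <- apply(Z^2, 1, max)
    Mx[Mx == 0] <- 1
    sum(Z^2 / Mx) / n
  }
  opt <- stats::optim(rep(0, nrow(pairs)), cost_of, method = "BFGS",
                      control = list(maxit = 200))
  opt$value
}

## rotation-based k selection (self-tuning spectral clustering comparator):
## pick the largest k whose best-rotation alignment cost is within eps of the
## minimum over the candidate range
rotation_select_k <- function(vectors, k_range, eps = 0.01) {
  ## k near n is degenerate: an n x n eigenbasis is orthogonal and can be
  ## rotated exactly onto the axes, so alignment cost is uninformative there
  kcap <- max(1L, nrow(vectors) - 2L)
  ks <- k_range[k_range >= 1 & k_range <= min(ncol(vectors), kcap)]
  if (length(ks) == 0L) return(1L)
  costs <- vapply(ks, function(k) {
    if (k == 1L) return(1)
    rotation_cost(vectors[, seq_len(k), drop = FALSE])
  }, numeric(1))
  best <- min(costs)
  max(ks[costs <= best + eps])
}

#' Clustering stability report
#'
#' Compares the reference constellation partition against:
#' (a) plain k-means on the same spectral embedding with `n_seeds` different
#' random initializations (one start each),
#' (b) self-tuning spectral clustering with rotation-based k selection, and
#' (c) a cross-method sensitivity set: Ward linkage on the shortest-path
#' dissimilarity and Louvain community detection on the affinity graph.
#' All comparisons are summarized by the adjusted Rand index.
#'
#' @param pg A `progress_graph`.
#' @param cs Optional reference `constellation_set` (computed if absent).
#' @param n_seeds Number of k-means reinitializations, default 100.
#' @param seed Integer master seed.
#' @param K_local,k_range Passed to the clustering machinery.
#' @return A `stability_report` list: `ari` (data.frame method, replicate,
#'   ari), `mean_ari`, `mean_ari_by_method`, `reference` membership.
#' @export
stability_report <- function(pg, cs = NULL, n_seeds = 100, seed = 1,
                             K_local = 7, k_range = 1:10) {
  if (is.null(cs)) cs <- self_tuning_cluster(pg, K_local = K_local,
                                             k_range = k_range, seed = seed)
  ref <- cs$membership
  la <- local_affinity(pg, K_local = K_local)
  rows <- list()
  ## (a) k-means with varied seeds on the same embedding, k fixed at reference
  set.seed(seed + 1L)
  for (s in seq_len(n_seeds)) {
    mem <- setNames(integer(length(ref)), names(ref))
    next_id <- 0L
    for (cp in cs$components) {
      if (is.null(cp$embedding) || cp$k == 1L) {
        mem[cp$nodes] <- next_id + 1L
        next_id <- next_id + max(1L, cp$k)
      } else {
        cl <- kmeans(cp$embedding, centers = cp$k, nstart = 1, iter.max = 100)$cluster
        mem[cp$nodes] <- next_id + cl
        next_id <- next_id + cp$k
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(method = "kmeans_seeds", replicate = s,
                                            ari = adjusted_rand_index(ref, mem))
  }
  ## (b) self-tuning spectral with rotation-based k
  mem_rot <- setNames(integer(length(ref)), names(ref))
  next_id <- 0L
  set.seed(seed + 2L)
  for (cp in cs$components) {
    if (length(cp$nodes) == 1L) {
      mem_rot[cp$nodes] <- next_id + 1L; next_id <- next_id + 1L; next
    }
    se <- spectral_embedding(cp$affinity, kmax = min(max(k_range), length(cp$nodes)))
    krot <- rotation_select_k(se$vectors, k_range)
    if (krot == 1L) {
      cl <- rep(1L, length(cp$nodes))
    } else {
      X <- row_normalize(se$vectors[, seq_len(krot), drop = FALSE])
      cl <- kmeans(X, centers = krot, nstart = 20, iter.max = 100)$cluster
    }
    mem_rot[cp$nodes] <- next_id + cl
    next_id <- next_id + krot
  }
  rows[[length(rows) + 1L]] <- data.frame(method = "self_tuning_spectral", replicate = 1L,
                                          ari = adjusted_rand_index(ref, mem_rot))
  ## (c) cross-method sensitivity: Ward on dissimilarity, Louvain on affinity
  dmat <- la$dissimilarity
  dmat[!is.finite(dmat)] <- 2 * max(dmat[is.finite(dmat)])
  hc <- hclust(as.dist(dmat), method = "ward.D2")
  mem_ward <- cutree(hc, k = max(ref))
  names(mem_ward) <- rownames(dmat)
  rows[[length(rows) + 1L]] <- data.frame(method = "ward", replicate = 1L,
                                          ari = adjusted_rand_index(ref, mem_ward))
  ga <- igraph::graph_from_adjacency_matrix(la$affinity, mode = "max",
                                            weighted = TRUE, diag = FALSE)
  set.seed(seed + 3L)
  lv <- igraph::cluster_louvain(ga)
  mem_lv <- setNames(igraph::membership(lv), igraph::V(ga)$name)
  rows[[length(rows) + 1L]] <- data.frame(method = "louvain", replicate = 1L,
                                          ari = adjusted_rand_index(ref, mem_lv))
  ari <- do.call(rbind, rows)
  by_method <- tapply(ari$ari, ari$method, mean)
  structure(list(ari = ari, mean_ari = mean(ari$ari),
                 mean_ari_by_method = by_method, reference = ref,
                 n_seeds = n_seeds, seed = seed),
            class = "stability_report")
}
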