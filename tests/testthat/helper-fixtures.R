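# Shared fixtures and independent oracles. Heavy simulated objects are
# memoised in a session-local environment so several test files can reuse
# them without recomputation.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, force(expr), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

# small confounded cohort with a planted graph (shared across files)
small_cohort <- function() {
  memo("small_cohort", {
    cfg <- sim_config(n = 4000, D = 6, seed = 101,
                      target_prevalence = seq(0.08, 0.25, length.out = 6))
    g <- make_planted_graph(6, density = 0.25, effect_range = c(0.5, 1.0),
                            negative_fraction = 0.2, seed = 5)
    ch <- simulate_cohort(cfg, g)
    list(cfg = cfg, gamma = g, cohort = ch)
  })
}

# hand-built effect matrix from a compact spec: data.frame(a, b, psi, se)
toy_effect_matrix <- function(df, diseases = sort(unique(c(df$a, df$b)))) {
  full <- enumerate_pairs(diseases)
  m <- merge(full, df, by = c("a", "b"), all.x = TRUE)
  m$psi[is.na(m$psi)] <- 0
  if (is.null(m$se)) m$se <- 0.001
  m$se[is.na(m$se)] <- 0.001
  m$ci_low <- m$psi - 1.96 * m$se
  m$ci_high <- m$psi + 1.96 * m$se
  m$p <- 2 * pnorm(-abs(m$psi / m$se))
  m$class <- ifelse(m$ci_low > 0, "increasing",
                    ifelse(m$ci_high < 0, "decreasing", "null"))
  if (!is.null(df$class)) {
    key <- paste(m$a, m$b)
    src <- paste(df$a, df$b)
    hit <- match(key, src)
    m$class[!is.na(hit) & !is.na(df$class[hit])] <-
      df$class[hit][!is.na(hit) & !is.na(df$class[hit])]
  }
  m$n <- 1000L
  m$clipped_frac <- 0
  m$skip_reason <- NA_character_
  m <- m[order(m$a, m$b), ]
  rownames(m) <- NULL
  structure(m, diseases = diseases, sex = "test", design = "ever-before",
            window = Inf, class = c("effect_matrix", "data.frame"))
}

# independent Lance-Williams recursion for Ward linkage (oracle for
# ward_tree): operates on squared Euclidean distances; heights returned on
# the distance scale (sqrt), matching hclust method "ward.D2".
lw_ward_heights <- function(X) {
  n <- nrow(X)
  d2 <- as.matrix(dist(X))^2
  active <- seq_len(n)
  sizes <- rep(1, n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bestv <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_len(ii - 1)) {
        i <- active[ii]; j <- active[jj]
        if (d2[i, j] < bestv) { bestv <- d2[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- sqrt(bestv)
    ni <- sizes[i]; nj <- sizes[j]
    for (k in active) {
      if (k == i || k == j) next
      nk <- sizes[k]
      d2new <- ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * d2[i, j]) /
        (ni + nj + nk)
      d2[i, k] <- d2[k, i] <- d2new
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  sort(heights)
}

# brute-force ARI by pair counting: agreements over all node pairs
pair_count_ari <- function(p1, p2) {
  n <- length(p1)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- p1[i] == p1[j]; b <- p2[i] == p2[j]
      if (a && b) s11 <- s11 + 1
      else if (!a && !b) s00 <- s00 + 1
      else if (a) s10 <- s10 + 1
      else s01 <- s01 + 1
    }
  }
  M <- choose(n, 2)
  expected <- (s11 + s10) * (s11 + s01) / M
  maxi <- ((s11 + s10) + (s11 + s01)) / 2
  if (maxi == expected) return(1)
  (s11 - expected) / (maxi - expected)
}

# planted block profile matrix for clustering tests
planted_blocks <- function(n_blocks = 3, per_block = 4, m = 20, signal = 5,
                           noise = 0.1, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(n_blocks * m, sd = signal), n_blocks, m)
  X <- centers[rep(seq_len(n_blocks), each = per_block), ] +
    matrix(rnorm(n_blocks * per_block * m, sd = noise), n_blocks * per_block, m)
  rownames(X) <- sprintf("n%02d", seq_len(nrow(X)))
  list(X = X, truth = rep(seq_len(n_blocks), each = per_block))
}

# planted block progression graph as an effect matrix: heavy within-block
# increasing effects, none between
planted_block_em <- function(n_blocks = 4, per_block = 10, within = 0.05,
                             between_frac = 0, seed = 1) {
  D <- n_blocks * per_block
  codes <- sim_disease_codes(D)
  block <- rep(seq_len(n_blocks), each = per_block)
  set.seed(seed)
  rows <- list()
  for (i in seq_len(D)) {
    for (j in seq_len(D)) {
      if (i == j) next
      same <- block[i] == block[j]
      link <- if (same) runif(1) < 0.6 else runif(1) < between_frac
      if (link) {
        rows[[length(rows) + 1L]] <- data.frame(
          a = codes[i], b = codes[j],
          psi = within * runif(1, 0.8, 1.2), se = 1e-4)
      }
    }
  }
  list(em = toy_effect_matrix(do.call(rbind, rows), diseases = codes),
       truth = setNames(block, codes), codes = codes)
}

# leaf labels of the k-th merge (both children must be leaves)
clade_labels <- function(hc, k) {
  m <- hc$merge[k, ]
  stopifnot(all(m < 0))
  hc$labels[-m]
}

# independent clade-signature extraction (test-local re-implementation)
clade_signatures_test <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", n - 1L)
  out <- character(n - 1L)
  for (k in seq_len(n - 1L)) {
    m <- hc$merge[k, ]
    l <- if (m[1] < 0) hc$labels[-m[1]] else sets[[m[1]]]
    r <- if (m[2] < 0) hc$labels[-m[2]] else sets[[m[2]]]
    sets[[k]] <- c(l, r)
    out[k] <- paste(sort(sets[[k]]), collapse = "|")
  }
  out
}
# all permutations of a vector (small n), as a list
combinat_perms <- function(x) {
  n <- length(x)
  if (n == 1) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in combinat_perms(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

# planted block progression graph with a within/between weight ratio: strong
# within-block increasing effects, weak between-block effects (ratio-fold
# smaller), all significant
planted_ratio_graph <- function(seed, n_blocks = 4, per_block = 10,
                                within = 0.05, ratio = 5, between_frac = 0.08) {
  D <- n_blocks * per_block
  codes <- sim_disease_codes(D)
  block <- rep(seq_len(n_blocks), each = per_block)
  set.seed(seed)
  rows <- list()
  for (i in seq_len(D)) for (j in seq_len(D)) if (i != j) {
    same <- block[i] == block[j]
    if (same && runif(1) < 0.5) {
      rows[[length(rows) + 1L]] <- data.frame(
        a = codes[i], b = codes[j], psi = within * runif(1, 0.8, 1.2), se = 1e-4)
    } else if (!same && runif(1) < between_frac) {
      rows[[length(rows) + 1L]] <- data.frame(
        a = codes[i], b = codes[j], psi = within / ratio * runif(1, 0.8, 1.2),
        se = 1e-4)
    }
  }
  list(em = toy_effect_matrix(do.call(rbind, rows), diseases = codes),
       truth = setNames(block, codes))
}
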