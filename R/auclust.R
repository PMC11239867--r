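## Ward clustering of effect profiles with multiscale-bootstrap AU
## (approximately unbiased) cluster support.

#' Ward hierarchical clustering of profile rows
#'
#' Ward linkage on Euclidean row distances (`stats::hclust` method
#' `"ward.D2"`, i.e. the Ward criterion on squared distances with heights on
#' the distance scale). Deterministic for a fixed row order.
#'
#' @param profiles Numeric matrix (rows = diseases), e.g. from
#'   [profile_matrix()].
#' @return An `hclust` tree with labels from the row names.
#' @export
ward_tree <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2L) stop("need at least 2 rows")
  if (!all(is.finite(profiles))) stop("non-finite values in profile matrix")
  if (is.null(rownames(profiles))) rownames(profiles) <- paste0("r", seq_len(nrow(profiles)))
  hclust(dist(profiles), method = "ward.D2")
}

## leaf sets (as sorted label signatures) for every internal edge of an hclust
clade_signatures <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    m <- hc$merge[k, ]
    left <- if (m[1] < 0) hc$labels[-m[1]] else sets[[m[1]]]
    right <- if (m[2] < 0) hc$labels[-m[2]] else sets[[m[2]]]
    sets[[k]] <- c(left, right)
  }
  vapply(sets, function(s) paste(sort(s), collapse = "|"), character(1))
}

#' Multiscale bootstrap of cluster support
#'
#' For each scale r, resamples `round(r * m)` of the m profile columns with
#' replacement, reclusters with [ward_tree()], and records per edge of the
#' reference tree the fraction of replicates whose tree contains that exact
#' leaf set (the bootstrap probability BP_r). BP at r = 1 is the ordinary
#' bootstrap probability.
#'
#' @param profiles Numeric matrix (rows clustered, columns resampled).
#' @param scales Scale grid; default `seq(0.5, 1.4, by = 0.1)`.
#' @param B Replicates per scale (>= 100 recommended).
#' @param seed Integer seed; the replicate stream is reproducible.
#' @return A `bp_table`: list with `bp` (edges x scales matrix), `scales`,
#'   `B`, `edges` (leaf-set signatures), and `tree` (the reference tree).
#' @export
multiscale_bootstrap <- function(profiles, scales = seq(0.5, 1.4, by = 0.1),
                                 B = 1000, seed = 1) {
  profiles <- as.matrix(profiles)
  stopifnot(all(scales > 0), B >= 1)
  hc <- ward_tree(profiles)
  ref_sigs <- clade_signatures(hc)
  m <- ncol(profiles)
  bp <- matrix(0, length(ref_sigs), length(scales),
               dimnames = list(NULL, paste0("r", scales)))
  set.seed(seed)
  for (j in seq_along(scales)) {
    mj <- max(1L, as.integer(round(scales[j] * m)))
    hits <- numeric(length(ref_sigs))
    for (b in seq_len(B)) {
      cols <- sample.int(m, mj, replace = TRUE)
      hcb <- ward_tree(profiles[, cols, drop = FALSE])
      hits <- hits + (ref_sigs %in% clade_signatures(hcb))
    }
    bp[, j] <- hits / B
  }
  structure(list(bp = bp, scales = scales, B = B, edges = ref_sigs, tree = hc),
            class = "bp_table")
}

#' Approximately unbiased p-value from multiscale bootstrap probabilities
#'
#' Fits the signed-distance/curvature model
#' `z_r = qnorm(1 - BP_r) = v * sqrt(r) + c / sqrt(r)`
#' by weighted least squares with weights `B * dnorm(z_r)^2 / (BP_r (1 - BP_r))`
#' and returns `AU = 1 - pnorm(v - c)`. Boundary BP values are clamped to
#' `[1/(2B), 1 - 1/(2B)]` before the probit transform; if every BP is exactly
#' 0 or exactly 1 the AU is set to that constant and the fit is skipped
#' (flagged).
#'
#' @param bp Numeric vector of bootstrap probabilities, one per scale.
#' @param scales Scale values r (> 0), same length as `bp`.
#' @param B Replicates per scale (scalar or vector).
#' @return List `(au, v, c, fit_skipped)`.
#' @export
au_pvalue <- function(bp, scales, B = 1000) {
  stopifnot(length(bp) == length(scales), all(scales > 0))
  if (length(B) == 1L) B <- rep(B, length(bp))
  if (all(bp %in% c(0, 1)) && length(unique(bp)) == 1L) {
    return(list(au = bp[1], v = NA_real_, c = NA_real_, fit_skipped = TRUE))
  }
  if (length(bp) < 2L) stop("need BP at >= 2 scales")
  bpc <- pmin(pmax(bp, 1 / (2 * B)), 1 - 1 / (2 * B))
  z <- qnorm(1 - bpc)
  X <- cbind(sqrt(scales), 1 / sqrt(scales))
  w <- B * dnorm(z)^2 / (bpc * (1 - bpc))
  fit <- stats::lm.wfit(X, z, w)
  v <- unname(fit$coefficients[1]); cc <- unname(fit$coefficients[2])
  list(au = 1 - pnorm(v - cc), v = v, c = cc, fit_skipped = FALSE)
}

#' AU support for every tree edge
#'
#' @param bpt A `bp_table` from [multiscale_bootstrap()].
#' @return data.frame with one row per edge: `edge` (leaf signature),
#'   `size`, `au`, `v`, `c`, `fit_skipped`, plus `bp_r*` columns.
#' @export
au_support <- function(bpt) {
  fits <- apply(bpt$bp, 1, function(row) au_pvalue(row, bpt$scales, bpt$B))
  out <- data.frame(edge = bpt$edges,
                    size = vapply(strsplit(bpt$edges, "\\|"), length, integer(1)),
                    au = vapply(fits, `[[`, numeric(1), "au"),
                    v = vapply(fits, `[[`, numeric(1), "v"),
                    c = vapply(fits, `[[`, numeric(1), "c"),
                    fit_skipped = vapply(fits, `[[`, logical(1), "fit_skipped"),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(bpt$bp))
}

#' Cut a supported dendrogram into clusters
#'
#' `mode = "fixed-k"` cuts the tree into k clusters (each cutree cluster is a
#' clade, so its AU is looked up directly; singletons take AU = 1 by
#' convention and are flagged). `mode = "au-threshold"` returns the maximal
#' (outermost, root excluded) clades with AU >= `parameter`; leaves not
#' covered become flagged singletons.
#'
#' @param bpt A `bp_table`.
#' @param mode `"fixed-k"` or `"au-threshold"`.
#' @param parameter k for fixed-k, the AU threshold otherwise. Default
#'   threshold 0.87.
#' @return List with `membership` (named integer vector), `clusters`
#'   (data.frame cluster, size, au, singleton), and `mean_au` over retained
#'   non-singleton clusters (1, flagged, if all are singletons).
#' @export
cut_support <- function(bpt, mode = c("au-threshold", "fixed-k"), parameter = 0.87) {
  mode <- match.arg(mode)
  hc <- bpt$tree
  labels <- hc$labels
  n <- length(labels)
  sup <- au_support(bpt)
  au_by_sig <- setNames(sup$au, sup$edge)
  if (mode == "fixed-k") {
    k <- as.integer(parameter)
    if (k > n) stop("k exceeds number of leaves")
    mem <- cutree(hc, k = k)
  } else {
    thr <- parameter
    sets <- strsplit(sup$edge, "\\|")
    sizes <- lengths(sets)
    ## root excluded; scan clades largest-first, keep if supported and not
    ## inside an already-retained clade
    ord <- order(-sizes)
    ord <- ord[sizes[ord] < n]
    taken <- character(0)
    kept <- list()
    for (i in ord) {
      if (sup$au[i] >= thr && !any(sets[[i]] %in% taken)) {
        kept[[length(kept) + 1L]] <- sets[[i]]
        taken <- c(taken, sets[[i]])
      }
    }
    mem <- setNames(rep(NA_integer_, n), labels)
    for (ci in seq_along(kept)) mem[kept[[ci]]] <- ci
    singles <- which(is.na(mem))
    mem[singles] <- length(kept) + seq_along(singles)
    mem <- mem[labels]
  }
  cl <- lapply(sort(unique(mem)), function(ci) {
    members <- names(mem)[mem == ci]
    sig <- paste(sort(members), collapse = "|")
    au <- if (length(members) == 1L) 1 else unname(au_by_sig[sig])
    if (length(members) > 1L && is.na(au)) au <- NA_real_  # non-clade (cannot occur via cutree)
    data.frame(cluster = ci, size = length(members), au = au,
               singleton = length(members) == 1L, members = sig,
               stringsAsFactors = FALSE)
  })
  clusters <- do.call(rbind, cl)
  nonsing <- clusters$au[!clusters$singleton & !is.na(clusters$au)]
  mean_au <- if (length(nonsing)) mean(nonsing) else 1
  list(membership = mem, clusters = clusters, mean_au = mean_au,
       all_singletons = all(clusters$singleton))
}

#' Export a dendrogram in Newick format
#'
#' @param hc An `hclust` tree.
#' @param path Output file.
#' @export
write_newick <- function(hc, path) {
  n <- length(hc$labels)
  node_str <- character(n - 1L)
  node_h <- hc$height
  str_of <- function(idx, parent_h) {
    if (idx < 0) {
      sprintf("%s:%.6g", hc$labels[-idx], parent_h)
    } else {
      sprintf("(%s,%s):%.6g",
              str_of(hc$merge[idx, 1], node_h[idx]),
              str_of(hc$merge[idx, 2], node_h[idx]),
              parent_h - node_h[idx])
    }
  }
  root <- n - 1L
  nwk <- sprintf("(%s,%s);",
                 str_of(hc$merge[root, 1], node_h[root]),
                 str_of(hc$merge[root, 2], node_h[root]))
  writeLines(nwk, path)
  invisible(path)
}
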