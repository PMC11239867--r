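## Bi-/uni-directional progression classification, chapter-level flow
## aggregation, and permutation testing of chapter crossing enrichment.

#' Classify unordered pairs as bi- / uni-directional progression
#'
#' A direction a -> b qualifies when its cell is classed `increasing` with
#' psi above the strong-effect threshold (0.01 by default). An unordered pair is `bi` when both directions qualify, `uni`
#' when exactly one does, `none` otherwise.
#'
#' @param em An `effect_matrix`.
#' @param min_effect Effect-size threshold, default 0.01.
#' @param chapters Chapter map used to annotate endpoints.
#' @return A `flow_edges` data.frame: `a, b, direction` (`"bi"`, `"uni"`,
#'   `"none"`; for `uni`, `a` is the source), `psi_ab, psi_ba, chapter_a,
#'   chapter_b, self_link`.
#' @export
classify_directionality <- function(em, min_effect = 0.01, chapters = chapter_map()) {
  diseases <- sort(unique(c(em$a, em$b)))
  D <- length(diseases)
  qual <- matrix(FALSE, D, D, dimnames = list(diseases, diseases))
  ok <- em$class == "increasing" & !is.na(em$psi) & em$psi > min_effect
  qual[cbind(match(em$a, diseases), match(em$b, diseases))] <- ok
  psi <- matrix(NA_real_, D, D, dimnames = list(diseases, diseases))
  psi[cbind(match(em$a, diseases), match(em$b, diseases))] <- em$psi
  ch <- map_chapter(diseases, chapters)
  rows <- list()
  for (i in seq_len(D - 1L)) {
    for (j in (i + 1L):D) {
      ab <- qual[i, j]; ba <- qual[j, i]
      if (ab && ba) {
        dir <- "bi"; src <- i; dst <- j
      } else if (ab) {
        dir <- "uni"; src <- i; dst <- j
      } else if (ba) {
        dir <- "uni"; src <- j; dst <- i
      } else {
        dir <- "none"; src <- i; dst <- j
      }
      rows[[length(rows) + 1L]] <- data.frame(
        a = diseases[src], b = diseases[dst], direction = dir,
        psi_ab = psi[src, dst], psi_ba = psi[dst, src],
        chapter_a = ch[src], chapter_b = ch[dst],
        self_link = ch[src] == ch[dst], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  structure(out, min_effect = min_effect, class = c("flow_edges", "data.frame"))
}

#' Aggregate progression flows between ICD-10 chapters
#'
#' Uni-directional counts are directed (from-chapter to to-chapter);
#' bi-directional counts are unordered and each pair is counted once (stored
#' at the upper triangle including the self-link diagonal). Totals conserve:
#' the sum of each table equals the number of qualifying edges of that class.
#'
#' @param edges A `flow_edges` data.frame.
#' @param chapters Chapter map (defines the table dimensions/order).
#' @return List with matrices `uni`, `bi`, counts and `crossing` (fraction of
#'   qualifying edges crossing chapters, per class).
#' @export
aggregate_flows <- function(edges, chapters = chapter_map()) {
  labs <- chapters$chapter
  k <- length(labs)
  uni <- matrix(0L, k, k, dimnames = list(from = labs, to = labs))
  bi <- matrix(0L, k, k, dimnames = list(labs, labs))
  eu <- edges[edges$direction == "uni", , drop = FALSE]
  if (nrow(eu)) {
    iu <- cbind(match(eu$chapter_a, labs), match(eu$chapter_b, labs))
    if (anyNA(iu)) stop("unmapped chapter in edges")
    for (r in seq_len(nrow(iu))) uni[iu[r, 1], iu[r, 2]] <- uni[iu[r, 1], iu[r, 2]] + 1L
  }
  eb <- edges[edges$direction == "bi", , drop = FALSE]
  if (nrow(eb)) {
    ib <- cbind(match(eb$chapter_a, labs), match(eb$chapter_b, labs))
    if (anyNA(ib)) stop("unmapped chapter in edges")
    ib <- t(apply(ib, 1, sort))
    for (r in seq_len(nrow(ib))) bi[ib[r, 1], ib[r, 2]] <- bi[ib[r, 1], ib[r, 2]] + 1L
  }
  crossing <- c(uni = if (sum(uni)) 1 - sum(diag(uni)) / sum(uni) else NA_real_,
                bi = if (sum(bi)) 1 - sum(diag(bi)) / sum(bi) else NA_real_)
  list(uni = uni, bi = bi, n_uni = sum(uni), n_bi = sum(bi), crossing = crossing)
}

## observed chapter-pair counts given a disease -> chapter assignment
flow_counts_for_assignment <- function(src_idx, dst_idx, ch_of, k, directed) {
  ca <- ch_of[src_idx]; cb <- ch_of[dst_idx]
  if (!directed) {
    lo <- pmin(ca, cb); hi <- pmax(ca, cb)
    ca <- lo; cb <- hi
  }
  counts <- integer(k * k)
  tab <- tabulate((ca - 1L) * k + cb, nbins = k * k)
  tab
}

#' Permutation test of chapter-level flow enrichment
#'
#' Null model: random reassignment of diseases to chapters preserving chapter
#' sizes, with the edge structure held fixed (degree structure preserved).
#' For each chapter pair, the one-sided enrichment p-value is
#' `(1 + #{null count >= observed}) / (B + 1)`, so the minimum attainable
#' p is `1/(B+1)` (e.g. 1/10,001 ~ 0.0001 at the default B).
#'
#' @param edges A `flow_edges` data.frame.
#' @param direction `"uni"` (directed chapter pairs) or `"bi"` (unordered).
#' @param B Number of permutations, default 10,000.
#' @param seed Integer seed.
#' @param chapters Chapter map.
#' @param alternative `"greater"` (enrichment, default) or `"less"`
#'   (depletion).
#' @return data.frame of chapter pairs with nonzero observed or null mass:
#'   `from, to, observed, null_mean, p_perm`.
#' @export
flow_permutation_test <- function(edges, direction = c("uni", "bi"), B = 10000,
                                  seed = 1, chapters = chapter_map(),
                                  alternative = c("greater", "less")) {
  direction <- match.arg(direction)
  alternative <- match.arg(alternative)
  stopifnot(B >= 1)
  labs <- chapters$chapter
  k <- length(labs)
  ee <- edges[edges$direction == direction, , drop = FALSE]
  diseases <- sort(unique(c(edges$a, edges$b)))
  ch_of <- match(map_chapter(diseases, chapters), labs)
  src <- match(ee$a, diseases); dst <- match(ee$b, diseases)
  directed <- direction == "uni"
  obs <- flow_counts_for_assignment(src, dst, ch_of, k, directed)
  ge <- integer(k * k)
  null_sum <- numeric(k * k)
  set.seed(seed)
  for (b in seq_len(B)) {
    perm <- ch_of[sample.int(length(ch_of))]
    nc <- flow_counts_for_assignment(src, dst, perm, k, directed)
    if (alternative == "greater") ge <- ge + (nc >= obs) else ge <- ge + (nc <= obs)
    null_sum <- null_sum + nc
  }
  p <- (1 + ge) / (B + 1)
  idx <- which(obs > 0 | null_sum > 0)
  out <- data.frame(from = labs[((idx - 1L) %/% k) + 1L],
                    to = labs[((idx - 1L) %% k) + 1L],
                    observed = obs[idx], null_mean = null_sum[idx] / B,
                    p_perm = p[idx], stringsAsFactors = FALSE)
  out <- out[order(out$p_perm, out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, direction = direction, B = B, class = c("flow_test", "data.frame"))
}

#' Chord-diagram export of chapter flows
#'
#' Serializes the aggregated chapter tables into the long format used by
#' chord plotting: one row per chapter pair with nonzero weight, with
#' self-links flagged.
#'
#' @param tables Output of [aggregate_flows()].
#' @return data.frame `(from, to, weight, direction, self_link)`.
#' @export
chord_export <- function(tables) {
  longify <- function(m, dir) {
    idx <- which(m > 0, arr.ind = TRUE)
    if (nrow(idx) == 0L) {
      return(data.frame(from = character(0), to = character(0),
                        weight = integer(0), direction = character(0),
                        self_link = logical(0)))
    }
    data.frame(from = rownames(m)[idx[, 1]], to = colnames(m)[idx[, 2]],
               weight = m[idx], direction = dir,
               self_link = rownames(m)[idx[, 1]] == colnames(m)[idx[, 2]],
               stringsAsFactors = FALSE)
  }
  out <- rbind(longify(tables$uni, "uni"), longify(tables$bi, "bi"))
  out <- out[order(out$direction, out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rebuild chapter count tables from a chord table
#'
#' Inverse of [chord_export()] (round-trip check and CSV re-import).
#' @param chord Chord table data.frame.
#' @param chapters Chapter map.
#' @return List with `uni` and `bi` matrices.
#' @export
chord_import <- function(chord, chapters = chapter_map()) {
  labs <- chapters$chapter
  k <- length(labs)
  uni <- matrix(0L, k, k, dimnames = list(from = labs, to = labs))
  bi <- matrix(0L, k, k, dimnames = list(labs, labs))
  for (r in seq_len(nrow(chord))) {
    i <- match(chord$from[r], labs); j <- match(chord$to[r], labs)
    if (chord$direction[r] == "uni") uni[i, j] <- uni[i, j] + chord$weight[r]
    else bi[i, j] <- bi[i, j] + chord$weight[r]
  }
  list(uni = uni, bi = bi)
}
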