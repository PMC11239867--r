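## Effect-spectrum summaries: pair-class counts, influential / influenced /
## preventive / prevented rankings, onset-interval timing, and the ray/ring
## profile matrices consumed by the clustering stage.

#' Count pair classifications
#'
#' @param em An `effect_matrix`.
#' @return List with counts `n_increasing`, `n_decreasing`, `n_null`,
#'   `n_skipped` and `proportions` over all D*(D-1) ordered pairs.
#' @export
classify_counts <- function(em) {
  cls <- factor(em$class, levels = c("increasing", "decreasing", "null", "skipped"))
  counts <- table(cls)
  total <- nrow(em)
  list(n_increasing = unname(counts[["increasing"]]),
       n_decreasing = unname(counts[["decreasing"]]),
       n_null = unname(counts[["null"]]),
       n_skipped = unname(counts[["skipped"]]),
       proportions = as.numeric(counts) / total,
       total = total)
}

rank_core <- function(em, min_effect, margin = c("row", "col"),
                      direction = c("increasing", "decreasing"), top_k = NULL) {
  margin <- match.arg(margin); direction <- match.arg(direction)
  key <- if (margin == "row") em$a else em$b
  diseases <- sort(unique(c(em$a, em$b)))
  hit <- if (direction == "increasing") {
    em$class == "increasing" & em$psi > min_effect
  } else {
    em$class == "decreasing" & em$psi < -min_effect
  }
  usable <- em$class != "skipped"
  prop <- vapply(diseases, function(d) {
    den <- sum(usable & key == d)
    if (den == 0) return(0)
    sum(hit & key == d, na.rm = TRUE) / den
  }, numeric(1))
  mean_abs <- vapply(diseases, function(d) {
    v <- abs(em$psi[usable & key == d])
    if (length(v) == 0) 0 else mean(v, na.rm = TRUE)
  }, numeric(1))
  ## ties broken by mean |psi|, then code
  o <- order(-prop, -mean_abs, diseases)
  out <- data.frame(disease = diseases[o], proportion = prop[o],
                    mean_abs_effect = mean_abs[o], rank = seq_along(o),
                    stringsAsFactors = FALSE)
  if (!is.null(top_k)) out <- head(out, top_k)
  rownames(out) <- NULL
  out
}

#' Rank diseases by how they affect, or are affected by, others
#'
#' Proportions are taken over each disease's non-skipped pairs (denominator
#' D - 1 minus skips). "Strong" effects require an absolute
#' risk difference beyond 0.01 in addition to significance (configurable).
#'
#' * `rank_influential()`: proportion of other diseases a disease
#'   significantly increases (class `increasing` and psi > `min_effect`),
#'   row-wise.
#' * `rank_influenced()`: proportion of other diseases significantly
#'   increasing it, column-wise.
#' * `rank_preventive()` / `rank_prevented()`: decreasing analogues
#'   (class `decreasing` and psi < -`min_effect`).
#'
#' Ties are broken by mean |psi| then code order.
#'
#' @param em An `effect_matrix`.
#' @param min_effect Strong-effect threshold, default 0.01.
#' @param top_k Optionally truncate to the top k rows.
#' @return data.frame `(disease, proportion, mean_abs_effect, rank)`.
#' @export
rank_influential <- function(em, min_effect = 0.01, top_k = NULL) {
  rank_core(em, min_effect, "row", "increasing", top_k)
}

#' @rdname rank_influential
#' @export
rank_influenced <- function(em, min_effect = 0.01, top_k = NULL) {
  rank_core(em, min_effect, "col", "increasing", top_k)
}

#' @rdname rank_influential
#' @export
rank_preventive <- function(em, min_effect = 0.01, top_k = NULL) {
  rank_core(em, min_effect, "row", "decreasing", top_k)
}

#' @rdname rank_influential
#' @export
rank_prevented <- function(em, min_effect = 0.01, top_k = NULL) {
  rank_core(em, min_effect, "col", "decreasing", top_k)
}

#' Onset-interval timing of significant progression pairs
#'
#' For each significant increasing pair (a, b) above the effect threshold,
#' computes the median time (years) from a's onset to b's onset among
#' participants diagnosed with both in that order (lower-median convention
#' for even counts). Pairs with fewer than `min_count` qualifying
#' participants are excluded. Per influential disease, reports the fraction
#' of its pairs whose median falls in the bands < 1, 1-5, and > 5 years.
#'
#' @param diag A `diagnosis_table` with day-resolution onsets.
#' @param em An `effect_matrix`.
#' @param min_effect Strong-effect threshold, default 0.01.
#' @param min_count Minimum qualifying participants per pair, default 5.
#' @return List with `pairs` (a, b, median_years, n_pairs_obs, band) and
#'   `bands` (per disease: fraction in each band; rows sum to 1).
#' @export
onset_intervals <- function(diag, em, min_effect = 0.01, min_count = 5L) {
  sig <- em[em$class == "increasing" & !is.na(em$psi) & em$psi > min_effect, , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(list(pairs = data.frame(a = character(0), b = character(0),
                                   median_years = numeric(0), n_obs = integer(0),
                                   band = character(0)),
                bands = data.frame(disease = character(0), lt1 = numeric(0),
                                   y1to5 = numeric(0), gt5 = numeric(0))))
  }
  onset_by_code <- split(diag[c("id", "onset_day")], diag$code)
  rows <- lapply(seq_len(nrow(sig)), function(i) {
    a <- sig$a[i]; b <- sig$b[i]
    da <- onset_by_code[[a]]; db <- onset_by_code[[b]]
    if (is.null(da) || is.null(db)) return(NULL)
    m <- merge(da, db, by = "id", suffixes = c("_a", "_b"))
    gaps <- m$onset_day_b - m$onset_day_a
    gaps <- gaps[m$onset_day_a < m$onset_day_b]
    if (length(gaps) < min_count) return(NULL)
    med <- lower_median(gaps) / 365.25
    data.frame(a = a, b = b, median_years = med, n_obs = length(gaps),
               band = cut(med, c(-Inf, 1, 5, Inf), labels = c("<1", "1-5", ">5"),
                          right = FALSE),
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  if (is.null(pairs)) {
    return(list(pairs = data.frame(), bands = data.frame()))
  }
  bands <- do.call(rbind, lapply(split(pairs, pairs$a), function(pp) {
    data.frame(disease = pp$a[1],
               lt1 = mean(pp$band == "<1"),
               y1to5 = mean(pp$band == "1-5"),
               gt5 = mean(pp$band == ">5"),
               n_pairs = nrow(pp), stringsAsFactors = FALSE)
  }))
  rownames(bands) <- NULL
  list(pairs = pairs, bands = bands)
}

## lower median: for even counts take the lower of the two middle values
lower_median <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

#' Ray / ring profile matrices
#'
#' Builds the D x (D-1) signed-effect matrix used for clustering. Rows are
#' diseases; for `type = "rays"` row d holds d's effects on every other
#' disease (its consequential spectrum ray), for `type = "rings"` the effects
#' of every other disease on d (its causal spectrum ring). Cells classed
#' null or skipped are imputed 0 (only significant signal drives similarity).
#'
#' @param em An `effect_matrix`.
#' @param type `"rays"` or `"rings"`.
#' @param signed If FALSE, uses the sign only (+1/-1/0).
#' @return Numeric matrix with disease codes as row names.
#' @export
profile_matrix <- function(em, type = c("rays", "rings"), signed = TRUE) {
  type <- match.arg(type)
  diseases <- sort(unique(c(em$a, em$b)))
  D <- length(diseases)
  full <- matrix(0, D, D, dimnames = list(diseases, diseases))
  sig <- em$class %in% c("increasing", "decreasing")
  val <- ifelse(sig, em$psi, 0)
  if (!signed) val <- sign(val)
  full[cbind(match(em$a, diseases), match(em$b, diseases))] <- val
  if (type == "rings") full <- t(full)
  ## drop each row's own column: row d = its profile over the other diseases
  out <- matrix(0, D, D - 1L, dimnames = list(diseases, paste0("o", seq_len(D - 1L))))
  for (i in seq_len(D)) out[i, ] <- full[i, -i]
  out
}
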