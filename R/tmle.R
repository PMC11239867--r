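## Doubly-robust TMLE for the directional effect of disease a on disease b,
## for every ordered pair, with influence-curve inference and an explicit
## positivity policy (propensity truncation + minimum exposed/unexposed
## counts).

#' Build the estimation dataset for one directional pair
#'
#' Eligibility: free of the outcome disease b at baseline (no onset day <= 0).
#' Exposure designs:
#' * `"ever-before"` (default): A = 1 iff a's onset strictly precedes both b's
#'   onset and the end of follow-up (same-day onsets do not count as
#'   preceding). Matches onset-interval analyses but carries immortal-time
#'   risk; see the methods vignette.
#' * `"landmark"`: A = 1 iff a is prevalent at baseline (onset day <= 0). The
#'   point-treatment TMLE with baseline-only covariates is strictly valid
#'   under this design.
#'
#' Y = 1 iff b onsets in (t0, t0 + window], where t0 = 0 except in the
#' one-year sensitivity design where t0 is a's onset day for the exposed
#' (baseline for the unexposed). W = baseline covariates plus baseline
#' indicators of every study disease except a and b.
#'
#' @param onset n x D matrix of onset days (NA = never), columns named by
#'   disease code; e.g. `simulate_cohort()$onset_day` or [onset_matrix()].
#' @param W0 Numeric matrix of baseline covariates (one row per participant,
#'   aligned with `onset`).
#' @param a,b Disease codes (columns of `onset`).
#' @param follow_up_end Scalar follow-up end day.
#' @param window Outcome window in days (default: full follow-up).
#' @param design `"ever-before"` or `"landmark"`.
#' @param anchor_exposed_onset If TRUE (used by the one-year sensitivity
#'   analysis), the outcome window for exposed participants starts at a's
#'   onset day (truncated to >= 0) instead of baseline.
#' @param min_group Minimum exposed and unexposed counts; below it the pair
#'   is skipped as a positivity violation (default 10).
#' @return A `pair_dataset` list with `Y`, `A`, `W` (covariates + other-disease
#'   baseline indicators), `n`, and `skip_reason` (NULL if usable).
#' @export
build_pair_dataset <- function(onset, W0, a, b, follow_up_end,
                               window = Inf, design = c("ever-before", "landmark"),
                               anchor_exposed_onset = FALSE, min_group = 10L) {
  design <- match.arg(design)
  stopifnot(a != b, a %in% colnames(onset), b %in% colnames(onset))
  oa <- onset[, a]; ob <- onset[, b]
  eligible <- is.na(ob) | ob > 0
  oa <- oa[eligible]; ob <- ob[eligible]
  W0e <- W0[eligible, , drop = FALSE]
  onset_e <- onset[eligible, , drop = FALSE]
  n <- sum(eligible)
  skip <- function(reason) {
    structure(list(Y = NULL, A = NULL, W = NULL, n = n, a = a, b = b,
                   skip_reason = reason), class = "pair_dataset")
  }
  if (n == 0L) return(skip("no eligible participants"))
  if (design == "landmark") {
    A <- !is.na(oa) & oa <= 0
  } else {
    b_or_end <- pmin(ifelse(is.na(ob), Inf, ob), follow_up_end)
    A <- !is.na(oa) & oa < b_or_end
  }
  t0 <- rep(0, n)
  if (anchor_exposed_onset) t0[A] <- pmax(oa[A], 0)
  t_end <- pmin(t0 + window, follow_up_end)
  Y <- !is.na(ob) & ob > t0 & ob <= t_end
  if (sum(A) < min_group || sum(!A) < min_group) {
    return(skip("positivity: exposed or unexposed below minimum"))
  }
  others <- setdiff(colnames(onset), c(a, b))
  base_ind <- matrix(0, n, length(others), dimnames = list(NULL, paste0("base_", others)))
  if (length(others)) {
    base_ind[] <- !is.na(onset_e[, others, drop = FALSE]) &
      onset_e[, others, drop = FALSE] <= 0
  }
  W <- cbind(W0e, base_ind)
  structure(list(Y = as.numeric(Y), A = as.numeric(A), W = W, n = n,
                 a = a, b = b, skip_reason = NULL),
            class = "pair_dataset")
}

#' Onset-day matrix from a diagnosis table
#'
#' @param diag A `diagnosis_table`.
#' @param cov Covariate table (defines the participant set and order).
#' @param diseases Disease codes (columns).
#' @return n x D numeric matrix of onset days, NA where never diagnosed.
#' @export
onset_matrix <- function(diag, cov, diseases) {
  ids <- as.character(cov$id)
  M <- matrix(NA_real_, length(ids), length(diseases),
              dimnames = list(ids, diseases))
  d <- diag[diag$code %in% diseases, , drop = FALSE]
  d <- d[d$id %in% ids, , drop = FALSE]
  M[cbind(match(d$id, ids), match(d$code, diseases))] <- d$onset_day
  M
}

#' Numeric baseline covariate matrix from a covariate table
#'
#' Drops `id` and `sex`, expands factors/characters into indicator columns.
#' @param cov Covariate table.
#' @return Numeric matrix, one row per participant.
#' @export
covariate_matrix <- function(cov) {
  X <- cov[, setdiff(names(cov), c("id", "sex")), drop = FALSE]
  if (ncol(X) == 0L) return(matrix(0, nrow(cov), 0))
  mm <- stats::model.matrix(~ . , data = as.data.frame(X))
  mm[, setdiff(colnames(mm), "(Intercept)"), drop = FALSE]
}

## Logistic regression with a ridge-penalized fallback for separated or
## singular fits. Returns a prediction closure over a design matrix.
logistic_learner <- function(x, y, ridge_lambda = 1e-3) {
  x <- as.matrix(x)
  if (stats::var(y) == 0) {
    p <- mean(y)
    return(function(newx) rep(p, nrow(as.matrix(newx))))
  }
  keep <- apply(x, 2, function(col) stats::sd(col) > 0)
  xk <- x[, keep, drop = FALSE]
  fit <- NULL
  if (ncol(xk) == 0L) {
    p <- mean(y)
    return(function(newx) rep(p, nrow(as.matrix(newx))))
  }
  df <- data.frame(y = y, xk)
  fit <- suppressWarnings(try(stats::glm(y ~ ., data = df, family = stats::binomial()),
                              silent = TRUE))
  bad <- inherits(fit, "try-error") || !fit$converged ||
    any(abs(coef(fit)[-1]) > 15, na.rm = TRUE) || anyNA(coef(fit))
  if (!bad) {
    return(function(newx) {
      nd <- data.frame(as.matrix(newx)[, keep, drop = FALSE])
      names(nd) <- colnames(xk)
      as.numeric(predict(fit, newdata = nd, type = "response"))
    })
  }
  ## ridge fallback (separation / singularity)
  if (ncol(xk) == 1L) xk2 <- cbind(xk, 0) else xk2 <- xk
  rf <- suppressWarnings(
    glmnet::glmnet(xk2, y, family = "binomial", alpha = 0, lambda = ridge_lambda))
  function(newx) {
    nx <- as.matrix(newx)[, keep, drop = FALSE]
    if (ncol(xk) == 1L) nx <- cbind(nx, 0)
    as.numeric(predict(rf, newx = nx, type = "response"))
  }
}

#' Fit nuisance models for TMLE
#'
#' Default learners are main-terms logistic regressions: the outcome model
#' `Qbar(A, W)` regresses Y on A and W; the propensity `g(W)` regresses A on
#' W. Any probabilistic classifier can be plugged in via `learners`: a list
#' with elements `Q` and `g`, each a function `(x, y)` returning a prediction
#' closure `f(newx) -> prob`. Propensity values are clipped to `g_bounds` and
#' the clipped fraction is recorded (positivity diagnostic).
#'
#' @param ds A `pair_dataset`.
#' @param learners Optional list of learner factories (`Q`, `g`).
#' @param g_bounds Truncation bounds for g; default `c(0.01, 0.99)`.
#' @return A `nuisance_fit` list with vectors `QAW`, `Q1W`, `Q0W`, `g` and the
#'   diagnostic `clipped_frac`.
#' @export
fit_nuisance <- function(ds, learners = NULL, g_bounds = c(0.01, 0.99)) {
  stopifnot(is.null(ds$skip_reason))
  Qlearn <- if (!is.null(learners$Q)) learners$Q else logistic_learner
  glearn <- if (!is.null(learners$g)) learners$g else logistic_learner
  XA <- cbind(A = ds$A, ds$W)
  Qfit <- Qlearn(XA, ds$Y)
  QAW <- Qfit(XA)
  Q1W <- Qfit(cbind(A = 1, ds$W))
  Q0W <- Qfit(cbind(A = 0, ds$W))
  gfit <- glearn(ds$W, ds$A)
  g_raw <- gfit(ds$W)
  g <- pmin(pmax(g_raw, g_bounds[1]), g_bounds[2])
  eps <- 1e-9
  structure(list(QAW = pmin(pmax(QAW, eps), 1 - eps),
                 Q1W = pmin(pmax(Q1W, eps), 1 - eps),
                 Q0W = pmin(pmax(Q0W, eps), 1 - eps),
                 g = g,
                 clipped_frac = mean(g_raw < g_bounds[1] | g_raw > g_bounds[2]),
                 g_bounds = g_bounds),
            class = "nuisance_fit")
}

#' TMLE targeting step and influence-curve inference
#'
#' Fluctuates the initial outcome regression along the clever covariate
#' `H(A, W) = A/g(W) - (1-A)/(1-g(W))` by a one-dimensional logistic
#' regression of Y on H with offset `logit Qbar(A, W)`. The targeted estimate
#' is the plug-in contrast `psi = mean(Q*(1, W) - Q*(0, W))`; its standard
#' error comes from the efficient influence curve
#' `IC = H (Y - Q*(A, W)) + Q*(1, W) - Q*(0, W) - psi`.
#' A directional pair is classed `increasing` when the 95% CI lies above 0,
#' `decreasing` when below, `null` otherwise.
#'
#' @param ds A `pair_dataset`.
#' @param fit A `nuisance_fit`.
#' @return A one-row data.frame (`tmle_result`): `a, b, psi, se, ci_low,
#'   ci_high, p, class, n, clipped_frac, skip_reason`, plus attribute
#'   `ic_mean` (mean influence curve after targeting; ~0 by construction).
#' @export
tmle_estimate <- function(ds, fit) {
  if (!is.null(ds$skip_reason)) return(skipped_result(ds$a, ds$b, ds$n, ds$skip_reason))
  H <- ds$A / fit$g - (1 - ds$A) / (1 - fit$g)
  off <- qlogis(fit$QAW)
  flu <- suppressWarnings(try(
    stats::glm(ds$Y ~ -1 + H, offset = off, family = stats::binomial(),
               start = 0, control = stats::glm.control(epsilon = 1e-14, maxit = 200)),
    silent = TRUE))
  if (inherits(flu, "try-error") || !flu$converged || !is.finite(coef(flu)[1])) {
    return(skipped_result(ds$a, ds$b, ds$n, "fluctuation non-convergence"))
  }
  epsilon <- as.numeric(coef(flu)[1])
  H1 <- 1 / fit$g
  H0 <- -1 / (1 - fit$g)
  Qs <- plogis(qlogis(fit$QAW) + epsilon * H)
  Q1s <- plogis(qlogis(fit$Q1W) + epsilon * H1)
  Q0s <- plogis(qlogis(fit$Q0W) + epsilon * H0)
  psi <- mean(Q1s - Q0s)
  IC <- H * (ds$Y - Qs) + Q1s - Q0s - psi
  se <- sd(IC) / sqrt(ds$n)
  ci <- psi + c(-1, 1) * 1.96 * se
  p <- 2 * pnorm(-abs(psi / se))
  cls <- if (ci[1] > 0) "increasing" else if (ci[2] < 0) "decreasing" else "null"
  out <- data.frame(a = ds$a, b = ds$b, psi = psi, se = se,
                    ci_low = ci[1], ci_high = ci[2], p = p, class = cls,
                    n = ds$n, clipped_frac = fit$clipped_frac,
                    ic_mean = mean(IC),
                    skip_reason = NA_character_, stringsAsFactors = FALSE)
  attr(out, "ic_mean") <- mean(IC)
  class(out) <- c("tmle_result", "data.frame")
  out
}

skipped_result <- function(a, b, n, reason) {
  out <- data.frame(a = a, b = b, psi = NA_real_, se = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                    class = "skipped", n = n, clipped_frac = NA_real_,
                    ic_mean = NA_real_,
                    skip_reason = reason, stringsAsFactors = FALSE)
  class(out) <- c("tmle_result", "data.frame")
  out
}

#' Estimate all directional pairwise effects
#'
#' Runs [build_pair_dataset()], [fit_nuisance()] and [tmle_estimate()] for
#' every ordered pair of study diseases and collects the results into an
#' effect matrix (long format, the exchange object for all downstream
#' analyses). Deterministic given the data.
#'
#' @param diag A `diagnosis_table` (or NULL if `onset` is given).
#' @param cov Covariate table.
#' @param diseases Character vector of study disease codes.
#' @param window Outcome window in days (default full follow-up).
#' @param design Exposure design, see [build_pair_dataset()].
#' @param g_bounds Propensity truncation bounds.
#' @param learners Optional nuisance learner factories.
#' @param adjust `"none"` (default; raw 95% CI classes) or `"BH"` for
#'   Benjamini-Hochberg: classes are then based on adjusted p < 0.05 with the
#'   sign of psi.
#' @param onset Optional precomputed onset matrix (skips `onset_matrix()`).
#' @param follow_up_end Scalar follow-up end day; inferred from `diag` if
#'   absent.
#' @param anchor_exposed_onset Passed to [build_pair_dataset()].
#' @param verbose Print progress every 50 pairs.
#' @return An `effect_matrix`: data.frame with one row per ordered pair and
#'   attributes `diseases`, `sex`, `design`, `window`.
#' @export
run_all_pairs <- function(diag, cov, diseases, window = Inf,
                          design = "ever-before", g_bounds = c(0.01, 0.99),
                          learners = NULL, adjust = c("none", "BH"),
                          onset = NULL, follow_up_end = NULL,
                          anchor_exposed_onset = FALSE, verbose = FALSE) {
  adjust <- match.arg(adjust)
  diseases <- sort(as.character(diseases))
  if (length(diseases) < 2L) stop("need at least 2 diseases")
  if (is.null(onset)) onset <- onset_matrix(diag, cov, diseases)
  if (is.null(follow_up_end)) {
    fu <- attr(diag, "follow_up_end")
    follow_up_end <- if (is.null(fu)) max(onset, na.rm = TRUE) else max(fu)
  }
  W0 <- covariate_matrix(cov)
  pairs <- enumerate_pairs(diseases)
  res <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ds <- build_pair_dataset(onset, W0, pairs$a[i], pairs$b[i], follow_up_end,
                             window = window, design = design,
                             anchor_exposed_onset = anchor_exposed_onset)
    if (is.null(ds$skip_reason)) {
      fit <- fit_nuisance(ds, learners = learners, g_bounds = g_bounds)
      res[[i]] <- tmle_estimate(ds, fit)
    } else {
      res[[i]] <- skipped_result(pairs$a[i], pairs$b[i], ds$n, ds$skip_reason)
    }
    if (verbose && i %% 50 == 0) message("pair ", i, "/", nrow(pairs))
  }
  em <- do.call(rbind, lapply(res, function(r) { attr(r, "ic_mean") <- NULL; r }))
  rownames(em) <- NULL
  if (adjust == "BH") {
    ok <- em$class != "skipped"
    padj <- p.adjust(em$p[ok], method = "BH")
    cls <- ifelse(padj < 0.05, ifelse(em$psi[ok] > 0, "increasing", "decreasing"), "null")
    em$p_adj <- NA_real_
    em$p_adj[ok] <- padj
    em$class[ok] <- cls
  }
  structure(em, diseases = diseases,
            sex = if (!is.null(cov$sex)) as.character(cov$sex[1]) else "unspecified",
            design = design, window = window,
            class = c("effect_matrix", "data.frame"))
}

#' One-year sensitivity analysis
#'
#' Re-runs the full pairwise estimation with the outcome window limited to
#' 365 days from time zero (a's onset for the exposed, baseline for the
#' unexposed), and reports, per exposure disease, the fraction of its pairs
#' whose one-year effect magnitude exceeds the full-follow-up magnitude —
#' a summary of how rapidly each disease's influence acts.
#'
#' @inheritParams run_all_pairs
#' @param full Optional precomputed full-window `effect_matrix` (avoids
#'   refitting).
#' @return List with `effects` (the one-year `effect_matrix`) and
#'   `rapidity` (per-disease data.frame of the fraction of pairs with
#'   `|effect_1yr| > |effect_full|`).
#' @export
one_year_sensitivity <- function(diag, cov, diseases, design = "ever-before",
                                 g_bounds = c(0.01, 0.99), learners = NULL,
                                 onset = NULL, follow_up_end = NULL, full = NULL) {
  em1 <- run_all_pairs(diag, cov, diseases, window = 365, design = design,
                       g_bounds = g_bounds, learners = learners, onset = onset,
                       follow_up_end = follow_up_end, anchor_exposed_onset = TRUE)
  if (is.null(full)) {
    full <- run_all_pairs(diag, cov, diseases, window = Inf, design = design,
                          g_bounds = g_bounds, learners = learners, onset = onset,
                          follow_up_end = follow_up_end)
  }
  key <- paste(em1$a, em1$b)
  fm <- full[match(key, paste(full$a, full$b)), ]
  ok <- em1$class != "skipped" & fm$class != "skipped"
  rap <- tapply(abs(em1$psi[ok]) > abs(fm$psi[ok]), em1$a[ok], mean)
  rapidity <- data.frame(disease = names(rap), frac_stronger_1yr = as.numeric(rap),
                         stringsAsFactors = FALSE)
  list(effects = em1, rapidity = rapidity)
}

#' Read / write effect matrices
#'
#' Long-format CSV with columns
#' `a, b, psi, se, ci_low, ci_high, p, class, n, clipped_frac, skip_reason`
#' — the exchange format consumed by the spectrum, flow and constellation
#' stages.
#' @param em An `effect_matrix`.
#' @param path File path.
#' @name effect_io
NULL

#' @rdname effect_io
#' @export
write_effect_matrix <- function(em, path) {
  df <- as.data.frame(em)
  df <- df[order(df$a, df$b), , drop = FALSE]
  ## full precision so a read-back reproduces downstream results bit-exactly
  for (col in names(df)) {
    if (is.numeric(df[[col]])) df[[col]] <- sprintf("%.17g", df[[col]])
  }
  df$n <- as.integer(em$n[order(em$a, em$b)])
  write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname effect_io
#' @param sex,design,window Metadata restored on read.
#' @export
read_effect_matrix <- function(path, sex = "unspecified", design = "ever-before",
                               window = Inf) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  structure(df, diseases = sort(unique(c(df$a, df$b))), sex = sex,
            design = design, window = window,
            class = c("effect_matrix", "data.frame"))
}
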