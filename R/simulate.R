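## Synthetic sex-stratified longitudinal cohorts from a planted directed
## effect graph, plus a Monte-Carlo do-intervention oracle for the
## ground-truth risk differences.

#' Simulation configuration
#'
#' Defines one sex stratum of a synthetic cohort. Onsets follow a discrete-time
#' hazard model on a quarterly (91-day) grid: at each step, every not-yet-onset
#' disease d onsets with probability
#' `plogis(alpha_d + beta_d' L_i + sum_{d' on} gamma[d', d])`,
#' where `L_i` are baseline covariates shared across diseases (the measured
#' confounders) and `gamma` is the planted effect graph. A pre-baseline
#' burn-in produces diagnoses prevalent at baseline (onset day <= 0).
#' `alpha_d` is calibrated so the marginal ever-diagnosed prevalence matches
#' `target_prevalence` under `gamma = 0`.
#'
#' @param n Number of participants.
#' @param D Number of diseases.
#' @param follow_up_years Follow-up length; default 12.7 years.
#' @param step_days Hazard grid step; default 91 (quarterly).
#' @param burn_in_years Pre-baseline burn-in generating prevalent disease;
#'   default 5 years.
#' @param n_covariates Number of standard-normal baseline covariates.
#' @param beta_sd SD of the per-disease covariate loadings (confounding
#'   strength); default 0.3 on the log-odds scale.
#' @param beta Optional explicit loading matrix (`n_covariates` x D) used
#'   instead of drawing loadings from `beta_sd`.
#' @param target_prevalence Length-D vector of target marginal (ever
#'   diagnosed) prevalences in (0,1); default evenly spaced 0.02..0.20.
#' @param sex Stratum label.
#' @param hidden_covariate If TRUE the first covariate is dropped from the
#'   emitted covariate table (unmeasured confounding switch); it still drives
#'   onsets.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n = 5000, D = 20, follow_up_years = 12.7, step_days = 91,
                       burn_in_years = 5, n_covariates = 4, beta_sd = 0.3,
                       beta = NULL, target_prevalence = NULL, sex = "female",
                       hidden_covariate = FALSE, seed = 1) {
  if (is.null(target_prevalence)) {
    target_prevalence <- seq(0.02, 0.20, length.out = D)
  }
  stopifnot(n >= 1, D >= 2, length(target_prevalence) == D,
            all(target_prevalence > 0), all(target_prevalence < 1),
            step_days >= 1, follow_up_years * 365.25 >= step_days)
  structure(list(n = as.integer(n), D = as.integer(D),
                 follow_up_years = follow_up_years, step_days = as.integer(step_days),
                 burn_in_years = burn_in_years, n_covariates = as.integer(n_covariates),
                 beta_sd = beta_sd, beta = beta,
                 target_prevalence = target_prevalence,
                 sex = sex, hidden_covariate = isTRUE(hidden_covariate),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Disease code labels used by the simulator
#'
#' Synthetic diseases are assigned valid three-character ICD-10 categories
#' spread across the study chapters so chapter-level analyses are exercised.
#' @param D Number of diseases.
#' @return Character vector of D codes.
#' @export
sim_disease_codes <- function(D) {
  letters10 <- c("A", "C", "D", "E", "F", "G", "H", "I", "J", "K",
                 "L", "M", "N", "O", "U", "B")
  code <- character(D)
  for (i in seq_len(D)) {
    l <- letters10[((i - 1L) %% length(letters10)) + 1L]
    num <- ((i - 1L) %/% length(letters10)) * 7L + 10L  # stays within chapters
    if (l == "U") num <- min(num, 49L)
    if (l == "D") num <- min(num, 48L)   # keep inside C00-D48? D10.. is C00-D48
    code[i] <- sprintf("%s%02d", l, num)
  }
  stopifnot(!anyDuplicated(code))
  code
}

n_steps <- function(config) {
  list(burn = as.integer(round(config$burn_in_years * 365.25 / config$step_days)),
       follow = as.integer(floor(config$follow_up_years * 365.25 / config$step_days)))
}

#' Plant a sparse directed effect graph
#'
#' @param D Number of diseases.
#' @param density Expected fraction of the D*(D-1) ordered pairs with a
#'   nonzero effect.
#' @param effect_range Magnitude range (log-odds scale) for nonzero effects.
#' @param negative_fraction Fraction of nonzero effects drawn negative.
#' @param seed Integer seed.
#' @return A D x D matrix `gamma` with zero diagonal; `gamma[d1, d2]` is the
#'   additive log-odds effect of having disease d1 on the onset hazard of d2.
#' @export
make_planted_graph <- function(D, density = 0.1, effect_range = c(0.3, 0.9),
                               negative_fraction = 0.25, seed = 1) {
  stopifnot(density >= 0, density <= 1, length(effect_range) == 2)
  set.seed(seed)
  gamma <- matrix(0, D, D)
  off <- which(row(gamma) != col(gamma))
  on <- off[runif(length(off)) < density]
  if (length(on)) {
    mag <- runif(length(on), min(effect_range), max(effect_range))
    sgn <- ifelse(runif(length(on)) < negative_fraction, -1, 1)
    gamma[on] <- sgn * mag
  }
  gamma
}

## Draw the fixed model parts (covariates, loadings, calibrated intercepts).
## Everything is a deterministic function of the config seed.
sim_model <- function(config, gamma) {
  ns <- n_steps(config)
  K <- ns$burn + ns$follow
  set.seed(config$seed)
  L <- matrix(rnorm(config$n * config$n_covariates), config$n, config$n_covariates)
  colnames(L) <- paste0("x", seq_len(config$n_covariates))
  beta <- if (!is.null(config$beta)) {
    stopifnot(nrow(config$beta) == config$n_covariates,
              ncol(config$beta) == config$D)
    config$beta
  } else {
    matrix(rnorm(config$n_covariates * config$D, sd = config$beta_sd),
           config$n_covariates, config$D)
  }
  eta_cov <- L %*% beta                       # n x D
  alpha <- vapply(seq_len(config$D), function(d) {
    target <- config$target_prevalence[d]
    f <- function(a) mean(1 - (1 - plogis(a + eta_cov[, d]))^K) - target
    lo <- -30; hi <- 5
    if (f(lo) > 0 || f(hi) < 0) stop("prevalence calibration failed for disease ", d)
    uniroot(f, c(lo, hi), tol = 1e-10)$root
  }, numeric(1))
  list(L = L, beta = beta, alpha = alpha, eta_cov = eta_cov,
       burn = ns$burn, follow = ns$follow)
}

## Core discrete-time engine. force_on / force_off are disease indices whose
## onset status is overridden: force_on is switched on from the first
## follow-up step (onset at day 0); force_off never onsets. Natural onsets of
## any forced disease are suppressed so the uniform draws stay aligned across
## counterfactual arms (common random numbers).
sim_engine <- function(model, gamma, config, force_on = integer(0),
                       force_off = integer(0), rng_seed) {
  n <- config$n; D <- config$D
  burn <- model$burn; follow <- model$follow
  forced <- union(force_on, force_off)
  status <- matrix(FALSE, n, D)
  onset_step <- matrix(NA_integer_, n, D)
  ## hazards change only for rows that acquire a disease with outgoing
  ## effects, so the probability matrix is updated incrementally
  eta_base <- sweep(model$eta_cov, 2, model$alpha, "+")
  eta_g <- matrix(0, n, D)
  P <- 1 / (1 + exp(-eta_base))
  has_out <- which(rowSums(gamma != 0) > 0)
  set.seed(rng_seed)
  for (s in seq_len(burn + follow)) {
    if (s == burn + 1L && length(force_on)) {
      status[, force_on] <- TRUE
      onset_step[, force_on] <- 0L           # onset day 0 marker
      fo <- intersect(force_on, has_out)
      if (length(fo)) {
        eta_g <- sweep(eta_g, 2, colSums(gamma[fo, , drop = FALSE]), "+")
        P <- 1 / (1 + exp(-(eta_base + eta_g)))
      }
    }
    u <- matrix(runif(n * D), n, D)
    new <- !status & (u < P)
    if (length(forced)) new[, forced] <- FALSE
    if (any(new)) {
      onset_step[new] <- s - burn             # day = step_index * step_days
      status <- status | new
      nd <- intersect(which(colSums(new) > 0), has_out)
      if (length(nd)) {
        rows <- which(rowSums(new[, nd, drop = FALSE]) > 0)
        eta_g[rows, ] <- eta_g[rows, ] +
          new[rows, nd, drop = FALSE] %*% gamma[nd, , drop = FALSE]
        P[rows, ] <- 1 / (1 + exp(-(eta_base[rows, , drop = FALSE] +
                                      eta_g[rows, , drop = FALSE])))
      }
    }
  }
  onset_step
}

#' Simulate a cohort from a planted graph
#'
#' @param config A [sim_config()].
#' @param gamma Planted effect graph from [make_planted_graph()] (or a zero
#'   matrix for a global-null cohort).
#' @return List with `diag` (a `diagnosis_table`), `cov` (covariate table with
#'   `id`, `sex` and covariate columns), `diseases` (code vector), `gamma`,
#'   and `onset_day` (n x D matrix of onset days, NA = never; kept for fast
#'   downstream use).
#' @export
simulate_cohort <- function(config, gamma = NULL) {
  if (is.null(gamma)) gamma <- matrix(0, config$D, config$D)
  stopifnot(nrow(gamma) == config$D, ncol(gamma) == config$D,
            all(diag(gamma) == 0), all(is.finite(gamma)))
  model <- sim_model(config, gamma)
  onset_step <- sim_engine(model, gamma, config, rng_seed = config$seed + 1L)
  onset_day <- onset_step * config$step_days
  codes <- sim_disease_codes(config$D)
  colnames(onset_day) <- codes
  ids <- sprintf("P%06d", seq_len(config$n))
  rownames(onset_day) <- ids
  fu_end <- model$follow * config$step_days
  idx <- which(!is.na(onset_day), arr.ind = TRUE)
  diag_tab <- diagnosis_table(id = ids[idx[, 1]], code = codes[idx[, 2]],
                              onset_day = onset_day[idx],
                              follow_up_end = setNames(rep(fu_end, config$n), ids),
                              sex = config$sex)
  Lout <- model$L
  if (config$hidden_covariate) Lout <- Lout[, -1, drop = FALSE]
  cov <- data.frame(id = ids, sex = config$sex, Lout, stringsAsFactors = FALSE)
  list(diag = diag_tab, cov = cov, diseases = codes, gamma = gamma,
       onset_day = onset_day, follow_up_end = fu_end, config = config)
}

#' Ground-truth do-intervention effects (Monte-Carlo oracle)
#'
#' For an exposure disease a, simulates paired counterfactual cohorts with
#' common random numbers: do(a onsets at baseline) vs do(a never onsets),
#' holding covariates and every other mechanism fixed. The true effect on each
#' outcome b is the difference in cumulative incidence of b over follow-up
#' among participants free of b at baseline (identical sets in both arms).
#'
#' @param gamma Planted effect graph.
#' @param config A [sim_config()]; `config$n` is ignored in favour of `n_mc`.
#' @param a Exposure disease index (or code from [sim_disease_codes()]).
#' @param n_mc Monte-Carlo cohort size.
#' @param seed Integer seed for the oracle draws.
#' @return data.frame with one row per outcome disease b != a: columns
#'   `a`, `b`, `effect` (risk difference) and `mc_se`.
#' @export
true_effect_profile <- function(gamma, config, a, n_mc = 50000, seed = 1) {
  codes <- sim_disease_codes(config$D)
  if (is.character(a)) a <- match(a, codes)
  stopifnot(a >= 1, a <= config$D)
  cfg <- config
  cfg$n <- as.integer(n_mc)
  cfg$seed <- as.integer(seed)
  model <- sim_model(cfg, gamma)
  on1 <- sim_engine(model, gamma, cfg, force_on = a, rng_seed = cfg$seed + 1L)
  on0 <- sim_engine(model, gamma, cfg, force_off = a, rng_seed = cfg$seed + 1L)
  out <- lapply(setdiff(seq_len(cfg$D), a), function(b) {
    ## b-free at baseline: no onset in burn-in (identical in both arms)
    free <- (is.na(on1[, b]) | on1[, b] > 0) & (is.na(on0[, b]) | on0[, b] > 0)
    y1 <- !is.na(on1[free, b]) & on1[free, b] > 0
    y0 <- !is.na(on0[free, b]) & on0[free, b] > 0
    d <- as.numeric(y1) - as.numeric(y0)
    data.frame(a = codes[a], b = codes[b], effect = mean(d),
               mc_se = sd(d) / sqrt(length(d)), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @rdname true_effect_profile
#' @param b Outcome disease index or code.
#' @export
true_effect <- function(gamma, config, a, b, n_mc = 50000, seed = 1) {
  codes <- sim_disease_codes(config$D)
  if (is.character(b)) b <- match(b, codes)
  prof <- true_effect_profile(gamma, config, a, n_mc = n_mc, seed = seed)
  prof[prof$b == codes[b], , drop = FALSE]
}

#' Full ground-truth effect matrix
#'
#' Runs [true_effect_profile()] for every exposure disease. One paired
#' counterfactual simulation per exposure yields the effects on all outcomes.
#'
#' @inheritParams true_effect_profile
#' @return data.frame with columns `a`, `b`, `effect`, `mc_se` for all ordered
#'   pairs.
#' @export
true_effect_matrix <- function(gamma, config, n_mc = 50000, seed = 1) {
  out <- lapply(seq_len(config$D), function(a) {
    true_effect_profile(gamma, config, a, n_mc = n_mc, seed = seed + a)
  })
  do.call(rbind, out)
}
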