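#' Pharmacological condition groups for the index-bias simulations
#'
#' The Monte-Carlo evaluation of Combination Index and BRAID false-call
#' rates runs over three groups of asymptotically additive conditions:
#' matched Hill slopes (1, 2, 3, 4 — slope 1 being the default baseline),
#' differing Hill slopes at fixed ratios (1/1.5, 0.9/1.8, 0.8/2.4, 0.75/3),
#' and a partial maximal effect of the second drug (90%, 80%, 70%, 60%).
#' All conditions share doses of median effect of 1 uM and a baseline of 0%.
#'
#' @return named list of condition definitions (fields `name`, `group`,
#'   `na`, `nb`, `efA`, `efB`).
#' @export
ci_condition_groups <- function() {
  conds <- list(
    list(name = "matched_slope_1", group = "matched", na = 1,    nb = 1),
    list(name = "matched_slope_2", group = "matched", na = 2,    nb = 2),
    list(name = "matched_slope_3", group = "matched", na = 3,    nb = 3),
    list(name = "matched_slope_4", group = "matched", na = 4,    nb = 4),
    list(name = "slope_ratio_1.5", group = "ratio",   na = 1,    nb = 1.5),
    list(name = "slope_ratio_2",   group = "ratio",   na = 0.9,  nb = 1.8),
    list(name = "slope_ratio_3",   group = "ratio",   na = 0.8,  nb = 2.4),
    list(name = "slope_ratio_4",   group = "ratio",   na = 0.75, nb = 3),
    list(name = "max_effect_90",   group = "maxeff",  na = 1,    nb = 1, efB = 90),
    list(name = "max_effect_80",   group = "maxeff",  na = 1,    nb = 1, efB = 80),
    list(name = "max_effect_70",   group = "maxeff",  na = 1,    nb = 1, efB = 70),
    list(name = "max_effect_60",   group = "maxeff",  na = 1,    nb = 1, efB = 60)
  )
  conds <- lapply(conds, function(cn) {
    cn$efA <- 100
    if (is.null(cn$efB)) cn$efB <- 100
    cn
  })
  names(conds) <- vapply(conds, `[[`, "", "name")
  conds
}

condition_pair <- function(cond, idm = 1, e0 = 0) {
  additive_pair(hill_params(idm, cond$na, e0, cond$efA),
                hill_params(idm, cond$nb, e0, cond$efB))
}

#' Simulate one asymptotically additive condition experiment
#'
#' Triplicate 15-point single-agent series and a triplicate 10x10
#' checkerboard drawn from the asymptotically additive surface of a
#' condition, with Gaussian response noise and log-normal dosing error.
#'
#' @param cond one element of [ci_condition_groups()].
#' @param design a [checkerboard_design()] (default: the standard bias
#'   design in triplicate).
#' @param noise a [noise_spec()] (default: 7.5% response noise and
#'   `log(1.1)` dosing error).
#' @param idm shared dose of median effect.
#' @return list with `checkerboard`, `singles` (list `A`, `B`), `spec`.
#' @export
simulate_condition_experiment <- function(cond,
                                          design = standard_bias_design(3),
                                          noise = noise_spec(7.5, log(1.1)),
                                          idm = 1) {
  spec <- condition_pair(cond, idm = idm)
  surf <- function(a, b) asymptotic_additive_effect(spec, a, b)
  list(checkerboard = simulate_checkerboard(surf, design, noise),
       singles = simulate_single_agents(spec$hillA, spec$hillB, design, noise),
       spec = spec)
}

fit_variant <- function(data, variant) {
  switch(variant,
    chou = fit_hill_median_effect(data),
    ls   = fit_hill_ls(data, fix_bounds = c(0, 100)))
}

#' Combination Index false-call simulation across condition groups
#'
#' For each pharmacological condition, simulates additive checkerboard
#' experiments and scores them with both Combination Index variants: the
#' median-effect "Chou Index" (logit linearisation) and the least-squares
#' "Combination Index" (direct log-logistic fit with effects constrained to
#' 0/100%).  Per experiment, the seven longest constant-ratio diagonals are
#' each fit and CI evaluated at the 50% and 99% effect levels; every
#' (ratio, level) judgment is tallied (the `pooled` rows), and a
#' per-experiment majority call over the defined ratios is tallied as well
#' (the `experiment` rows).
#'
#' @param conditions list of conditions, default [ci_condition_groups()].
#' @param n_sims simulated experiments per condition.
#' @param variants CI variants to run.
#' @param design,noise,idm see [simulate_condition_experiment()].
#' @param seed integer seed for the whole run.
#' @return a `data.frame` (BiasTable): one row per (condition, variant,
#'   level, tally) with percent synergistic / antagonistic calls.
#' @export
run_ci_condition_sim <- function(conditions = ci_condition_groups(),
                                 n_sims = 1000,
                                 variants = c("chou", "ls"),
                                 design = standard_bias_design(3),
                                 noise = noise_spec(7.5, log(1.1)),
                                 idm = 1, seed = NULL) {
  maybe_seed(seed)
  levels_pct <- c(50, 99)
  out <- list()
  for (cond in conditions) {
    # judgments[variant, level] lists of call vectors
    tallies <- list()
    for (s in seq_len(n_sims)) {
      ex <- simulate_condition_experiment(cond, design, noise, idm)
      diags <- extract_diagonals(ex$checkerboard, 7)
      for (v in variants) {
        fA <- try(fit_variant(ex$singles$A, v), silent = TRUE)
        fB <- try(fit_variant(ex$singles$B, v), silent = TRUE)
        if (inherits(fA, "try-error") || inherits(fB, "try-error")) next
        for (lev in levels_pct) {
          cis <- vapply(diags, function(dg) {
            fd <- try(fit_variant(
              dose_response_data(dg$total, dg$response, dg$replicate), v),
              silent = TRUE)
            if (inherits(fd, "try-error")) return(NA_real_)
            combination_index(fA, fB, fd, lev, attr(dg, "ratio"))
          }, numeric(1))
          calls <- classify_ci(cis)
          key <- paste(v, lev, sep = "_")
          tallies[[key]] <- c(tallies[[key]], list(calls))
        }
      }
    }
    for (key in names(tallies)) {
      vl <- strsplit(key, "_")[[1]]
      allcalls <- unlist(tallies[[key]])
      defined <- allcalls[!is.na(allcalls)]
      per_exp <- vapply(tallies[[key]], function(calls) {
        calls <- calls[!is.na(calls)]
        if (!length(calls)) return(NA_character_)
        ns <- sum(calls == "synergistic"); na_ <- sum(calls == "antagonistic")
        if (ns > length(calls) / 2) "synergistic"
        else if (na_ > length(calls) / 2) "antagonistic" else "additive"
      }, character(1))
      per_exp <- per_exp[!is.na(per_exp)]
      out[[length(out) + 1]] <- data.frame(
        condition = cond$name, group = cond$group, variant = vl[1],
        level = as.numeric(vl[2]),
        tally = c("pooled", "experiment"),
        pct_synergistic = 100 * c(mean(defined == "synergistic"),
                                  mean(per_exp == "synergistic")),
        pct_antagonistic = 100 * c(mean(defined == "antagonistic"),
                                   mean(per_exp == "antagonistic")),
        n = c(length(defined), length(per_exp)))
    }
  }
  do.call(rbind, out)
}

#' BRAID false-call simulation across condition groups
#'
#' Fits the 8-parameter BRAID surface (with a bootstrap `kappa` interval)
#' to the same kind of simulated additive experiments as
#' [run_ci_condition_sim()] and tallies how often the interval rule falsely
#' calls synergy or antagonism.
#'
#' @inheritParams run_ci_condition_sim
#' @param n_boot bootstrap resamples per fit.
#' @return a `data.frame`: one row per condition with percent false synergy
#'   / antagonism calls.
#' @export
run_braid_condition_sim <- function(conditions = ci_condition_groups(),
                                    n_sims = 1000, n_boot = 200,
                                    design = standard_bias_design(3),
                                    noise = noise_spec(7.5, log(1.1)),
                                    idm = 1, seed = NULL) {
  maybe_seed(seed)
  out <- lapply(conditions, function(cond) {
    calls <- vapply(seq_len(n_sims), function(s) {
      ex <- simulate_condition_experiment(cond, design, noise, idm)
      dat <- combine_combination_data(ex$checkerboard, ex$singles$A,
                                      ex$singles$B)
      fit <- try(fit_braid(dat, n_boot = n_boot), silent = TRUE)
      if (inherits(fit, "try-error")) return(NA_character_)
      fit$call_type
    }, character(1))
    calls <- calls[!is.na(calls)]
    data.frame(condition = cond$name, group = cond$group,
               pct_synergistic = 100 * mean(calls == "synergistic"),
               pct_antagonistic = 100 * mean(calls == "antagonistic"),
               n = length(calls))
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Configuration of the simulated Bliss combination screens
#'
#' Defaults follow the screen-bias study design: eight compounds differing
#' only in Hill slope (0.5 to 4 in 0.5 steps), doses of median effect of
#' 1 uM, percent effects 0-100, 15-point two-fold single-agent series
#' centered on 1 uM, 10x10 two-fold checkerboards with maximum 32 uM, and
#' 5% Gaussian response noise.
#'
#' @param slopes Hill slopes of the screened compounds.
#' @param idm shared dose of median effect.
#' @param e0,ef effect bounds (percent scale).
#' @param design a [checkerboard_design()].
#' @param noise_sd response noise sd (percent points).
#' @param n_screens number of simulated screens.
#' @param calibration which compounds set the self-vs-self thresholds:
#'   all of them, only the low-slope half (<= 2), or only the high-slope
#'   half (>= 2.5).
#' @param calibration_reps self-vs-self repetitions per compound.
#' @param seed integer seed.
#' @return a list of class `bliss_screen_config`.
#' @export
bliss_screen_config <- function(slopes = seq(0.5, 4, by = 0.5), idm = 1,
                                e0 = 0, ef = 100,
                                design = standard_bias_design(),
                                noise_sd = 5, n_screens = 1000,
                                calibration = c("all", "low", "high"),
                                calibration_reps = 3, seed = NULL) {
  calibration <- match.arg(calibration)
  structure(list(slopes = slopes, idm = idm, e0 = e0, ef = ef,
                 design = design, noise_sd = noise_sd,
                 n_screens = n_screens, calibration = calibration,
                 calibration_reps = calibration_reps, seed = seed),
            class = "bliss_screen_config")
}

#' Simulated Bliss combination screens with empirical thresholds
#'
#' Runs repeated simulated all-vs-all combination screens of additive
#' (Loewe) surfaces and tallies, per compound pair, how often the Bliss
#' volume with self-vs-self-calibrated thresholds judges the pair
#' non-additive.  Per screen: (1) thresholds are set from the 2.5/97.5
#' percentiles of the calibration compounds' sham-combination Bliss
#' volumes (3 repetitions each); (2) all 64 ordered compound pairs
#' (including self-vs-self) are simulated, their Bliss volumes computed
#' from freshly fitted single-agent curves, and classified.
#'
#' Because the additive reference surfaces are deterministic for a given
#' slope pair, they are precomputed once on the dose grid; each screen
#' adds fresh measurement noise.
#'
#' @param config a [bliss_screen_config()].
#' @return a `data.frame` (BiasTable): one row per ordered slope pair with
#'   synergy/antagonism call counts and percentages across screens.
#' @export
run_bliss_screen_sim <- function(config = bliss_screen_config()) {
  maybe_seed(config$seed)
  slopes <- config$slopes
  k <- length(slopes)
  des <- config$design
  compounds <- lapply(slopes, function(s)
    hill_params(config$idm, s, config$e0, config$ef))
  grid <- expand.grid(dA = des$concsA, dB = des$concsB,
                      KEEP.OUT.ATTRS = FALSE)

  # deterministic additive surfaces per unordered slope pair
  surf_true <- vector("list", k * k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j < i) { surf_true[[(i - 1) * k + j]] <-
        surf_true[[(j - 1) * k + i]]; next }
    spec <- additive_pair(compounds[[i]], compounds[[j]])
    surf_true[[(i - 1) * k + j]] <- loewe_effect(spec, grid$dA, grid$dB)
  }
  truth <- function(i, j) surf_true[[(i - 1) * k + j]]

  single_true <- lapply(compounds, function(p) hill_effect(p, des$singleA))
  fit_one <- function(i) {
    y <- single_true[[i]] + stats::rnorm(length(des$singleA), 0,
                                         config$noise_sd)
    fit_hill_ls(dose_response_data(des$singleA, y),
                fix_bounds = c(config$e0, config$ef))
  }
  noisy_grid <- function(i, j)
    truth(i, j) + stats::rnorm(nrow(grid), 0, config$noise_sd)

  cal_idx <- switch(config$calibration,
    all = seq_len(k),
    low = which(slopes <= 2),
    high = which(slopes >= 2.5))

  syn <- matrix(0L, k, k); ant <- matrix(0L, k, k)
  chk_template <- data.frame(dA = grid$dA, dB = grid$dB, response = 0)
  for (s in seq_len(config$n_screens)) {
    vols_cal <- unlist(lapply(cal_idx, function(i) {
      vapply(seq_len(config$calibration_reps), function(r) {
        fA <- fit_one(i); fB <- fit_one(i)
        chk <- chk_template; chk$response <- noisy_grid(i, i)
        bliss_volume(chk, fA, fB)
      }, numeric(1))
    }))
    th <- stats::quantile(vols_cal, c(0.025, 0.975), names = FALSE)
    fitsA <- lapply(seq_len(k), fit_one)
    fitsB <- lapply(seq_len(k), fit_one)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      chk <- chk_template; chk$response <- noisy_grid(i, j)
      v <- bliss_volume(chk, fitsA[[i]], fitsB[[j]])
      if (v > th[2]) syn[i, j] <- syn[i, j] + 1L
      else if (v < th[1]) ant[i, j] <- ant[i, j] + 1L
    }
  }
  idx <- expand.grid(i = seq_len(k), j = seq_len(k))
  data.frame(
    slopeA = slopes[idx$i], slopeB = slopes[idx$j],
    slope_product = slopes[idx$i] * slopes[idx$j],
    n_synergistic = syn[cbind(idx$i, idx$j)],
    n_antagonistic = ant[cbind(idx$i, idx$j)],
    pct_synergistic = 100 * syn[cbind(idx$i, idx$j)] / config$n_screens,
    pct_antagonistic = 100 * ant[cbind(idx$i, idx$j)] / config$n_screens,
    n_screens = config$n_screens)
}

#' Pooled non-additive call rate over slope-product cells
#'
#' Aggregates a [run_bliss_screen_sim()] table over the combination cells
#' whose Hill-slope product satisfies a condition, pooling screens and
#' cells.
#'
#' @param bias_table result of [run_bliss_screen_sim()].
#' @param product_min,product_max open bounds on the slope product
#'   (`NULL` = unbounded).
#' @return named numeric: `pct_synergistic`, `pct_antagonistic`, `n_cells`.
#' @export
bliss_call_rate <- function(bias_table, product_min = NULL,
                            product_max = NULL) {
  keep <- rep(TRUE, nrow(bias_table))
  if (!is.null(product_min)) keep <- keep & bias_table$slope_product > product_min
  if (!is.null(product_max)) keep <- keep & bias_table$slope_product < product_max
  tb <- bias_table[keep, ]
  n <- sum(tb$n_screens)
  c(pct_synergistic = 100 * sum(tb$n_synergistic) / n,
    pct_antagonistic = 100 * sum(tb$n_antagonistic) / n,
    n_cells = nrow(tb))
}
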