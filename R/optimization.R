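#' Balanced sensitivity/specificity objective
#'
#' `2 - ((sensitivity + specificity) - |sensitivity - specificity|)`,
#' minimal (0) when both are 1, maximal (2) when either is 0; equivalently
#' `2 - 2 * min(sensitivity, specificity)`, so minimising it maximises the
#' worse of the two rates.
#'
#' @param sensitivity,specificity Rates in `[0, 1]`.
#' @return Objective values in `[0, 2]`.
#' @export
objective_value <- function(sensitivity, specificity) {
  2 - ((sensitivity + specificity) - abs(sensitivity - specificity))
}

#' Differential-evolution control parameters
#'
#' @param population_size Members per generation (>= 4).
#' @param max_generations Generations to run.
#' @param F Differential weight (mutation scale).
#' @param CR Crossover probability.
#' @param seed Integer seed; the run is deterministic given the seed.
#' @param convergence_tolerance Stop early once the population's objective
#'   spread (max - min) falls to this value or below; 0 disables early
#'   stopping in practice for noisy landscapes.
#' @return A list of class `de_control`.
#' @export
de_control <- function(population_size = 15, max_generations = 30,
                       F = 0.7, CR = 0.9, seed = 1,
                       convergence_tolerance = 0) {
  if (population_size < 4) {
    abort("population_size must be at least 4", class = "trnascore_bad_config")
  }
  if (max_generations < 1) {
    abort("max_generations must be positive", class = "trnascore_bad_config")
  }
  structure(list(population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 F = F, CR = CR, seed = as.integer(seed),
                 convergence_tolerance = convergence_tolerance),
            class = "de_control")
}

#' Differential-evolution minimiser (rand/1/bin)
#'
#' Classic DE: each generation, every member i receives a mutant
#' `a + F * (b - c)` built from three distinct random other members,
#' clipped to the bounds, recombined by binomial crossover (rate `CR`, one
#' coordinate forced from the mutant), and replaces i only if its objective
#' is no worse (greedy selection). Deterministic given `control$seed`.
#'
#' @param fn Objective function taking a numeric vector, returning a scalar.
#' @param lower,upper Bound vectors (equal length, `lower < upper`).
#' @param control A [de_control()] object.
#' @return A list of class `de_result`: `par`, `value`, `trace` (tibble
#'   with `generation`, `best_objective`, non-increasing), `control`.
#' @export
de_optimize <- function(fn, lower, upper, control = de_control()) {
  d <- length(lower)
  if (length(upper) != d || any(!is.finite(lower)) || any(!is.finite(upper)) ||
        any(lower >= upper)) {
    abort("invalid bounds: need finite lower < upper",
          class = "trnascore_bad_config")
  }
  np <- control$population_size
  set.seed(control$seed)

  pop <- matrix(runif(np * d, rep(lower, each = np), rep(upper, each = np)),
                nrow = np, ncol = d)
  fit <- apply(pop, 1, fn)
  trace <- numeric(control$max_generations)

  for (gen in seq_len(control$max_generations)) {
    for (i in seq_len(np)) {
      abc <- sample(setdiff(seq_len(np), i), 3)
      mutant <- pop[abc[1], ] + control$F * (pop[abc[2], ] - pop[abc[3], ])
      mutant <- clamp(mutant, lower, upper)
      jrand <- sample.int(d, 1)
      cross <- runif(d) < control$CR
      cross[jrand] <- TRUE
      trial <- ifelse(cross, mutant, pop[i, ])
      f_trial <- fn(trial)
      if (f_trial <= fit[i]) {
        pop[i, ] <- trial
        fit[i] <- f_trial
      }
    }
    trace[gen] <- min(fit)
    if (max(fit) - min(fit) <= control$convergence_tolerance) {
      trace <- trace[seq_len(gen)]
      break
    }
  }

  best <- which.min(fit)
  structure(list(par = pop[best, ], value = fit[best],
                 trace = tibble::tibble(generation = seq_along(trace),
                                        best_objective = trace),
                 control = control),
            class = "de_result")
}

#' Default scaling-factor bounds for tuning
#'
#' `(0, 20)` for the positive factors and `(-5, 20)` for `var_hx_scal`
#' (allowing the benign-rewarding branch to flip sign).
#'
#' @return A tibble with `factor`, `lower`, `upper`.
#' @export
default_factor_bounds <- function() {
  tibble::tibble(
    factor = factor_names(),
    lower = c(-5, 0, 0, 0, 0, 0),
    upper = rep(20, 6)
  ) |>
    dplyr::mutate(lower = dplyr::if_else(
      .data$factor %in% c("var_hx_cons_scal", "SS_scal", "Pos_scal"),
      1e-6, .data$lower))
}

#' Build the take-one-out evaluation design
#'
#' Caches, for each labelled variant, the factor-independent pieces of its
#' take-one-out score (conservation, steric score, adjusted slot component
#' means), so the balanced objective can be re-evaluated for arbitrary
#' scaling factors without touching the score table again.
#'
#' @param scores A `trna_scores` table (any factors).
#' @param labels A data frame with `position`, `ref`, `alt`, `label`
#'   (`"pathogenic"` / `"benign"`), both labels present.
#' @return A list of class `loo_design`.
#' @export
loo_design <- function(scores, labels) {
  labels <- tibble::as_tibble(labels)
  stopifnot(all(c("position", "ref", "alt", "label") %in% names(labels)))
  if (length(unique(labels$label)) < 2) {
    abort("labels must include both classes",
          class = "trnascore_degenerate_labels")
  }
  hit <- labels |>
    dplyr::left_join(
      scores |>
        dplyr::select("position", "ref", "alt", "cons_score",
                      "hist_component", "novel_component",
                      "secondary_structure_score",
                      dplyr::starts_with("slot_")),
      by = c("position", "ref", "alt")
    )
  if (any(is.na(hit$slot_n_positions))) {
    abort("labelled variant(s) missing from the score table",
          class = "trnascore_evaluation")
  }
  m4 <- 4 * hit$slot_n_positions
  structure(list(
    label = hit$label,
    cons = hit$cons_score,
    ss = hit$secondary_structure_score,
    slot_hist = hit$slot_hist_mean - hit$hist_component / m4,
    slot_novel = hit$slot_novel_mean + (1 - hit$novel_component) / m4,
    slot_cons = hit$slot_cons_mean
  ), class = "loo_design")
}

# Take-one-out totals for all labelled variants under candidate factors.
loo_design_scores <- function(design, factors) {
  f <- factors
  vhc <- f$cons_scal * design$cons + f$base_scal
  pos <- f$var_hx_scal * design$slot_hist +
    f$cons_scal * design$slot_cons +
    f$base_scal * design$slot_novel
  f$var_hx_cons_scal * vhc + f$Pos_scal * pos + f$SS_scal * design$ss
}

#' Balanced objective of a factor vector under take-one-out evaluation
#'
#' Runs the full take-one-out sweep under the candidate factors and returns
#' [objective_value()] at the crossover threshold.
#'
#' @param factors A [scaling_factors()] object (or coercible vector).
#' @param design A [loo_design()] object.
#' @return Scalar objective in `[0, 2]`.
#' @export
loo_objective <- function(factors, design) {
  factors <- as_scaling_factors(factors)
  sw <- sweep_thresholds(
    tibble::tibble(total_score = loo_design_scores(design, factors),
                   label = design$label)
  )
  objective_value(attr(sw, "sensitivity_at_crossover"),
                  attr(sw, "specificity_at_crossover"))
}

#' Tune the six scaling factors by differential evolution
#'
#' Minimises the balanced take-one-out objective over the scaling factors
#' within `bounds` using [de_optimize()].
#'
#' @param scores A `trna_scores` table.
#' @param labels Labelled reference variants (see [loo_design()]).
#' @param control A [de_control()] object.
#' @param bounds A bounds tibble as from [default_factor_bounds()].
#' @return A list of class `trna_tuning`: `factors` (a
#'   [scaling_factors()]), `objective`, `sweep` (the take-one-out sweep at
#'   the tuned factors), `trace`, `seed`.
#' @export
tune_scaling_factors <- function(scores, labels, control = de_control(),
                                 bounds = default_factor_bounds()) {
  design <- loo_design(scores, labels)
  bounds <- bounds[match(factor_names(), bounds$factor), ]
  if (any(is.na(bounds$lower)) || any(bounds$lower >= bounds$upper)) {
    abort("invalid factor bounds", class = "trnascore_bad_config")
  }
  raw_objective <- function(x) {
    f <- setNames(as.list(x), factor_names())
    loo_objective_raw(f, design)
  }
  fit <- de_optimize(raw_objective, bounds$lower, bounds$upper, control)
  factors <- as_scaling_factors(setNames(fit$par, factor_names()))
  sw <- sweep_thresholds(
    tibble::tibble(total_score = loo_design_scores(design, factors),
                   label = design$label)
  )
  structure(list(factors = factors, objective = fit$value, sweep = sw,
                 trace = fit$trace, seed = control$seed, control = control),
            class = "trna_tuning")
}

# As loo_objective but without scaling_factors validation, so DE may probe
# boundary values of the positive factors freely.
loo_objective_raw <- function(f, design) {
  sw <- sweep_thresholds(
    tibble::tibble(total_score = loo_design_scores(design, f),
                   label = design$label)
  )
  objective_value(attr(sw, "sensitivity_at_crossover"),
                  attr(sw, "specificity_at_crossover"))
}

#' Run the tuner for several seeds and select the best run
#'
#' Differential evolution is stochastic: different seeds reach different
#' near-optimal factor vectors. This mirrors the usual practice of running
#' several optimisations and keeping the lowest objective (ties to the
#' first seed).
#'
#' @param scores,labels,bounds As in [tune_scaling_factors()].
#' @param seeds Integer vector of seeds.
#' @param control Base [de_control()]; its seed is replaced per run.
#' @return A list: `runs` (tibble, one row per seed with objective,
#'   sensitivity, specificity, crossover and factor columns, plus
#'   `selected`), `best` (the selected `trna_tuning`).
#' @export
tune_scaling_factors_multi <- function(scores, labels, seeds,
                                       control = de_control(),
                                       bounds = default_factor_bounds()) {
  if (length(seeds) == 0) {
    abort("at least one seed is required", class = "trnascore_bad_config")
  }
  fits <- purrr::map(seeds, function(s) {
    ctl <- control
    ctl$seed <- as.integer(s)
    tune_scaling_factors(scores, labels, ctl, bounds)
  })
  runs <- purrr::map2_dfr(fits, seeds, function(fit, s) {
    g <- glance(fit$sweep)
    tibble::tibble(seed = as.integer(s), objective = fit$objective,
                   sensitivity = g$sensitivity, specificity = g$specificity,
                   crossover_threshold = g$crossover_threshold) |>
      dplyr::bind_cols(tibble::as_tibble(unclass(fit$factors)))
  })
  best_i <- which.min(runs$objective)
  runs$selected <- seq_len(nrow(runs)) == best_i
  list(runs = runs, best = fits[[best_i]])
}

#' @export
print.trna_tuning <- function(x, ...) {
  g <- glance(x)
  cat("<trna_tuning> seed", x$seed, "\n")
  cat(sprintf("  objective %.4f  sensitivity %.3f  specificity %.3f  crossover %.3f\n",
              g$objective, g$sensitivity, g$specificity,
              g$crossover_threshold))
  print(x$factors)
  invisible(x)
}

#' @rdname tune_scaling_factors
#' @param x A `trna_tuning` object.
#' @param ... Unused.
#' @export
glance.trna_tuning <- function(x, ...) {
  g <- glance(x$sweep)
  tibble::tibble(seed = x$seed, objective = x$objective,
                 sensitivity = g$sensitivity, specificity = g$specificity,
                 crossover_threshold = g$crossover_threshold,
                 crossover_value = g$crossover_value) |>
    dplyr::bind_cols(tibble::as_tibble(unclass(x$factors)))
}

#' @rdname tune_scaling_factors
#' @export
tidy.trna_tuning <- function(x, ...) {
  x$trace
}
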