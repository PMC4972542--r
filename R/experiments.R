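#' Specify a concentration sweep
#'
#' A sweep crosses population configurations with odor concentrations. For
#' each (configuration, concentration, panel) cell, a fresh odor panel is
#' generated, all trials are simulated to steady state, and the half-split
#' decoding accuracy is recorded; the panel is the statistical unit. Panels
#' and their noisy trials are shared across configurations within a cell so
#' that configurations are compared on identical inputs.
#'
#' @param n_odors Panel size (8 or 32 in the headline experiments).
#' @param concentrations Percent of maximum concentration, each in (0, 100];
#'   percent `c` maps to presentation intensity `10 * c` on the 0-1000 scale.
#' @param n_panels Panel replicates per concentration (>= 2).
#' @param n_trials Trials per panel (default 2000).
#' @param configurations Character vector of [bulb_config()] names.
#' @param seed Root seed; all randomness derives from it via [child_seed()].
#' @param sigmoid_mode `"type"` or `"common"` (see [bulb_config()]).
#' @param inhibition_kind Optional override for the MC/TC configurations
#'   (e.g. `"none"` for the sigmoid-differences-only variant).
#' @param target_drop Gate-center calibration drop in Hz.
#' @param classifier `"gnb"` or `"lda"`.
#' @param freeze_connectivity If `TRUE`, one adjacency realization per
#'   configuration is reused across panels; default draws a fresh one per
#'   panel.
#' @param n_glomeruli,dt,tol,max_steps Model and integration controls.
#' @return A `sweep_spec` object.
#' @export
sweep_spec <- function(n_odors = 32L,
                       concentrations = seq(10, 100, by = 10),
                       n_panels = 100L, n_trials = 2000L,
                       configurations = c("TC", "MC", "none"),
                       seed = 1L,
                       sigmoid_mode = c("type", "common"),
                       inhibition_kind = NULL,
                       target_drop = 15,
                       classifier = c("gnb", "lda"),
                       freeze_connectivity = FALSE,
                       n_glomeruli = 150L,
                       dt = 0.4, tol = 1e-4, max_steps = 2000L) {
  sigmoid_mode <- match.arg(sigmoid_mode)
  classifier <- match.arg(classifier)
  stopifnot(all(concentrations > 0 & concentrations <= 100),
            n_panels >= 2L, n_odors >= 2L, n_trials >= 2L * n_odors)
  structure(list(
    n_odors = as.integer(n_odors), concentrations = concentrations,
    n_panels = as.integer(n_panels), n_trials = as.integer(n_trials),
    configurations = configurations, seed = as.integer(seed),
    sigmoid_mode = sigmoid_mode, inhibition_kind = inhibition_kind,
    target_drop = target_drop, classifier = classifier,
    freeze_connectivity = isTRUE(freeze_connectivity),
    n_glomeruli = as.integer(n_glomeruli),
    dt = dt, tol = tol, max_steps = as.integer(max_steps)
  ), class = "sweep_spec")
}

#' Run a concentration sweep
#'
#' @param spec A [sweep_spec()].
#' @param verbose Emit a progress message per panel.
#' @return A `sweep_result`: a data frame with one row per (configuration,
#'   concentration, panel) holding `accuracy` (fraction correct), plus
#'   convergence diagnostics. Rows for cells whose simulation failed carry
#'   `NA` accuracy and the error text in `note`. The resolved spec is
#'   attached as `attr(result, "spec")`.
#' @export
run_sweep <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  rows <- list()
  r <- 0L
  for (ci in seq_along(spec$concentrations)) {
    conc <- spec$concentrations[ci]
    ipres <- 10 * conc
    for (pi in seq_len(spec$n_panels)) {
      pseed <- child_seed(spec$seed, "panel", ci, pi)
      base <- make_base_odor(grid_spec(), ipres,
                             seed = child_seed(pseed, "make"))
      panel <- derive_similar_odors(base, spec$n_odors,
                                    seed = child_seed(pseed, "derive"))
      labs <- balanced_labels(spec$n_odors, spec$n_trials,
                              child_seed(pseed, "labels"))
      x <- sample_trials(panel, labs, seed = child_seed(pseed, "noise"))
      for (cfg_name in spec$configurations) {
        r <- r + 1L
        cseed <- if (spec$freeze_connectivity) {
          child_seed(spec$seed, "conn", cfg_name)
        } else {
          child_seed(pseed, "conn", cfg_name)
        }
        rows[[r]] <- tryCatch({
          cfg <- bulb_config(cfg_name, n_glomeruli = spec$n_glomeruli,
                             sigmoid_mode = spec$sigmoid_mode,
                             inhibition_kind = spec$inhibition_kind,
                             target_drop = spec$target_drop,
                             connectivity_seed = cseed)
          sim <- simulate_trials(x, cfg, dt = spec$dt, tol = spec$tol,
                                 max_steps = spec$max_steps)
          acc <- decode_accuracy(t(sim$rates), labs,
                                 split_seed = child_seed(pseed, "split"),
                                 classifier = spec$classifier)
          data.frame(configuration = cfg_name, concentration = conc,
                     panel = pi, accuracy = acc, converged = sim$converged,
                     steps = sim$steps, note = "",
                     stringsAsFactors = FALSE)
        }, error = function(e) {
          data.frame(configuration = cfg_name, concentration = conc,
                     panel = pi, accuracy = NA_real_, converged = NA,
                     steps = NA_integer_, note = conditionMessage(e),
                     stringsAsFactors = FALSE)
        })
      }
      if (verbose) {
        message(sprintf("concentration %g%%: panel %d/%d done",
                        conc, pi, spec$n_panels))
      }
    }
  }
  res <- do.call(rbind, rows)
  attr(res, "spec") <- spec
  class(res) <- c("sweep_result", class(res))
  res
}

#' Run the dual-output-neuron sweep
#'
#' Variant where each glomerulus drives two output neurons (300 units on the
#' default grid). Validates that only the dual configurations `"MC-MC"`,
#' `"TC-TC"`, `"MC-TC"` are requested, then delegates to [run_sweep()]; the
#' dual connectivity rules (type-segregated inhibition, no edges between the
#' two units of one glomerulus) are enforced by [bulb_config()], and the
#' classifier sees all units as features.
#'
#' @inheritParams run_sweep
#' @export
dual_cell_configurations <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  if (!all(spec$configurations %in% c("MC-MC", "TC-TC", "MC-TC"))) {
    stop("dual sweeps accept only the MC-MC, TC-TC and MC-TC configurations")
  }
  run_sweep(spec, verbose = verbose)
}

#' Per-concentration significance of configuration differences
#'
#' At each concentration, a one-way ANOVA compares panel accuracies across
#' configurations; its p-value is Bonferroni-corrected by the number of
#' concentrations tested. Where the corrected ANOVA is significant, pairwise
#' Welch t-tests (two-tailed) check whether the best-scoring configuration
#' beats each of the others; `best_significant` is `TRUE` only if it does on
#' every comparison.
#'
#' @param result A `sweep_result` (or any data frame with `configuration`,
#'   `concentration`, `accuracy`).
#' @param alpha Significance level for both stages.
#' @return Data frame with one row per concentration: `p_anova`, `p_adj`,
#'   `significant`, `best`, `best_significant`, `max_p_posthoc`, `note`
#'   (non-empty when a degenerate cell was skipped).
#' @export
significance <- function(result, alpha = 0.05) {
  d0 <- result[!is.na(result$accuracy), , drop = FALSE]
  concs <- sort(unique(d0$concentration))
  n_conc <- length(concs)
  out <- lapply(concs, function(cc) {
    d <- d0[d0$concentration == cc, , drop = FALSE]
    d$configuration <- factor(d$configuration)
    row <- data.frame(concentration = cc,
                      p_anova = NA_real_, p_adj = NA_real_,
                      significant = FALSE, best = NA_character_,
                      best_significant = FALSE, max_p_posthoc = NA_real_,
                      note = "", stringsAsFactors = FALSE)
    if (nlevels(d$configuration) < 2L || min(table(d$configuration)) < 2L) {
      row$note <- "fewer than 2 configurations or 2 panels"
      return(row)
    }
    if (stats::var(d$accuracy) == 0) {
      # all accuracies identical: nothing to flag
      row$p_anova <- 1
      row$p_adj <- 1
      row$note <- "degenerate: zero variance"
      return(row)
    }
    p <- tryCatch({
      fit <- stats::aov(accuracy ~ configuration, data = d)
      summary(fit)[[1]][["Pr(>F)"]][1]
    }, error = function(e) NA_real_)
    if (!is.finite(p)) {
      row$note <- "ANOVA undefined"
      return(row)
    }
    row$p_anova <- p
    row$p_adj <- min(1, p * n_conc)
    row$significant <- row$p_adj < alpha
    means <- tapply(d$accuracy, d$configuration, mean)
    best <- names(which.max(means))
    row$best <- best
    if (row$significant) {
      others <- setdiff(levels(d$configuration), best)
      ph <- vapply(others, function(o) {
        a <- d$accuracy[d$configuration == best]
        b <- d$accuracy[d$configuration == o]
        if (stats::sd(a) == 0 && stats::sd(b) == 0) {
          return(if (mean(a) == mean(b)) 1 else 0)
        }
        stats::t.test(a, b)$p.value
      }, numeric(1))
      row$max_p_posthoc <- max(ph)
      row$best_significant <- all(ph < alpha) &&
        all(means[best] > means[others])
    }
    row
  })
  do.call(rbind, out)
}

#' Compare mean-over-concentration accuracies between configurations
#'
#' Pools each configuration's panel accuracies across all concentrations in
#' the sweep and runs two-tailed Welch t-tests of a target configuration
#' against each competitor (used for the mixed mitral-tufted population
#' comparison).
#'
#' @param result A `sweep_result`.
#' @param target Configuration of interest (e.g. `"MC-TC"`).
#' @param others Competitors; default all other configurations present.
#' @return Data frame with one row per competitor: mean accuracies, their
#'   difference, and the Welch p-value.
#' @export
compare_mean_accuracy <- function(result, target,
                                  others = setdiff(unique(result$configuration),
                                                   target)) {
  d <- result[!is.na(result$accuracy), , drop = FALSE]
  stopifnot(target %in% d$configuration, length(others) >= 1L)
  a <- d$accuracy[d$configuration == target]
  out <- lapply(others, function(o) {
    b <- d$accuracy[d$configuration == o]
    data.frame(target = target, other = o,
               mean_target = mean(a), mean_other = mean(b),
               difference = mean(a) - mean(b),
               p_value = stats::t.test(a, b)$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Summarize a sweep as mean and s.e.m. per cell
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return Data frame with `configuration`, `concentration`, `n`,
#'   `mean_accuracy`, `sem`, and the fraction of converged simulations.
#' @export
summary.sweep_result <- function(object, ...) {
  d <- object[!is.na(object$accuracy), , drop = FALSE]
  key <- interaction(d$configuration, d$concentration, drop = TRUE)
  out <- do.call(rbind, lapply(split(d, key), function(g) {
    data.frame(configuration = g$configuration[1],
               concentration = g$concentration[1],
               n = nrow(g),
               mean_accuracy = mean(g$accuracy),
               sem = stats::sd(g$accuracy) / sqrt(nrow(g)),
               frac_converged = mean(g$converged),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$configuration, out$concentration), ]
  rownames(out) <- NULL
  out
}
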