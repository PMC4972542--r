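#' Input sigmoid parameters
#'
#' Glomerular input intensity (0-1000) is translated into an excitatory drive
#' (Hz) by a logistic sigmoid saturating at `max_rate`. Tufted cells have a
#' steeper slope and lower midpoint than mitral cells, reflecting their
#' stronger sensory input and higher intrinsic excitability.
#'
#' @param slope Sigmoid slope (1/intensity units); > 0.
#' @param midpoint Intensity at half-maximal drive; in (0, 1000).
#' @param max_rate Saturation rate in Hz (default 100).
#' @return A `sigmoid_params` object.
#' @export
sigmoid_params <- function(slope, midpoint, max_rate = 100) {
  stopifnot(slope > 0, midpoint > 0, midpoint < 1000, max_rate > 0)
  structure(list(slope = slope, midpoint = midpoint, max_rate = max_rate),
            class = "sigmoid_params")
}

#' @rdname sigmoid_params
#' @export
mc_sigmoid <- function() sigmoid_params(0.007, 500)

#' @rdname sigmoid_params
#' @export
tc_sigmoid <- function() sigmoid_params(0.01, 350)

#' Type-neutral sigmoid for single-difference model variants
#'
#' When the model variant under study differs only in its inhibition (the
#' activity-dependent gate, or subtractive/divisive controls), all
#' populations share one input sigmoid so that inhibition is the only moving
#' part. Its slope and midpoint are the midpoints of the mitral and tufted
#' values.
#' @export
common_sigmoid <- function() sigmoid_params(0.0085, 425)

#' Excitatory drive from glomerular input
#'
#' `max_rate / (1 + exp(-slope * (intensity - midpoint)))`; strictly
#' increasing in intensity.
#'
#' @param intensity Input intensity (vectorized).
#' @param p A [sigmoid_params()].
#' @return Drive in Hz.
#' @export
input_drive <- function(intensity, p) {
  stopifnot(inherits(p, "sigmoid_params"), all(is.finite(intensity)))
  p$max_rate / (1 + exp(-p$slope * (intensity - p$midpoint)))
}

# mean drive over a uniform 0-1000 input; the reference sender rate used by
# the gain calibration
.uniform_mean_rate <- function(p) {
  mean(input_drive(seq(0, 1000, by = 5), p))
}

#' Lateral inhibition parameters
#'
#' Four inhibition models. Activity-dependent lateral inhibition (`"adli"`)
#' multiplies the summed presynaptic rate `u` by a Gaussian gate on the
#' postsynaptic rate `v`: `gi * u * exp(-(v - mu)^2 / sigma)`, so only cells
#' firing within a band around `mu` are inhibited. The tufted-cell gate is
#' centered at low rates (`mu = 10`, `sigma = 350` Hz^2) and the mitral gate
#' at intermediate rates (`mu = 50`, `sigma = 500` Hz^2). Activity-independent
#' controls: `"subtractive"` (`gi * u`), `"divisive"` (`gi * v` as printed;
#' the network-dependent variant `gi * u * v` is available via
#' `network_divisive = TRUE`), and `"none"`.
#'
#' @param kind One of `"adli"`, `"subtractive"`, `"divisive"`, `"none"`.
#' @param gi Inhibitory gain; >= 0.
#' @param mu Gate center in Hz (adli only).
#' @param sigma Squared gate width in Hz^2 (adli only); > 0.
#' @param network_divisive If `TRUE`, divisive inhibition is `gi * u * v`.
#' @return An `inhibition_params` object.
#' @export
inhibition_params <- function(kind = c("adli", "subtractive", "divisive", "none"),
                              gi = 0, mu = NA_real_, sigma = NA_real_,
                              network_divisive = FALSE) {
  kind <- match.arg(kind)
  stopifnot(gi >= 0)
  if (kind == "adli") stopifnot(is.finite(mu), is.finite(sigma), sigma > 0)
  structure(list(kind = kind, gi = gi, mu = mu, sigma = sigma,
                 network_divisive = isTRUE(network_divisive)),
            class = "inhibition_params")
}

#' @rdname inhibition_params
#' @param gi Inhibitory gain.
#' @export
tc_adli <- function(gi) inhibition_params("adli", gi = gi, mu = 10, sigma = 350)

#' @rdname inhibition_params
#' @export
mc_adli <- function(gi) inhibition_params("adli", gi = gi, mu = 50, sigma = 500)

#' Instantaneous inhibitory rate decrement
#'
#' @param v Postsynaptic rate(s), Hz; >= 0.
#' @param u Summed presynaptic rate(s), Hz; >= 0.
#' @param p An [inhibition_params()].
#' @return Rate decrement in Hz (same shape as `v`).
#' @export
inhibition_term <- function(v, u, p) {
  stopifnot(inherits(p, "inhibition_params"))
  switch(p$kind,
    adli = p$gi * u * exp(-(v - p$mu)^2 / p$sigma),
    subtractive = p$gi * u,
    divisive = if (p$network_divisive) p$gi * u * v else p$gi * v,
    none = 0 * v
  )
}

#' Single-cell rate dynamics constants
#'
#' `tau * dv/dt = stim - gl * (v - El) - inhib`, integrated by forward Euler
#' and clipped at `rate_floor`. Time is in units of the membrane-like
#' constant `tau`; with `gl = 1`, `El = 0` the uninhibited steady state
#' equals the sigmoid drive, so concentration maps directly onto output rate.
#'
#' @param tau Relaxation time constant (arbitrary units); > 0.
#' @param gl Leak gain; >= 0.
#' @param El Leak reversal in rate units.
#' @param rate_floor Lower clip for rates (Hz).
#' @return A `cell_dynamics` object.
#' @export
cell_dynamics <- function(tau = 1, gl = 1, El = 0, rate_floor = 0) {
  stopifnot(tau > 0, gl >= 0)
  structure(list(tau = tau, gl = gl, El = El, rate_floor = rate_floor),
            class = "cell_dynamics")
}

#' Random lateral connectivity
#'
#' Directed receiver x sender adjacency. Each eligible edge is an independent
#' Bernoulli draw with the receiver's connection fraction (0.75 for mitral,
#' 0.60 for tufted cells, reflecting the shorter lateral dendrites of tufted
#' cells). Self-connections are never allowed; optionally, units of different
#' types never connect (inhibition segregated by pathway) and units sharing a
#' glomerulus never connect (sister cells do not inhibit one another).
#'
#' @param cell_type Character vector, one entry per unit.
#' @param glomerulus Integer vector mapping each unit to its input pixel.
#' @param fraction Named numeric (by cell type) or scalar connection
#'   probability per receiver.
#' @param seed Integer seed.
#' @param segregate_by_type,exclude_same_glomerulus Eligibility rules.
#' @return A 0/1 numeric matrix `A` with `A[i, j] = 1` iff unit `i` receives
#'   from unit `j`.
#' @export
make_connectivity <- function(cell_type, glomerulus, fraction, seed = 1L,
                              segregate_by_type = TRUE,
                              exclude_same_glomerulus = TRUE) {
  n <- length(cell_type)
  stopifnot(length(glomerulus) == n, n >= 2L)
  frac <- if (length(fraction) == 1L && is.null(names(fraction))) {
    rep(fraction, n)
  } else {
    unname(fraction[cell_type])
  }
  stopifnot(all(frac >= 0 & frac <= 1))
  set.seed(child_seed(seed, "connectivity"))
  A <- matrix(as.numeric(stats::runif(n * n) < frac), n, n) # recycles by row
  diag(A) <- 0
  if (segregate_by_type) {
    A[outer(cell_type, cell_type, `!=`)] <- 0
  }
  if (exclude_same_glomerulus) {
    same <- outer(glomerulus, glomerulus, `==`)
    diag(same) <- FALSE
    A[same] <- 0
  }
  A
}

#' Assemble a population configuration
#'
#' Low-level constructor; most users will call [bulb_config()]. Sigmoid and
#' inhibition parameters are supplied per cell type and expanded to per-unit
#' vectors. All units must share one inhibition kind (the types may differ in
#' gate center/width/gain).
#'
#' @param cell_type Character vector per unit.
#' @param glomerulus Integer vector mapping units to input pixels.
#' @param sigmoid Named list of [sigmoid_params()] keyed by cell type.
#' @param inhibition Named list of [inhibition_params()] keyed by cell type.
#' @param dynamics A [cell_dynamics()].
#' @param connectivity Adjacency matrix from [make_connectivity()].
#' @return A `population_config` object.
#' @export
population_config <- function(cell_type, glomerulus, sigmoid, inhibition,
                              dynamics = cell_dynamics(), connectivity) {
  n <- length(cell_type)
  stopifnot(length(glomerulus) == n,
            is.matrix(connectivity), all(dim(connectivity) == n),
            all(diag(connectivity) == 0),
            inherits(dynamics, "cell_dynamics"))
  types <- unique(cell_type)
  stopifnot(all(types %in% names(sigmoid)), all(types %in% names(inhibition)))
  kinds <- unique(vapply(inhibition[types], `[[`, "", "kind"))
  if (length(kinds) != 1L) stop("all units must share one inhibition kind")
  pick <- function(lst, field) {
    vapply(cell_type, function(ty) {
      v <- lst[[ty]][[field]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1), USE.NAMES = FALSE)
  }
  structure(list(
    n_units = n,
    cell_type = cell_type,
    glomerulus = as.integer(glomerulus),
    slope = pick(sigmoid, "slope"),
    midpoint = pick(sigmoid, "midpoint"),
    max_rate = pick(sigmoid, "max_rate"),
    kind = kinds,
    gi = pick(inhibition, "gi"),
    mu = pick(inhibition, "mu"),
    sigma = pick(inhibition, "sigma"),
    network_divisive = any(vapply(inhibition[types], `[[`, TRUE,
                                  "network_divisive")),
    dynamics = dynamics,
    adjacency = connectivity
  ), class = "population_config")
}

# calibrated ADLI/subtractive gain: a cell sitting at its gate center should
# lose ~target_drop Hz when its presynaptic pool fires at the mean rate
# evoked by uniform input
.calibrated_gain <- function(target_drop, expected_in_degree, sender_sigmoid) {
  target_drop / (expected_in_degree * .uniform_mean_rate(sender_sigmoid))
}

#' Build a named olfactory-bulb model configuration
#'
#' Convenience constructor for the configurations compared in the sweeps.
#' Single-population models place one unit on each glomerulus:
#' `"TC"` / `"MC"` (activity-dependent gates at 10 / 50 Hz), `"none"`,
#' `"subtractive"`, `"divisive"` (type-neutral controls). Dual models place
#' two units on each glomerulus: `"MC-MC"`, `"TC-TC"`, `"MC-TC"`; inhibition
#' is segregated by type and sister units sharing a glomerulus never inhibit
#' one another.
#'
#' With `sigmoid_mode = "type"`, mitral/tufted units use their own sigmoids
#' and connection fractions (0.75 / 0.60); with `"common"` every unit shares
#' [common_sigmoid()] and fraction 0.75, isolating inhibition as the only
#' difference between configurations.
#'
#' Inhibitory gains are calibrated at build time so that a unit at its gate
#' center loses about `target_drop` Hz (default 15 Hz, matching the visible
#' rate decreases in the model and the experimental ~10-20 Hz scale):
#' `gi = target_drop / (expected in-degree x mean sender rate under uniform
#' input)`. Pass `gains` to override.
#'
#' @param name Configuration name (see above).
#' @param n_glomeruli Number of input pixels (default 150).
#' @param sigmoid_mode `"type"` or `"common"`.
#' @param inhibition_kind Override for the MC/TC(-dual) configurations, e.g.
#'   `"none"` for the sigmoid-differences-only variant. Ignored for the
#'   control configurations, whose name fixes their kind.
#' @param target_drop Gate-center rate decrease used to calibrate `gi` (Hz).
#' @param gains Optional named numeric of explicit `gi` values by cell type
#'   (or a scalar).
#' @param connectivity_seed Seed for the random adjacency.
#' @param network_divisive Use the `gi * u * v` divisive variant.
#' @return A `population_config`.
#' @export
bulb_config <- function(name, n_glomeruli = 150L,
                        sigmoid_mode = c("type", "common"),
                        inhibition_kind = NULL, target_drop = 15,
                        gains = NULL, connectivity_seed = 1L,
                        network_divisive = FALSE) {
  sigmoid_mode <- match.arg(sigmoid_mode)
  valid <- c("TC", "MC", "none", "subtractive", "divisive",
             "MC-MC", "TC-TC", "MC-TC")
  if (!name %in% valid) {
    stop("unknown configuration `", name, "`; expected one of: ",
         paste(valid, collapse = ", "))
  }
  n_glomeruli <- as.integer(n_glomeruli)
  dual <- name %in% c("MC-MC", "TC-TC", "MC-TC")
  cell_type <- switch(name,
    "TC" = rep("TC", n_glomeruli),
    "MC" = rep("MC", n_glomeruli),
    "none" = , "subtractive" = , "divisive" = rep("G", n_glomeruli),
    "MC-MC" = rep("MC", 2L * n_glomeruli),
    "TC-TC" = rep("TC", 2L * n_glomeruli),
    "MC-TC" = rep(c("MC", "TC"), each = n_glomeruli)
  )
  glomerulus <- if (dual) rep(seq_len(n_glomeruli), 2L) else seq_len(n_glomeruli)
  type_sig <- list(MC = mc_sigmoid(), TC = tc_sigmoid(), G = common_sigmoid())
  if (sigmoid_mode == "common") {
    type_sig <- list(MC = common_sigmoid(), TC = common_sigmoid(),
                     G = common_sigmoid())
  }
  frac_by_type <- if (sigmoid_mode == "common") {
    c(MC = 0.75, TC = 0.75, G = 0.75)
  } else {
    c(MC = 0.75, TC = 0.60, G = 0.75)
  }
  kind <- switch(name,
    "none" = "none", "subtractive" = "subtractive", "divisive" = "divisive",
    if (is.null(inhibition_kind)) "adli" else inhibition_kind
  )
  A <- make_connectivity(cell_type, glomerulus, frac_by_type, connectivity_seed)
  types <- unique(cell_type)
  gi_for <- function(ty) {
    if (!is.null(gains)) {
      return(if (length(gains) == 1L && is.null(names(gains))) gains
             else unname(gains[[ty]]))
    }
    if (kind == "divisive") return(0.18)
    if (kind == "none") return(0)
    # eligible senders share the receiver's type and sit on other glomeruli
    n_senders <- sum(cell_type == ty) - (if (dual) 2L else 1L)
    .calibrated_gain(target_drop, frac_by_type[[ty]] * n_senders,
                     type_sig[[ty]])
  }
  inhib <- lapply(stats::setNames(types, types), function(ty) {
    gi <- gi_for(ty)
    switch(kind,
      adli = if (ty == "TC") tc_adli(gi) else if (ty == "MC") mc_adli(gi)
             else stop("adli requires MC or TC units"),
      inhibition_params(kind, gi = gi, network_divisive = network_divisive)
    )
  })
  cfg <- population_config(cell_type, glomerulus,
                           sigmoid = type_sig[types], inhibition = inhib,
                           connectivity = A)
  cfg$name <- name
  cfg$sigmoid_mode <- sigmoid_mode
  cfg$target_drop <- target_drop
  cfg
}

#' One forward-Euler update of the population state
#'
#' `v <- clip(v + (dt/tau) * (stim - gl*(v - El) - inhib(v, u)))`, with the
#' presynaptic sums `u = A v` recomputed from the updated rates.
#'
#' @param state List with numeric `v` (rates per unit, Hz).
#' @param drives Excitatory drive per unit (Hz).
#' @param config A `population_config`.
#' @param dt Time step; must be below `tau`.
#' @return List with updated `v` and `u`.
#' @export
step_population <- function(state, drives, config, dt = 0.4) {
  dyn <- config$dynamics
  stopifnot(dt > 0, dt < dyn$tau, length(state$v) == config$n_units)
  v <- state$v
  if (any(!is.finite(v))) stop("non-finite population state")
  u <- as.numeric(config$adjacency %*% v)
  inhib <- .inhib_matrix(v, u, config)
  vn <- v + (dt / dyn$tau) * (drives - dyn$gl * (v - dyn$El) - inhib)
  vn <- pmax(dyn$rate_floor, vn)
  list(v = vn, u = as.numeric(config$adjacency %*% vn))
}

# inhibition for per-unit parameter vectors; v, u may be vectors or
# units x trials matrices (per-unit vectors recycle down columns)
.inhib_matrix <- function(v, u, config) {
  switch(config$kind,
    adli = config$gi * u * exp(-(v - config$mu)^2 / config$sigma),
    subtractive = config$gi * u,
    divisive = if (config$network_divisive) config$gi * u * v
               else config$gi * v,
    none = 0
  )
}

#' Relax a block of trials to steady state
#'
#' Iterates the forward-Euler map on all trials simultaneously (rates held as
#' a units x trials matrix) until the largest per-step rate change falls
#' below `tol` or `max_steps` is reached. The fixed point of the map is the
#' steady state of the rate equation and does not depend on `dt`; `dt` only
#' sets the relaxation speed (default 0.2 tau, well inside the stability
#' margin for the default gains). Steady-state rates are the feature vectors
#' handed to the decoder.
#'
#' @param intensities Pixels x trials matrix of input intensities (a single
#'   trial may be given as a vector).
#' @param config A `population_config`.
#' @param dt,tol,max_steps Integration controls.
#' @param v0 Optional initial rates (scalar or units x trials). The default
#'   starts at the uninhibited balance `stim / gl`, which halves iteration
#'   counts; the reached fixed point does not depend on the start (tested).
#' @return List with `rates` (units x trials steady-state matrix), `steps`,
#'   `converged`, `max_delta`. Non-convergence is flagged, not an error.
#' @export
simulate_trials <- function(intensities, config, dt = 0.4, tol = 1e-4,
                            max_steps = 2000L, v0 = NULL) {
  if (is.vector(intensities)) intensities <- matrix(intensities)
  stopifnot(inherits(config, "population_config"),
            nrow(intensities) >= max(config$glomerulus))
  dyn <- config$dynamics
  stopifnot(dt > 0, dt < dyn$tau)
  S <- config$max_rate /
    (1 + exp(-config$slope *
               (intensities[config$glomerulus, , drop = FALSE] -
                  config$midpoint)))
  n <- config$n_units
  nt <- ncol(S)
  V <- if (is.null(v0)) {
    if (dyn$gl > 0) S / dyn$gl + dyn$El else matrix(dyn$rate_floor, n, nt)
  } else {
    matrix(v0, n, nt)
  }
  V[V < dyn$rate_floor] <- dyn$rate_floor
  A <- config$adjacency
  need_u <- config$kind %in% c("adli", "subtractive") ||
    (config$kind == "divisive" && config$network_divisive)
  a <- dt / dyn$tau
  converged <- FALSE
  delta <- Inf
  k <- 0L
  while (k < max_steps) {
    k <- k + 1L
    u <- if (need_u) A %*% V else 0
    inhib <- .inhib_matrix(V, u, config)
    Vn <- V + a * (S - dyn$gl * (V - dyn$El) - inhib)
    Vn[Vn < dyn$rate_floor] <- dyn$rate_floor
    delta <- max(abs(Vn - V))
    if (!is.finite(delta)) stop("non-finite rates during integration")
    V <- Vn
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(rates = V, steps = k, converged = converged, max_delta = delta)
}

#' @rdname simulate_trials
#' @param trial A single trial intensity vector.
#' @export
simulate_trial <- function(trial, config, dt = 0.4, tol = 1e-4,
                           max_steps = 2000L, v0 = NULL) {
  res <- simulate_trials(matrix(trial), config, dt, tol, max_steps, v0)
  structure(drop(res$rates), steps = res$steps, converged = res$converged)
}

#' @export
print.population_config <- function(x, ...) {
  cat("population_config: ", x$n_units, " units (",
      paste(sprintf("%s=%d", names(table(x$cell_type)), table(x$cell_type)),
            collapse = ", "),
      "), inhibition = ", x$kind, "\n", sep = "")
  if (x$kind %in% c("adli", "subtractive", "divisive")) {
    for (ty in unique(x$cell_type)) {
      i <- match(ty, x$cell_type)
      cat(sprintf("  %s: gi=%.3g mu=%s sigma=%s, in-degree ~ %.0f\n", ty,
                  x$gi[i], format(x$mu[i]), format(x$sigma[i]),
                  sum(x$adjacency[i, ])))
    }
  }
  invisible(x)
}
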