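#' Glomerular grid specification
#'
#' The odor input space is a rectangular array of pixels, one per glomerulus.
#' The default 15 x 10 grid gives the 150 glomeruli used throughout the
#' simulations.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @return An object of class `grid_spec` with fields `n_rows`, `n_cols`,
#'   `n_pixels`.
#' @export
grid_spec <- function(n_rows = 15L, n_cols = 10L) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L ||
      n_rows * n_cols < 2L) {
    stop("grid must have at least 2 pixels")
  }
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 n_pixels = n_rows * n_cols),
            class = "grid_spec")
}

#' Construct the base odor of a panel
#'
#' One third of pixels (rounded down) are non-activatable (NA): they never
#' respond to odors at any concentration. Every activatable pixel gets a
#' concentration threshold drawn from U(0, 1000); a pixel is ON at the
#' presented concentration `I_pres` iff its threshold is below `I_pres`,
#' otherwise OFF. ON pixels receive a mean activation intensity
#' `I_base ~ N(I_pres, 50)` (truncated at 0). Concentration is expressed on
#' the 0-1000 input-intensity scale, where 1000 drives the output sigmoids
#' to their 100 Hz saturation.
#'
#' @param grid A [grid_spec()].
#' @param concentration Presentation intensity `I_pres` in `[0, 1000]`.
#' @param seed Integer seed; the panel is bit-reproducible given
#'   `(grid, concentration, seed)`.
#' @return An `odor_panel` with `n_odors = 1`. Fields: `pixel_state`
#'   (odors x pixels character matrix, `"NA"`/`"ON"`/`"OFF"`), `thresholds`,
#'   `base_intensity` (both odors x pixels, `NA` where undefined),
#'   `change_flags` (which pixels were resampled when deriving each odor),
#'   `grid`, `concentration`, `seed`.
#' @export
make_base_odor <- function(grid = grid_spec(), concentration, seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"))
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      !is.finite(concentration) || concentration < 0 || concentration > 1000) {
    stop("`concentration` must lie in [0, 1000]")
  }
  n <- grid$n_pixels
  set.seed(child_seed(seed, "base-odor"))
  n_na <- floor(n / 3)
  na_idx <- sample.int(n, n_na)
  state <- rep("OFF", n)
  state[na_idx] <- "NA"
  thr <- rep(NA_real_, n)
  act <- setdiff(seq_len(n), na_idx)
  thr[act] <- stats::runif(length(act), 0, 1000)
  on <- act[thr[act] < concentration]
  state[on] <- "ON"
  ib <- rep(NA_real_, n)
  if (length(on)) {
    ib[on] <- pmax(0, stats::rnorm(length(on), concentration, 50))
  }
  structure(list(
    grid = grid,
    concentration = concentration,
    n_odors = 1L,
    pixel_state = matrix(state, 1L, n),
    thresholds = matrix(thr, 1L, n),
    base_intensity = matrix(ib, 1L, n),
    change_flags = matrix(FALSE, 1L, n),
    seed = as.integer(seed)
  ), class = "odor_panel")
}

# One mutation pass over the base odor: flag each pixel with prob change_prob
# and apply the transition table
#   NA  -> NA  w.p. 1/3,  NA -> ON w.p. 2/3 (fresh threshold and I_base)
#   ON  -> NA  w.p. 1/3,  ON -> ON w.p. 2/3 (fresh I_base)
#   OFF -> OFF w.p. 1
.mutate_odor <- function(state, thr, ib, concentration, change_prob) {
  n <- length(state)
  flagged <- stats::runif(n) < change_prob
  idx_na <- which(flagged & state == "NA")
  idx_on <- which(flagged & state == "ON")
  # flagged OFF pixels stay OFF: no draws consumed, per the transition table
  if (length(idx_na)) {
    to_on <- idx_na[stats::runif(length(idx_na)) < 2 / 3]
    if (length(to_on)) {
      state[to_on] <- "ON"
      thr[to_on] <- stats::runif(length(to_on), 0, 1000)
      ib[to_on] <- pmax(0, stats::rnorm(length(to_on), concentration, 50))
    }
  }
  if (length(idx_on)) {
    u <- stats::runif(length(idx_on))
    to_na <- idx_on[u < 1 / 3]
    stay_on <- idx_on[u >= 1 / 3]
    if (length(to_na)) {
      state[to_na] <- "NA"
      thr[to_na] <- NA_real_
      ib[to_na] <- NA_real_
    }
    if (length(stay_on)) {
      ib[stay_on] <- pmax(0, stats::rnorm(length(stay_on), concentration, 50))
    }
  }
  list(state = state, thr = thr, ib = ib, flagged = flagged)
}

.pixel_key <- function(state_row) paste(state_row, collapse = "")

#' Derive a panel of similar odors from a base odor
#'
#' Each derived odor is built from Odor 1 by flagging each pixel independently
#' with probability `change_prob` (default 0.10, making derived odors ~90%
#' similar to the base) and applying the pixel-state transition table (see
#' [make_base_odor()] for the base construction and `.mutate_odor` above for
#' the table). Duplicate pixel-state patterns are rejected and resampled so
#' that no two odors in the panel are identical; uniqueness compares pixel
#' states only, since intensities are redrawn on every trial anyway.
#'
#' @param panel An `odor_panel` with a single base odor.
#' @param n_odors Total panel size (including the retained Odor 1); >= 2.
#' @param seed Integer seed.
#' @param change_prob Per-pixel resampling probability.
#' @param max_retries Bound on duplicate-rejection retries per odor.
#' @return The input panel grown to `n_odors` odors. `change_flags[i, ]`
#'   records which pixels were flagged for resampling when odor `i` was
#'   derived (all `FALSE` for Odor 1).
#' @export
derive_similar_odors <- function(panel, n_odors, seed = 1L,
                                 change_prob = 0.10, max_retries = 1000L) {
  stopifnot(inherits(panel, "odor_panel"))
  if (panel$n_odors != 1L) stop("`panel` must contain exactly the base odor")
  n_odors <- as.integer(n_odors)
  if (is.na(n_odors) || n_odors < 2L) stop("`n_odors` must be at least 2")
  n <- panel$grid$n_pixels
  base_state <- panel$pixel_state[1L, ]
  base_thr <- panel$thresholds[1L, ]
  base_ib <- panel$base_intensity[1L, ]
  state <- matrix(NA_character_, n_odors, n)
  thr <- matrix(NA_real_, n_odors, n)
  ib <- matrix(NA_real_, n_odors, n)
  flags <- matrix(FALSE, n_odors, n)
  state[1L, ] <- base_state
  thr[1L, ] <- base_thr
  ib[1L, ] <- base_ib
  seen <- new.env(parent = emptyenv())
  assign(.pixel_key(base_state), TRUE, envir = seen)
  set.seed(child_seed(seed, "derive"))
  for (i in 2:n_odors) {
    ok <- FALSE
    for (r in seq_len(max_retries)) {
      d <- .mutate_odor(base_state, base_thr, base_ib,
                        panel$concentration, change_prob)
      key <- .pixel_key(d$state)
      if (!exists(key, envir = seen, inherits = FALSE)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not derive ", n_odors, " unique odors after ",
           max_retries, " retries per odor; the grid is too small or ",
           "`change_prob` too low for this panel size")
    }
    assign(key, TRUE, envir = seen)
    state[i, ] <- d$state
    thr[i, ] <- d$thr
    ib[i, ] <- d$ib
    flags[i, ] <- d$flagged
  }
  panel$n_odors <- n_odors
  panel$pixel_state <- state
  panel$thresholds <- thr
  panel$base_intensity <- ib
  panel$change_flags <- flags
  panel
}

#' Sample noisy single-trial glomerular inputs
#'
#' Trial-to-trial variability: NA and OFF pixels are resampled from
#' U(0, 1000) on every presentation (mimicking fluctuating background odor),
#' while ON pixels fluctuate tightly around their odor-specific mean,
#' `I_trial ~ N(I_base, 5)`, truncated at 0.
#'
#' @param panel An `odor_panel`.
#' @param odor_index Integer vector, one entry per trial, each in
#'   `1:panel$n_odors`.
#' @param seed Integer seed; the whole block of trials is reproducible.
#' @return A pixels x trials numeric matrix of input intensities on the
#'   0-1000 scale (values above 1000 can occur for ON pixels near saturation
#'   and are tolerated; the output sigmoid saturates anyway). Pixel order is
#'   row-major over the grid.
#' @export
sample_trials <- function(panel, odor_index, seed = 1L) {
  stopifnot(inherits(panel, "odor_panel"))
  idx <- as.integer(odor_index)
  if (length(idx) < 1L || anyNA(idx) || any(idx < 1L | idx > panel$n_odors)) {
    stop("`odor_index` entries must lie in 1..", panel$n_odors)
  }
  n <- panel$grid$n_pixels
  nt <- length(idx)
  set.seed(child_seed(seed, "trials"))
  x <- matrix(stats::runif(n * nt, 0, 1000), n, nt)
  on <- t(panel$pixel_state[idx, , drop = FALSE] == "ON")
  if (any(on)) {
    ibase <- t(panel$base_intensity[idx, , drop = FALSE])
    x[on] <- pmax(0, stats::rnorm(sum(on), ibase[on], 5))
  }
  rownames(x) <- sprintf("px%03d", seq_len(n))
  x
}

#' @rdname sample_trials
#' @export
sample_trial <- function(panel, odor_index, seed = 1L) {
  stopifnot(length(odor_index) == 1L)
  drop(sample_trials(panel, odor_index, seed))
}

#' Balanced random odor labels for a block of trials
#'
#' Assigns odors to trials as a random permutation of a balanced design
#' (every odor appears `floor(n_trials / n_odors)` or one more time), which
#' guarantees the >= 2 trials per odor needed by the stratified split.
#'
#' @param n_odors,n_trials Counts.
#' @param seed Integer seed.
#' @return Integer vector of length `n_trials`.
#' @export
balanced_labels <- function(n_odors, n_trials, seed = 1L) {
  stopifnot(n_odors >= 1L, n_trials >= n_odors)
  set.seed(child_seed(seed, "labels"))
  sample(rep_len(seq_len(n_odors), n_trials))
}

#' @export
print.odor_panel <- function(x, ...) {
  st <- x$pixel_state
  cat("odor_panel: ", x$n_odors, " odor(s) on a ", x$grid$n_rows, "x",
      x$grid$n_cols, " grid, I_presentation = ", x$concentration, "\n",
      sep = "")
  cat("  pixel states (odor 1): ",
      sum(st[1, ] == "NA"), " NA / ", sum(st[1, ] == "ON"), " ON / ",
      sum(st[1, ] == "OFF"), " OFF\n", sep = "")
  invisible(x)
}
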