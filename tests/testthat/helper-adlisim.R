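# Independent steady-state oracle: damped Newton iteration on the rate
# equation's residual with a numerically differenced Jacobian. Shares no code
# with the package's Euler relaxation.
newton_steady_state <- function(stim, config, v0 = NULL, tol = 1e-10,
                                max_iter = 100L) {
  n <- length(stim)
  dyn <- config$dynamics
  residual <- function(v) {
    u <- as.numeric(config$adjacency %*% v)
    inhib <- switch(config$kind,
      adli = config$gi * u * exp(-(v - config$mu)^2 / config$sigma),
      subtractive = config$gi * u,
      divisive = config$gi * v,
      none = rep(0, n)
    )
    stim - dyn$gl * (v - dyn$El) - inhib
  }
  v <- if (is.null(v0)) stim / max(dyn$gl, 1e-12) else v0
  for (it in seq_len(max_iter)) {
    r <- residual(v)
    if (max(abs(r)) < tol) break
    J <- matrix(0, n, n)
    h <- 1e-6
    for (j in seq_len(n)) {
      vp <- v
      vp[j] <- vp[j] + h
      J[, j] <- (residual(vp) - r) / h
    }
    step <- tryCatch(solve(J, r), error = function(e) {
      # ridge fallback for ill-conditioned Jacobians; the fixed point
      # (residual = 0) is unchanged
      solve(J + diag(1e-6, n), r)
    })
    # backtracking line search keeps the iteration inside the basin
    lambda <- 1
    for (bt in 1:30) {
      v_new <- v - lambda * step
      r_new <- residual(v_new)
      if (all(is.finite(r_new)) && sum(r_new^2) < sum(r^2)) break
      lambda <- lambda / 2
    }
    v <- v_new
  }
  v
}

# Brute-force Gaussian naive Bayes posterior: literal product of univariate
# normal densities with MLE moments and uniform priors.
brute_force_gnb_predict <- function(train_x, train_y, test_x,
                                    var_floor = 1e-6) {
  classes <- sort(unique(as.character(train_y)))
  post <- sapply(classes, function(k) {
    xk <- train_x[train_y == k, , drop = FALSE]
    apply(test_x, 1, function(row) {
      p <- 1 / length(classes)
      for (j in seq_len(ncol(train_x))) {
        m <- mean(xk[, j])
        v <- max(mean((xk[, j] - m)^2), var_floor)
        p <- p * stats::dnorm(row[j], m, sqrt(v))
      }
      p
    })
  })
  if (is.null(dim(post))) post <- matrix(post, nrow = 1)
  classes[apply(post, 1, which.max)]
}

# do two label vectors define the same partition (up to renaming)?
same_partition <- function(a, b) {
  identical(outer(a, a, `==`), outer(b, b, `==`))
}

# small labeled-response fixture: `k` well-separated Gaussian classes
make_test_responses <- function(k = 3L, n_per = 20L, p = 5L, sep = 6,
                                seed = 1L) {
  set.seed(seed)
  y <- rep(seq_len(k), each = n_per)
  centers <- matrix(stats::rnorm(k * p, 0, sep), k, p)
  x <- centers[y, ] + matrix(stats::rnorm(length(y) * p), length(y), p)
  list(x = x, y = y)
}
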