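# Penalized composite link model engine.
#
# All model fitting in the package reduces to one problem: counts
# d ~ Poisson(C %*% gamma) with gamma = exp(X %*% beta) built from one or
# more B-spline blocks, a quadratic difference penalty per block, optional
# asymmetric shape penalties, optional prior regression weights (used by
# the data-augmentation constraint rows), and an optional linear "mass"
# penalty kappa * sum(w * gamma_j) that acts as a tie-break in directions
# where the likelihood cannot allocate mass between components. The solver
# is a penalized iteratively reweighted least squares scheme: linearize the
# mean through U = C diag(gamma) X, take a damped Newton step on the
# penalized log-likelihood, and step-halve so the objective never decreases
# between accepted iterations.

ETA_CAP <- 40 # |log rate| guard against overflow in exp()

clm_objective <- function(beta, d, C, X, prior_w, P_smooth, blocks, idx,
                          ridge) {
  eta <- drop(X %*% beta)
  gamma <- exp(pmin(eta, ETA_CAP))
  mu <- as.numeric(C %*% gamma)
  mu_safe <- pmax(mu, 1e-300)
  ll <- sum(prior_w * (ifelse(d > 0, d * log(mu_safe), 0) - mu))
  pen <- 0.5 * drop(crossprod(beta, P_smooth %*% beta)) +
    0.5 * ridge * sum(beta^2)
  shp <- 0
  mass <- 0
  for (j in seq_along(blocks)) {
    b <- blocks[[j]]
    shp <- shp + shape_penalty_value(beta[idx[[j]]], b$penalty$shape,
                                     b$penalty$shape_weight)
    if (!is.null(b$mass_w)) {
      gj <- exp(pmin(drop(b$X %*% beta[idx[[j]]]), ETA_CAP))
      mass <- mass + sum(b$mass_w * gj)
    }
  }
  ll - pen - shp - mass
}

# d: response (real-valued pseudo-counts allowed)
# C: composition matrix (base or Matrix), ncol(C) == sum of basis rows
# blocks: list of list(X = basis matrix, penalty = penalty_bundle,
#         mass_w = optional per-age linear penalty weights on gamma)
# prior_w: per-row regression weights (scalar or length(d))
clm_fit <- function(d, C, blocks, prior_w = 1, beta_init = NULL,
                    ridge = 1e-6, max_iter = 200L, tol = 1e-6,
                    shape_tol = 1e-9, max_shape_weight = 1e12) {
  n <- length(d)
  if (any(d < 0)) abort("negative counts in the response.")
  prior_w <- rep_len(prior_w, n)
  p_j <- vapply(blocks, function(b) ncol(b$X), integer(1))
  m_j <- vapply(blocks, function(b) nrow(b$X), integer(1))
  p <- sum(p_j)
  if (ncol(C) != sum(m_j)) abort("composition matrix does not match bases.")
  idx <- split(seq_len(p), rep(seq_along(blocks), p_j))
  X <- as.matrix(Matrix::bdiag(lapply(blocks, `[[`, "X")))
  C <- methods::as(C, "CsparseMatrix")

  # fixed quadratic smoothness penalty (block diagonal)
  P_smooth <- as.matrix(Matrix::bdiag(lapply(blocks, function(b) {
    D <- difference_matrix(ncol(b$X), b$penalty$order)
    b$penalty$lambda * crossprod(D)
  })))

  beta <- if (is.null(beta_init)) rep(log(1e-4), p) else beta_init
  stopifnot(length(beta) == p)

  obj <- function(b) clm_objective(b, d, C, X, prior_w, P_smooth, blocks,
                                   idx, ridge)
  obj_old <- obj(beta)
  obj_trace <- obj_old
  converged <- FALSE
  inner_converged <- FALSE # coefficient change fell below tol at least once
  iter <- 0L
  info <- NULL
  delta_prev <- Inf

  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    gamma <- exp(pmin(eta, ETA_CAP))
    mu <- as.numeric(C %*% gamma)
    U <- as.matrix(C %*% (gamma * X))
    W <- prior_w / pmax(mu, 1e-10)

    # penalty matrix with the current active shape sets
    P <- P_smooth + diag(ridge, p)
    for (j in seq_along(blocks)) {
      b <- blocks[[j]]
      if (b$penalty$shape != "none") {
        P[idx[[j]], idx[[j]]] <- P[idx[[j]], idx[[j]]] +
          shape_violation_penalty(beta[idx[[j]]], b$penalty$shape,
                                  b$penalty$shape_weight)
      }
    }
    # damped Newton step on the penalized log-likelihood
    grad <- drop(crossprod(U, prior_w * (d - mu) / pmax(mu, 1e-10))) -
      drop(P %*% beta)
    H_extra <- matrix(0, p, p)
    for (j in seq_along(blocks)) {
      b <- blocks[[j]]
      if (!is.null(b$mass_w)) {
        gj <- gamma[rep(seq_along(blocks), m_j) == j]
        grad[idx[[j]]] <- grad[idx[[j]]] -
          drop(crossprod(b$X, b$mass_w * gj))
        H_extra[idx[[j]], idx[[j]]] <- crossprod(b$X * sqrt(b$mass_w * gj))
      }
    }
    info <- crossprod(U, W * U)
    # near the optimum switch from Fisher scoring to observed-information
    # Newton: in weakly curved directions Fisher scoring converges only
    # linearly, while the observed Hessian keeps quadratic convergence
    H_lik <- info
    if (iter > 1L && delta_prev < 1e-3) {
      s <- as.numeric(Matrix::crossprod(C, prior_w * (d - mu) /
                                          pmax(mu, 1e-10)))
      H_obs <- crossprod(U, (prior_w * d / pmax(mu, 1e-10)^2) * U) -
        crossprod(X, (gamma * s) * X)
      if (all(is.finite(H_obs))) H_lik <- H_obs
    }
    prop <- tryCatch(
      beta + drop(solve(H_lik + P + H_extra, grad)),
      error = function(e) NULL
    )
    if (!is.null(prop) && !identical(H_lik, info)) {
      # fall back to the Fisher step if the Newton step is not an ascent
      if (!is.finite(obj(prop)) ||
          obj(prop) < obj_old - (1e-10 + 1e-13 * abs(obj_old))) {
        prop2 <- tryCatch(
          beta + drop(solve(info + P + H_extra, grad)),
          error = function(e) NULL
        )
        if (!is.null(prop2)) prop <- prop2
      }
    }
    if (is.null(prop)) {
      # singular Newton system (extreme shape weights); the iterate stands
      # if the inner iteration had converged and violations are negligible
      worst <- max(vapply(seq_along(blocks), function(j) {
        shape_violation_size(beta[idx[[j]]], blocks[[j]]$penalty$shape)
      }, numeric(1)))
      if (inner_converged && worst <= 1e-8) converged <- TRUE
      break
    }

    # accept any step that does not decrease the objective beyond floating
    # point resolution at its magnitude
    accept_tol <- 1e-10 + 1e-13 * abs(obj_old)
    step <- 1
    accepted <- FALSE
    for (h in 1:30) {
      cand <- beta + step * (prop - beta)
      obj_new <- obj(cand)
      if (is.finite(obj_new) && obj_new >= obj_old - accept_tol) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) {
      # no productive step left within floating-point resolution; the
      # iterate is a fixed point if the proposal is below tolerance, or if
      # the inner iteration had already converged and only the shape-weight
      # escalation (whose Newton system is nearly singular at high weights)
      # stalled while residual violations are already negligible
      worst <- max(vapply(seq_along(blocks), function(j) {
        shape_violation_size(beta[idx[[j]]], blocks[[j]]$penalty$shape)
      }, numeric(1)))
      if (max(abs(prop - beta) / pmax(abs(beta), 1)) < tol ||
          (inner_converged && worst <= 1e-8)) {
        converged <- TRUE
      }
      break
    }
    delta <- max(abs(cand - beta) / pmax(abs(beta), 1))
    delta_prev <- delta
    beta <- cand
    obj_old <- obj_new
    obj_trace <- c(obj_trace, obj_new)

    if (delta < tol) {
      inner_converged <- TRUE
      # escalate shape weights until residual violations are negligible
      worst <- 0
      for (j in seq_along(blocks)) {
        worst <- max(worst, shape_violation_size(beta[idx[[j]]],
                                                 blocks[[j]]$penalty$shape))
      }
      escalated <- FALSE
      for (j in seq_along(blocks)) {
        bj <- blocks[[j]]
        if (bj$penalty$shape != "none" && worst > shape_tol &&
            bj$penalty$shape_weight < max_shape_weight) {
          blocks[[j]]$penalty$shape_weight <- bj$penalty$shape_weight * 100
          escalated <- TRUE
        }
      }
      if (escalated) {
        obj_old <- obj(beta)
        next
      }
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
  }

  eta <- drop(X %*% beta)
  gamma <- exp(pmin(eta, ETA_CAP))
  mu <- as.numeric(C %*% gamma)
  mu_safe <- pmax(mu, 1e-300)
  dev <- 2 * sum(prior_w *
                   (ifelse(d > 0, d * log(d / mu_safe), 0) - (d - mu)))
  ed <- tryCatch({
    P <- P_smooth + diag(ridge, p)
    for (j in seq_along(blocks)) {
      bj <- blocks[[j]]
      if (bj$penalty$shape != "none") {
        P[idx[[j]], idx[[j]]] <- P[idx[[j]], idx[[j]]] +
          shape_violation_penalty(beta[idx[[j]]], bj$penalty$shape,
                                  bj$penalty$shape_weight)
      }
    }
    sum(diag(solve(info + P, info)))
  }, error = function(e) NA_real_)

  list(
    beta = beta,
    beta_blocks = lapply(idx, function(i) beta[i]),
    gamma_blocks = {
      g <- split(gamma, rep(seq_along(blocks), m_j))
      names(g) <- names(blocks)
      g
    },
    mu = mu,
    deviance = dev,
    ed = ed,
    objective = obj_old,
    objective_trace = obj_trace,
    converged = converged,
    iterations = iter,
    shape_weights = vapply(blocks, function(b) b$penalty$shape_weight,
                           numeric(1))
  )
}
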