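# Shared fixtures and independent oracles, built in code at test time.

# Small-world config for fast integration tests.
tiny_config <- function(n = 10L, horizon = 5L, seed = 42L, ...) {
  default_config(geometry = list(nx = n, ny = n, nz = n),
                 run = list(horizon = as.integer(horizon),
                            seed = as.integer(seed)), ...)
}

# Dense matrix operator for one explicit diffusion step with the no-flux
# (mirror-the-center) convention: an independent oracle for the stencil
# solver. Rows: C'_i = C_i + lambda * (sum_in-bounds-nb C_j - n_in(i) C_i).
dense_diffusion_operator <- function(lattice, lambda) {
  n <- lattice$n
  M <- diag(n)
  for (i in seq_len(n)) {
    nbs <- lattice$nb[i, ]
    nbs <- nbs[nbs > 0L]
    for (j in nbs) M[i, j] <- M[i, j] + lambda
    M[i, i] <- M[i, i] - lambda * length(nbs)
  }
  M
}

# A small deterministic Markov decision process and its exact solution by
# value iteration (the dynamic-programming oracle for the learning loop).
toy_mdp <- function() {
  trans <- list(
    s1 = list(a = list(state = "s2", reward = 0.10),
              b = list(state = "s3", reward = -0.20)),
    s2 = list(a = list(state = "s1", reward = 0.30),
              b = list(state = "s3", reward = 0.50)),
    s3 = list(a = list(state = "s3", reward = 0.00),
              b = list(state = "s1", reward = 0.40)))
  list(
    states = names(trans),
    reset = function() "s1",
    actions = function(s) names(trans[[s]]),
    step = function(s, a) trans[[s]][[a]],
    trans = trans
  )
}

value_iteration <- function(env, gamma, tol = 1e-12, max_iter = 10000L) {
  Q <- sapply(env$states, function(s) {
    v <- rep(0, length(env$actions(s)))
    names(v) <- env$actions(s)
    v
  }, simplify = FALSE)
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (s in env$states) for (a in env$actions(s)) {
      nx <- env$step(s, a)
      target <- nx$reward + gamma * max(Q[[nx$state]])
      delta <- max(delta, abs(target - Q[[s]][a]))
      Q[[s]][a] <- target
    }
    if (delta < tol) break
  }
  Q
}

# Brute-force non-dominated filter over a dense grid: the oracle Pareto
# front for toy multi-objective problems.
grid_pareto <- function(f, lower, upper, n_grid = 2001L) {
  xs <- seq(lower, upper, length.out = n_grid)
  FF <- t(vapply(xs, f, numeric(2)))
  keep <- vapply(seq_len(nrow(FF)), function(i) {
    !any(FF[, 1] >= FF[i, 1] & FF[, 2] >= FF[i, 2] &
           (FF[, 1] > FF[i, 1] | FF[, 2] > FF[i, 2]))
  }, logical(1))
  list(x = xs[keep], F = FF[keep, , drop = FALSE])
}

# Synthetic Q-regression task: smooth bounded target over the cancer-cell
# state layout, for ensemble-vs-single-kernel comparisons.
synth_q_task <- function(n, seed, noise = 0.05) {
  set.seed(seed)
  vars <- state_vars_for("cancerous")
  X <- matrix(runif(n * length(vars)), nrow = n,
              dimnames = list(NULL, vars))
  acts <- allowed_actions("cancerous")
  a <- sample(acts, n, replace = TRUE)
  f <- function(X, a) {
    0.8 * tanh(1.5 * X[, "oxygen"] - X[, "hypoxia_counter"] +
                 0.5 * (a == "proliferation") - 0.4 * (a == "necrosis")) -
      0.2 * X[, "tnfa"]
  }
  y <- pmin(pmax(f(X, a) + rnorm(n, sd = noise), -1), 1)
  w <- new_experience_window(n, vars)
  for (i in seq_len(n))
    w <- admit_experience(w, X[i, ], a[i], y[i], reward = 1, theta = 0)
  list(window = w, X = X, a = a, y = y, f = f)
}
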