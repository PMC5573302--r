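#' Per-policy reward function
#'
#' The smooth reward contribution of one policy rule:
#' `direction * tanh((x - threshold) / gradient)`. It is 0 exactly at the
#' threshold, changes sign there, and is strictly inside (-1, 1) everywhere.
#'
#' @param x scalar (or vector) state-variable value.
#' @param rule a policy rule list with `threshold`, `gradient` (> 0) and
#'   `direction` (+1 if larger `x` favors survival, -1 otherwise).
#' @return reward value(s) in (-1, 1).
#' @examples
#' r <- list(threshold = 5, gradient = 2, direction = 1)
#' reward_fn(5, r)   # 0
#' reward_fn(7, r)   # tanh(1)
#' @export
reward_fn <- function(x, rule) {
  stopifnot(rule$gradient > 0, rule$direction %in% c(-1, 1))
  rule$direction * tanh((x - rule$threshold) / rule$gradient)
}

rule_state_value <- function(state, variable) {
  v <- state[[variable]]
  if (is.null(v) && variable == "n_moore_nb")
    v <- (state[["n_healthy_nb"]] %||% 0) + (state[["n_cancer_nb"]] %||% 0)
  if (is.null(v)) stop("state lacks variable: ", variable, call. = FALSE)
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

applicable_rules <- function(rules, celltype)
  Filter(function(r) celltype %in% r$types, rules)

#' Total reward of a state
#'
#' The arithmetic mean of the per-policy reward terms over all rules
#' applicable to the cell type; strictly inside (-1, 1).
#'
#' @param state named list/vector of state-variable values.
#' @param rules list of policy rules (see [default_policy_rules()]).
#' @param celltype the cell type the state belongs to.
#' @return scalar total reward.
#' @export
total_reward <- function(state, rules, celltype = "cancerous") {
  app <- applicable_rules(rules, celltype)
  if (!length(app)) stop("no applicable policy rule for ", celltype,
                         call. = FALSE)
  mean(vapply(app, function(r) reward_fn(rule_state_value(state, r$variable), r),
              numeric(1)))
}

# Vectorized total reward over a state data.frame (rows = cells).
total_reward_rows <- function(states, rules, celltype) {
  app <- applicable_rules(rules, celltype)
  acc <- numeric(nrow(states))
  for (r in app) {
    x <- if (r$variable %in% names(states)) states[[r$variable]]
         else states$n_healthy_nb + states$n_cancer_nb
    acc <- acc + r$direction * tanh((x - r$threshold) / r$gradient)
  }
  acc / length(app)
}

#' Policy-rule action biases
#'
#' Multiplicative per-action selection weights implementing the ten policy
#' rules: each triggered rule multiplies its favored actions by the bias
#' strength (shifting probability mass toward them and, after
#' normalization, away from the rest). Two hard constraints are encoded as
#' zero biases: migration is impossible with two or fewer tissue Moore
#' neighbors (rule 7), and only the rules applicable to the cell type fire.
#'
#' @param state named list/vector of state-variable values; tissue cells may
#'   additionally carry `plcg_mean_others` (mean PLC-gamma of the other
#'   cells, rule 6) and `death_signal` (TNF-pathway readout, rule 8).
#' @param rules policy rule list.
#' @param celltype cell type.
#' @param agent the agent threshold section of the config.
#' @param bias_strength multiplicative factor applied by a triggered rule.
#' @return named numeric vector of non-negative weights over
#'   `allowed_actions(celltype)`.
#' @export
policy_bias <- function(state, rules, celltype,
                        agent = default_config()$agent, bias_strength = 4) {
  df <- as.data.frame(as.list(unlist(state)))
  drop(policy_bias_rows(df, rules, celltype, agent, bias_strength)[1, ])
}

policy_bias_rows <- function(states, rules, celltype,
                             agent, k = 4) {
  acts <- allowed_actions(celltype)
  n <- nrow(states)
  B <- matrix(1, nrow = n, ncol = length(acts),
              dimnames = list(NULL, acts))
  col <- function(nm, default = 0)
    if (nm %in% names(states)) states[[nm]] else rep(default, n)
  mult <- function(B, rows, actions, f) {
    actions <- intersect(actions, colnames(B))
    if (length(actions) && any(rows)) {
      if (length(f) > 1L) f <- f[rows]
      B[rows, actions] <- B[rows, actions] * f
    }
    B
  }
  # a triggered rule shifts selection mass: favored actions gain a factor k
  # and every other allowed action loses the same factor
  shift_mass <- function(B, rows, favored, k) {
    favored <- intersect(favored, colnames(B))
    if (!length(favored) || !any(rows)) return(B)
    B[rows, favored] <- B[rows, favored] * k
    others <- setdiff(colnames(B), favored)
    if (length(others)) B[rows, others] <- B[rows, others] / k
    B
  }
  death <- if (celltype == "healthy") "apoptosis" else "necrosis"
  ids <- vapply(applicable_rules(rules, celltype), `[[`, integer(1), "id")
  have <- function(i) i %in% ids
  th <- function(i) {
    r <- Filter(function(r) r$id == i, rules)[[1]]
    r$threshold
  }

  if (celltype %in% c("healthy", "cancerous")) {
    if (have(1)) {
      low <- col("oxygen") < th(1)
      B <- shift_mass(B, low, c("hypoxia", death), k)
      B <- shift_mass(B, !low, c("proliferation", "migration"), k)
    }
    if (have(2)) {
      g <- col("glucose")
      B <- shift_mass(B, g > agent$glucose_active,
                      c("proliferation", "migration"), k)
      B <- shift_mass(B, g < agent$glucose_dead, death, k)
      if (celltype == "healthy")
        B <- shift_mass(B, g >= agent$glucose_dead & g <= agent$glucose_active,
                        "quiescence", k)
    }
    if (have(3) && celltype == "healthy")
      B <- shift_mass(B, col("division_counter") > agent$division_limit,
                      "quiescence", k)
    if (have(4))
      B <- shift_mass(B, col("prolif_delay") > th(4), c("hypoxia", death), k)
    if (have(5)) {
      hc <- col("hypoxia_counter")
      B <- shift_mass(B, hc > agent$hypoxia_counter_limit, death, k)
      mid <- hc > 1 & hc <= agent$hypoxia_counter_limit
      B <- shift_mass(B, mid, "hypoxia", k)
      if (celltype == "healthy") B <- mult(B, mid, "apoptosis", k / 2)
    }
    if (have(6)) {
      pref <- col("plcg") > col("plcg_mean_others")
      B <- shift_mass(B, pref, "proliferation", k)
      B <- shift_mass(B, !pref, "migration", k)
    }
    if (have(7)) {
      nnb <- col("n_healthy_nb") + col("n_cancer_nb")
      B <- mult(B, nnb <= 2, "migration", 0)
      crowded <- nnb > 2
      B <- mult(B, crowded, "migration", 1 + (k - 1) * (nnb - 2) / 24)
    }
    if (have(8)) {
      B <- shift_mass(B, col("tnfa") > th(8), death, k)
      B <- mult(B, col("death_signal") >= ds_threshold(), death, k^2)
    }
  } else if (celltype == "stalk") {
    # branching and lateral sprouting are rare baseline events; rule 9
    # raises sprouting when VEGF is above its threshold
    B[, "branch"] <- B[, "branch"] * 0.1
    B[, "sprout"] <- B[, "sprout"] * 0.1
    if (have(9)) B <- shift_mass(B, col("vegf") > th(9), "sprout", k)
  } else if (celltype == "tip") {
    B[, "branch"] <- B[, "branch"] * 0.1
    B[, "quiescence"] <- B[, "quiescence"] * 0.2
    if (have(10)) {
      mature <- col("tip_age") >= agent$tip_maturity
      B <- shift_mass(B, mature, "branch", k)
      B <- shift_mass(B, !mature, "expansion", k)
    }
  }
  B
}

#' Q-learning value update
#'
#' `Q <- (1 - eta) Q + eta * (r + gamma_disc * max_next_Q)`.
#'
#' @param Q current state-action value.
#' @param r immediate reward.
#' @param max_next_Q maximum Q over the successor state's actions.
#' @param eta learning rate in (0, 1].
#' @param gamma_disc discount factor in \[0, 1).
#' @return updated Q value.
#' @examples
#' q_update(0.5, 1, 0.8, 0.1, 0.9)  # 0.622
#' @export
q_update <- function(Q, r, max_next_Q, eta, gamma_disc) {
  stopifnot(eta > 0 || eta == 0, eta <= 1, gamma_disc >= 0, gamma_disc < 1)
  (1 - eta) * Q + eta * (r + gamma_disc * max_next_Q)
}

shift_q_weights <- function(q, eps = 0.05) {
  q - min(min(q), 0) + eps
}

#' Sample an action proportionally to its (shifted) Q value
#'
#' Training-phase selection: `Prob(a) = Q_a / sum(Q)`. Because learned Q
#' values derive from rewards in (-1, 1) they can be negative, the values
#' are shifted by their negative part and a small floor `eps` is always
#' added before normalizing. The floor keeps every action reachable (plain
#' proportionality would starve zero-valued actions forever) while leaving
#' the proportions of well-separated values essentially unchanged.
#' Optional multiplicative prior weights (`bias`) are applied after the
#' shift; if every weight is zero the choice is uniform.
#'
#' @param q_values named numeric vector of per-action Q values.
#' @param bias optional non-negative prior weights of the same length.
#' @param eps exploration floor added after the shift.
#' @return the selected action name (or index if unnamed).
#' @export
select_action_train <- function(q_values, bias = NULL, eps = 0.05) {
  stopifnot(length(q_values) >= 1L)
  w <- shift_q_weights(q_values, eps)
  if (!is.null(bias)) {
    stopifnot(length(bias) == length(q_values), all(bias >= 0))
    w <- w * bias
  }
  if (sum(w) <= 0) w <- rep(1, length(w)) * (if (is.null(bias)) 1 else (bias > 0))
  if (sum(w) <= 0) w <- rep(1, length(w))
  i <- sample.int(length(w), 1L, prob = w)
  if (is.null(names(q_values))) i else names(q_values)[i]
}

#' Pick the highest-Q action
#'
#' Test-phase selection: argmax over the (optionally bias-masked) Q values;
#' ties are broken uniformly at random from the current RNG stream.
#'
#' @inheritParams select_action_train
#' @return the selected action name (or index if unnamed).
#' @export
select_action_test <- function(q_values, bias = NULL) {
  stopifnot(length(q_values) >= 1L)
  q <- q_values
  if (!is.null(bias)) {
    stopifnot(length(bias) == length(q_values))
    q[bias <= 0] <- -Inf
    if (all(is.infinite(q))) q <- q_values
  }
  top <- which(q == max(q))
  i <- if (length(top) == 1L) top else top[sample.int(length(top), 1L)]
  if (is.null(names(q_values))) i else names(q_values)[i]
}

#' Sliding experience window
#'
#' The training dataset of the learning engine: a FIFO buffer of experience
#' samples (state vector, action, Q value, reward, macro step), capped at
#' capacity `d`; the newest samples constitute the train set and the oldest
#' are evicted first.
#'
#' @param capacity window size `d` (>= 1).
#' @param state_vars character vector naming (and ordering) the state-vector
#'   layout; the layout is versioned into dataset exports.
#' @return an `experience_window`.
#' @export
new_experience_window <- function(capacity, state_vars) {
  stopifnot(capacity >= 1, length(state_vars) >= 1)
  structure(list(capacity = as.integer(capacity), state_vars = state_vars,
                 state = matrix(numeric(0), ncol = length(state_vars),
                                dimnames = list(NULL, state_vars)),
                 action = character(0), q = numeric(0), reward = numeric(0),
                 step = integer(0)),
            class = "experience_window")
}

window_size <- function(window) length(window$action)

#' Admit an experience into the window
#'
#' The sample is appended only when its reward strictly exceeds the
#' admission threshold `theta`; when the window is full the oldest sample is
#' evicted.
#'
#' @param window an [new_experience_window()] object.
#' @param state named numeric state vector (must cover the window layout).
#' @param action action label.
#' @param q the sample's Q value (finite).
#' @param reward the observed reward.
#' @param theta admission threshold (admit iff `reward > theta`).
#' @param step macro-step index.
#' @return the updated window.
#' @export
admit_experience <- function(window, state, action, q, reward, theta,
                             step = NA_integer_) {
  stopifnot(is.finite(q))
  if (!(reward > theta)) return(window)
  sv <- unlist(state)[window$state_vars]
  sv[is.na(sv)] <- 0
  window$state <- rbind(window$state, sv, deparse.level = 0)
  window$action <- c(window$action, action)
  window$q <- c(window$q, q)
  window$reward <- c(window$reward, reward)
  window$step <- c(window$step, as.integer(step))
  overflow <- window_size(window) - window$capacity
  if (overflow > 0) {
    keep <- seq.int(overflow + 1L, window_size(window))
    window$state <- window$state[keep, , drop = FALSE]
    window$action <- window$action[keep]
    window$q <- window$q[keep]
    window$reward <- window$reward[keep]
    window$step <- window$step[keep]
  }
  window
}

admit_batch <- function(window, states, actions, qs, rewards, theta, step) {
  ok <- which(rewards > theta & is.finite(qs))
  for (i in ok)
    window <- admit_experience(window, states[i, , drop = TRUE], actions[i],
                               qs[i], rewards[i], theta, step)
  window
}

#' Tabular Q store
#'
#' An exact state-action value table for small discrete problems: the
#' tabular-capable special case of the value-function representation, used
#' to exercise the learning loop on toy Markov decision processes.
#'
#' @param default initial Q value for unseen pairs.
#' @return a `q_table` with `get(state, action)`, `set(state, action, q)`
#'   and `predict(state, actions)` closures.
#' @export
new_q_table <- function(default = 0) {
  tab <- new.env(parent = emptyenv())
  key <- function(s, a) paste(s, a, sep = "\r")
  list(
    get = function(s, a) get0(key(s, a), envir = tab, ifnotfound = default),
    set = function(s, a, q) assign(key(s, a), q, envir = tab),
    predict = function(s, actions)
      vapply(actions, function(a) get0(key(s, a), envir = tab,
                                       ifnotfound = default),
             numeric(1))
  )
}

#' Run the Q-learning training loop on a generic environment
#'
#' The train-phase step sequence on a single-agent environment: read the
#' state, predict Q for every allowed action, sample an action
#' proportionally to shifted Q, advance the environment, observe the reward,
#' and apply the Q update. This is the same decision plumbing the tumor
#' simulator drives per cell; exposed separately so the learning dynamics
#' can be verified on small Markov decision processes with a tabular store.
#'
#' @param env environment list with `reset()` -> state id, `actions(state)`
#'   -> action names, and `step(state, action)` -> `list(state, reward)`.
#' @param n_steps number of interaction steps.
#' @param eta,gamma_disc learning rate and discount.
#' @param qstore a Q store (default a fresh [new_q_table()]).
#' @param eps proportional-sampling floor.
#' @return list with `qstore` and a trace data.frame
#'   (`step`, `state`, `action`, `reward`).
#' @export
q_learning_train <- function(env, n_steps, eta = 0.5, gamma_disc = 0.9,
                             qstore = new_q_table(), eps = 0.05) {
  s <- env$reset()
  trace <- vector("list", n_steps)
  for (t in seq_len(n_steps)) {
    acts <- env$actions(s)
    qv <- qstore$predict(s, acts)
    names(qv) <- acts
    a <- select_action_train(qv, eps = eps)
    nxt <- env$step(s, a)
    next_q <- max(qstore$predict(nxt$state, env$actions(nxt$state)))
    qstore$set(s, a, q_update(qstore$get(s, a), nxt$reward, next_q,
                              eta, gamma_disc))
    trace[[t]] <- data.frame(step = t, state = s, action = a,
                             reward = nxt$reward)
    s <- nxt$state
  }
  list(qstore = qstore, trace = do.call(rbind, trace))
}

#' Greedy policy of a Q store over an environment's states
#' @param qstore a Q store.
#' @param states state ids.
#' @param actions_fn `function(state)` -> allowed action names.
#' @return named character vector of greedy actions.
#' @export
greedy_policy <- function(qstore, states, actions_fn) {
  vapply(states, function(s) {
    q <- qstore$predict(s, actions_fn(s))
    names(q)[which.max(q)] %||% actions_fn(s)[which.max(q)]
  }, character(1))
}
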