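#' @title Simulation configuration
#' @name config
#' @description
#' Every model constant and threshold lives in a single nested configuration
#' list of class `oncosim_config`, organized in five sections:
#'
#' \describe{
#'   \item{geometry}{lattice dimensions `nx, ny, nz` (sites), spacing `dS`
#'     (micrometers), vessel radii `r_art`, `r_cap` (micrometers), and the
#'     parent-vessel layout switch `arteries_at` (`"faces"` places the four
#'     arteries on the vertical mid-face lines and the four veins on the
#'     vertical edges; `"edges"` swaps them).}
#'   \item{fields}{per-species transport constants: diffusion coefficient `D`
#'     (um^2/h), vessel-wall permeability `Pe` (um/h, oxygen/glucose/VEGF),
#'     intravascular concentrations `rho_art`, `rho_cap` (a.u., oxygen and
#'     glucose), constant per-cell production `SO` (a.u./h, TGF-alpha and
#'     TNF-alpha), decay `omega` (1/h, VEGF), cancer-cell base uptake
#'     `beta_c` (1/h), normal-cell uptake `alpha_n` (1/h), and cancer-cell
#'     VEGF base production `phi_c` (a.u./h).}
#'   \item{agent}{phenotype thresholds: hypoxia oxygen threshold and counter
#'     limit, healthy-cell division limit, proliferation oxygen minimum and
#'     cell-cycle length (hours), glucose dead/active thresholds, tip
#'     maturation age `psi` (hours), initialization probabilities and tumor
#'     seed radius (micrometers), VEGF sprouting threshold.}
#'   \item{learning}{Q-learning rate `eta`, discount `gamma_disc`, reward
#'     admission threshold `theta`, sliding-window size `window`, SVR
#'     hyperparameter search ranges and NSGA-II budget, which cell types
#'     learn, and the policy bias strength.}
#'   \item{run}{horizon (macro steps of one hour), snapshot cadence, master
#'     seed.}
#' }
#'
#' All concentrations are in normalized arbitrary units with the arterial
#' intravascular level at 1. Numeric values are implementation defaults
#' chosen for biological plausibility (see the methods vignette), not
#' measured constants.
NULL

#' Default simulation configuration
#'
#' Returns the fully-resolved default configuration: a 40 x 40 x 40 lattice
#' at 20 um spacing, a 504-hour (21-day) horizon, eight parent vessels, and
#' documented defaults for every transport, agent, policy, and learning
#' constant.
#'
#' @param ... named overrides applied on top of the defaults, using the same
#'   nesting as the sections above, e.g.
#'   `default_config(geometry = list(nx = 20, ny = 20, nz = 20))`.
#' @return a validated `oncosim_config` object.
#' @examples
#' cfg <- default_config()
#' cfg$geometry$nx             # 40
#' cfg$run$horizon             # 504
#' @export
default_config <- function(...) {
  cfg <- list(
    geometry = list(
      nx = 40L, ny = 40L, nz = 40L,
      dS = 20,          # um, approximately one cell diameter
      r_art = 6,        # um, arteriole radius (12 um vessels)
      r_cap = 4,        # um, capillary radius (8 um vessels)
      arteries_at = "faces"
    ),
    fields = list(
      # Warburg-scale tumor uptake excess; normal demand high enough that
      # the avascular interior of the tissue block sits at the hypoxic
      # margin (Krogh-type diffusion limit)
      oxygen  = list(D = 400, Pe = 5, rho_art = 1.0, rho_cap = 0.6,
                     beta_c = 0.4,  alpha_n = 0.10),
      glucose = list(D = 400, Pe = 5, rho_art = 1.0, rho_cap = 0.6,
                     beta_c = 0.25, alpha_n = 0.05),
      tgfa    = list(D = 100, SO = 0.02),
      tnfa    = list(D = 100, SO = 0.005),
      vegf    = list(D = 200, Pe = 5, omega = 0.1, phi_c = 0.05)
    ),
    agent = list(
      hypoxia_o2_threshold = 0.1,   # a.u. oxygen below which a cell is hypoxic
      hypoxia_counter_limit = 48,   # hours a (tumor) cell endures hypoxia
                                    # before necrosis
      hypoxia_death_prob = 0.3,     # per-hour death chance of a hypoxic
                                    # healthy cell (cancer endures to the limit)
      division_limit = 10,          # healthy-cell division budget
      prolif_o2_min = 0.05,         # a.u. oxygen needed to complete division
                                    # (glycolytic cells divide in mild hypoxia)
      cycle_hours = 0,              # optional minimal cell-cycle gate, hours
                                    # (0 = division limited only by oxygen,
                                    # space and the decision policy)
      glucose_dead = 0.05,          # a.u.
      glucose_active = 0.2,         # a.u.
      tip_maturity = 10,            # psi, hours before a tip may branch
      tnfa_death_threshold = 0.2,   # a.u.
      vegf_sprout_threshold = 0.05, # a.u. VEGF at a vessel wall to sprout
                                    # (the wall level an established hypoxic
                                    # tumor sustains at the domain scale)
      sprout_prob = 0.1,            # per eligible parent-vessel site per hour
                                    # (each wall site initiates at most once:
                                    # lateral inhibition)
      init_p_cancer = 0.7,
      init_p_healthy = 0.7,
      seed_radius_um = 60,          # tumor seed sphere radius
      nutrient_init_sigma = 5,      # sites, width of initial perivascular profile
      nutrient_init_amp = 1.0,      # a.u., peak of the initial profile
      nutrient_init_floor = 0.2,    # a.u., baseline far from vessels
                                    # (homeostatic tissue starts viable)
      necrotic_uptake = TRUE        # necrotic debris consumes at beta_c/8 as written
    ),
    learning = list(
      eta = 0.5, gamma_disc = 0.8, theta = 0,
      window = 200, min_window = 50, refit_every = 100,
      enabled_types = "cancerous",
      q_floor_eps = 0.05,           # floor added after min-shift in prop. sampling
      bias_strength = 4,            # multiplicative policy-bias factor
      svr_ranges = list(C = c(0.01, 100), epsilon = c(0.001, 0.5),
                        gamma = c(0.001, 10)),
      nsga_pop = 8L, nsga_generations = 3L, cv_folds = 3L
    ),
    policy = default_policy_rules(),
    run = list(horizon = 504L, dt_hours = 1, snapshot_every = 50L, seed = 1L)
  )
  over <- list(...)
  if (length(over)) {
    stopifnot(!is.null(names(over)), all(nzchar(names(over))))
    cfg <- modifyList(cfg, over)
  }
  class(cfg) <- "oncosim_config"
  validate_config(cfg)
}

#' Default phenotype policy rules
#'
#' The ten policy rules linking state variables to phenotype preferences.
#' Each rule carries the state variable it reads, a threshold and gradient
#' for the tanh reward term, a direction (+1 when larger values of the
#' variable favor survival, -1 otherwise), the cell types it applies to, and
#' the actions it favors when triggered. Rules with two-sided or banded
#' logic (glucose, hypoxia duration, tip maturity) are handled by
#' [policy_bias()] using these thresholds plus the agent section.
#'
#' @return a list of 10 policy rule lists.
#' @export
default_policy_rules <- function() {
  rule <- function(id, variable, threshold, gradient, direction, types, favored)
    list(id = id, variable = variable, threshold = threshold,
         gradient = gradient, direction = direction, types = types,
         favored = favored)
  list(
    rule(1L, "oxygen",          0.1,   0.05, +1, c("cancerous", "healthy"),
         c("proliferation", "migration")),   # favored when above threshold
    rule(2L, "glucose",         0.125, 0.1,  +1, c("cancerous", "healthy"),
         c("proliferation", "migration")),
    rule(3L, "division_counter", 10,   2,    -1, "healthy", "quiescence"),
    rule(4L, "prolif_delay",     6,    2,    -1, c("cancerous", "healthy"),
         c("hypoxia", "necrosis", "apoptosis")),
    rule(5L, "hypoxia_counter",  12,   3,    -1, c("cancerous", "healthy"),
         c("necrosis", "apoptosis")),
    rule(6L, "plcg",             0.5,  0.25, +1, c("cancerous", "healthy"),
         "proliferation"),
    rule(7L, "n_moore_nb",       13,   4,    -1, c("cancerous", "healthy"),
         "migration"),
    rule(8L, "tnfa",             0.2,  0.1,  -1, c("cancerous", "healthy"),
         c("necrosis", "apoptosis")),
    rule(9L, "vegf",             0.1,  0.05, +1, "stalk", "sprout"),
    rule(10L, "tip_age",         10,   3,    +1, "tip", "branch")
  )
}

fail_key <- function(key, constraint) {
  stop(sprintf("config invariant violated: `%s` %s", key, constraint),
       call. = FALSE)
}

check_range <- function(x, key, lo = -Inf, hi = Inf, lo_open = FALSE,
                        hi_open = FALSE) {
  if (is.null(x) || length(x) != 1L || !is.finite(x))
    fail_key(key, "must be a single finite number")
  if (x < lo || (lo_open && x == lo))
    fail_key(key, sprintf("must be %s %s", if (lo_open) ">" else ">=", lo))
  if (x > hi || (hi_open && x == hi))
    fail_key(key, sprintf("must be %s %s", if (hi_open) "<" else "<=", hi))
  invisible(x)
}

#' Validate a simulation configuration
#'
#' Checks every structural and numeric invariant of the configuration;
#' failures name the offending key and the violated constraint.
#'
#' @param config an `oncosim_config` (or plain list with the same shape).
#' @return the config, invisibly classed as `oncosim_config`.
#' @export
validate_config <- function(config) {
  g <- config$geometry
  for (k in c("nx", "ny", "nz"))
    check_range(g[[k]], paste0("geometry.", k), lo = 1)
  check_range(g$dS, "geometry.dS", lo = 0, lo_open = TRUE)
  check_range(g$r_art, "geometry.r_art", lo = 0)
  check_range(g$r_cap, "geometry.r_cap", lo = 0, hi = g$r_art)
  if (!g$arteries_at %in% c("faces", "edges"))
    fail_key("geometry.arteries_at", "must be 'faces' or 'edges'")

  needed <- list(
    oxygen  = c("D", "Pe", "rho_art", "rho_cap", "beta_c", "alpha_n"),
    glucose = c("D", "Pe", "rho_art", "rho_cap", "beta_c", "alpha_n"),
    tgfa    = c("D", "SO"),
    tnfa    = c("D", "SO"),
    vegf    = c("D", "Pe", "omega", "phi_c")
  )
  for (sp in names(needed)) {
    fp <- config$fields[[sp]]
    if (is.null(fp)) fail_key(paste0("fields.", sp), "must be present")
    for (k in needed[[sp]])
      check_range(fp[[k]], paste0("fields.", sp, ".", k), lo = 0)
    extra <- setdiff(names(fp), needed[[sp]])
    if (length(extra))
      fail_key(paste0("fields.", sp, ".", extra[1]),
               "does not apply to this species")
  }

  a <- config$agent
  for (k in c("hypoxia_o2_threshold", "prolif_o2_min", "glucose_dead",
              "glucose_active", "tnfa_death_threshold",
              "vegf_sprout_threshold", "nutrient_init_sigma",
              "nutrient_init_amp", "nutrient_init_floor", "seed_radius_um"))
    check_range(a[[k]], paste0("agent.", k), lo = 0)
  for (k in c("hypoxia_counter_limit", "division_limit", "cycle_hours",
              "tip_maturity"))
    check_range(a[[k]], paste0("agent.", k), lo = 0)
  check_range(a$glucose_active, "agent.glucose_active", lo = a$glucose_dead)
  for (k in c("init_p_cancer", "init_p_healthy", "sprout_prob",
              "hypoxia_death_prob"))
    check_range(a[[k]], paste0("agent.", k), lo = 0, hi = 1)

  l <- config$learning
  check_range(l$eta, "learning.eta", lo = 0, lo_open = TRUE, hi = 1)
  check_range(l$gamma_disc, "learning.gamma_disc", lo = 0, hi = 1,
              hi_open = TRUE)
  check_range(l$window, "learning.window", lo = 1)
  check_range(l$min_window, "learning.min_window", lo = 1)
  check_range(l$refit_every, "learning.refit_every", lo = 1)
  check_range(l$theta, "learning.theta")
  check_range(l$q_floor_eps, "learning.q_floor_eps", lo = 0, lo_open = TRUE)
  check_range(l$bias_strength, "learning.bias_strength", lo = 1)
  for (k in c("C", "epsilon", "gamma")) {
    r <- l$svr_ranges[[k]]
    if (is.null(r) || length(r) != 2L || r[1] > r[2] || any(r < 0))
      fail_key(paste0("learning.svr_ranges.", k),
               "must be a non-negative increasing pair")
  }
  check_range(l$nsga_pop, "learning.nsga_pop", lo = 4)
  check_range(l$nsga_generations, "learning.nsga_generations", lo = 1)
  bad <- setdiff(l$enabled_types, c("cancerous", "healthy", "tip", "stalk"))
  if (length(bad))
    fail_key("learning.enabled_types", "must name known cell types")

  state_vars <- c("oxygen", "glucose", "division_counter", "prolif_delay",
                  "hypoxia_counter", "plcg", "n_healthy_nb", "n_cancer_nb",
                  "n_moore_nb", "tnfa", "vegf", "tip_age")
  for (rl in config$policy) {
    key <- paste0("policy.rule", rl$id)
    check_range(rl$gradient, paste0(key, ".gradient"), lo = 0, lo_open = TRUE)
    check_range(rl$threshold, paste0(key, ".threshold"))
    if (!rl$direction %in% c(-1, 1))
      fail_key(paste0(key, ".direction"), "must be +1 or -1")
    if (!rl$variable %in% state_vars)
      fail_key(paste0(key, ".variable"), "must be a known state variable")
    union_allowed <- unique(unlist(lapply(rl$types, allowed_actions)))
    badact <- setdiff(rl$favored, union_allowed)
    if (length(badact))
      fail_key(paste0(key, ".favored"),
               sprintf("action '%s' not allowed for any of types %s",
                       badact[1], paste(rl$types, collapse = "/")))
  }

  check_range(config$run$horizon, "run.horizon", lo = 0)
  check_range(config$run$dt_hours, "run.dt_hours", lo = 0, lo_open = TRUE)
  check_range(config$run$snapshot_every, "run.snapshot_every", lo = 1)
  class(config) <- "oncosim_config"
  invisible(config)
}

#' Load a simulation configuration from a YAML file
#'
#' Reads a (possibly partial) YAML configuration, fills every missing key
#' with the documented default, validates all invariants, and returns the
#' fully resolved configuration. A minimal file containing only, say, the
#' grid dimensions therefore yields a complete runnable config.
#'
#' @param path path to a YAML file.
#' @return a validated `oncosim_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  known <- c("geometry", "fields", "agent", "learning", "policy", "run")
  unknown <- setdiff(names(user), known)
  if (length(unknown))
    stop("unknown config key: ", unknown[1], call. = FALSE)
  cfg <- unclass(default_config())
  if (!is.null(user$policy)) {
    cfg$policy <- lapply(seq_along(cfg$policy), function(i) {
      u <- Filter(function(r) identical(as.integer(r$id), as.integer(i)),
                  user$policy)
      if (length(u)) modifyList(cfg$policy[[i]], u[[1]]) else cfg$policy[[i]]
    })
    user$policy <- NULL
  }
  cfg <- modifyList(cfg, user)
  class(cfg) <- "oncosim_config"
  validate_config(cfg)
}

#' Write a configuration to YAML
#'
#' The inverse of [load_config()]: `load_config(write_config(cfg, path))`
#' reproduces `cfg` field for field. A resolved-config echo written this way
#' accompanies every run directory for provenance.
#'
#' @param config an `oncosim_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' Sub-step count for stable explicit diffusion
#'
#' The explicit 26-neighbor scheme is stable when `D * dt / dS^2 <= 1/26`.
#' Given a macro time step (one hour by default), this returns the minimal
#' number of equal sub-steps `n_sub` and their duration `dt_diff` such that
#' `n_sub * dt_diff = dt_macro` and the stability bound holds.
#'
#' @param field a per-species field parameter list (with `D`) or a single
#'   diffusion coefficient.
#' @param dS lattice spacing (same length unit as `D`).
#' @param dt_macro macro step duration (same time unit as `D`).
#' @return list with `n_sub` (integer) and `dt_diff`.
#' @examples
#' resolve_substep(0, 20, 1)                   # no diffusion: one sub-step
#' resolve_substep(400, 20, 1)$n_sub           # lambda = 1 -> 26 sub-steps
#' @export
resolve_substep <- function(field, dS, dt_macro) {
  D <- if (is.list(field)) field$D else field
  stopifnot(D >= 0, dS > 0, dt_macro > 0)
  lam <- D * dt_macro / dS^2
  n_sub <- max(1L, as.integer(ceiling(26 * lam - 1e-12)))
  list(n_sub = n_sub, dt_diff = dt_macro / n_sub)
}

#' @export
print.oncosim_config <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("<oncosim_config> %d x %d x %d lattice, dS = %g um, horizon %d h, seed %d\n",
              g$nx, g$ny, g$nz, g$dS, x$run$horizon, x$run$seed))
  invisible(x)
}
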