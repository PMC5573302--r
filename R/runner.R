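#' State-vector layout per cell type
#'
#' Fixed, versioned orderings of the per-type state variables used in the
#' experience dataset and regressor features: tissue cells carry local
#' oxygen, glucose, the division counter (healthy only), proliferation time
#' delay, hypoxia counter, PLC-gamma, healthy/cancerous Moore-neighbor
#' counts and local TNF-alpha; vessel cells carry local VEGF and tip-cell
#' age.
#'
#' @param celltype cell type.
#' @return character vector of state-variable names, in layout order.
#' @export
state_vars_for <- function(celltype) {
  switch(celltype,
    healthy = c("oxygen", "glucose", "division_counter", "prolif_delay",
                "hypoxia_counter", "plcg", "n_healthy_nb", "n_cancer_nb",
                "tnfa"),
    cancerous = c("oxygen", "glucose", "prolif_delay", "hypoxia_counter",
                  "plcg", "n_healthy_nb", "n_cancer_nb", "tnfa"),
    tip = c("vegf", "tip_age"),
    stalk = c("vegf", "tip_age"),
    stop("unknown cell type: ", celltype, call. = FALSE))
}

DATASET_SCHEMA <- "oncolattice-dataset-v1"
TRACE_SCHEMA <- "oncolattice-trace-v1"

row_mins <- function(M) {
  out <- M[, 1]
  for (j in seq_len(ncol(M))[-1]) out <- pmin(out, M[, j])
  out
}

# Vectorized proportional sampling over rows of weight matrix W (>= 0).
sample_rows <- function(W) {
  tot <- rowSums(W)
  bad <- tot <= 0
  if (any(bad)) { W[bad, ] <- 1; tot[bad] <- ncol(W) }
  u <- runif(nrow(W)) * tot
  cum <- W
  for (j in seq_len(ncol(W))[-1]) cum[, j] <- cum[, j] + cum[, j - 1]
  1L + rowSums(cum < u)
}

# Per-type decision states (layout vars + bias helper columns).
decision_states <- function(world, rows) {
  cc <- world$cells
  ty <- cc$type[rows[1]]
  vars <- state_vars_for(ty)
  df <- as.data.frame(lapply(vars, function(v) cc[[v]][rows]))
  names(df) <- vars
  if (ty %in% c("healthy", "cancerous")) {
    tis <- which(cc$alive & cc$type %in% c("healthy", "cancerous"))
    n <- length(tis)
    tot <- sum(cc$plcg[tis])
    df$plcg_mean_others <- if (n > 1L) (tot - cc$plcg[rows]) / (n - 1L) else 0
    df$death_signal <- cc$death_signal[rows]
  }
  df
}

signaling_phase <- function(world, dt) {
  cc <- world$cells
  rows <- which(cc$alive & cc$type %in% c("healthy", "cancerous"))
  if (!length(rows)) return(invisible(NULL))
  s <- cc$site[rows]
  # EGFR: TGF-alpha -> PLC-gamma
  L <- world$fields$tgfa$C[s]
  r <- integrate_pathway("egfr_surrogate",
                         cbind(cc$sig_egfr1[rows], cc$sig_egfr2[rows]), L, dt)
  world$cells$sig_egfr1[rows] <- r$S[, 1]
  world$cells$sig_egfr2[rows] <- r$S[, 2]
  world$cells$plcg[rows] <- r$out
  world$fields$tgfa$C[s] <- pmax(world$fields$tgfa$C[s] - r$consumed, 0)
  # TNF: TNF-alpha -> death signal
  L2 <- world$fields$tnfa$C[s]
  r2 <- integrate_pathway("tnf_surrogate",
                          cbind(cc$sig_tnf1[rows], cc$sig_tnf2[rows]), L2, dt)
  world$cells$sig_tnf1[rows] <- r2$S[, 1]
  world$cells$sig_tnf2[rows] <- r2$S[, 2]
  world$cells$death_signal[rows] <- r2$out
  world$fields$tnfa$C[s] <- pmax(world$fields$tnfa$C[s] - r2$consumed, 0)
  invisible(NULL)
}

refresh_states <- function(world, dt) {
  cc <- world$cells
  lat <- world$lat
  a <- world$config$agent
  tis <- which(cc$alive & cc$type %in% c("healthy", "cancerous"))
  if (length(tis)) {
    s <- cc$site[tis]
    world$cells$oxygen[tis] <- world$fields$oxygen$C[s]
    world$cells$glucose[tis] <- world$fields$glucose$C[s]
    world$cells$tnfa[tis] <- world$fields$tnfa$C[s]
    world$cells$prolif_clock[tis] <- cc$prolif_clock[tis] + dt
    hyp <- world$fields$oxygen$C[s] < a$hypoxia_o2_threshold
    world$cells$hypoxia_counter[tis] <-
      ifelse(hyp, cc$hypoxia_counter[tis] + 1L, 0L)
    # Moore-neighbor type counts from indicator stencils
    n_in <- world$n_inbounds
    h_ind <- numeric(lat$n); c_ind <- numeric(lat$n)
    hrows <- tis[cc$type[tis] == "healthy"]
    crows <- tis[cc$type[tis] == "cancerous"]
    h_ind[cc$site[hrows]] <- 1
    c_ind[cc$site[crows]] <- 1
    sth <- cpp_nb_stats(h_ind, lat$nb)
    stc <- cpp_nb_stats(c_ind, lat$nb)
    world$cells$n_healthy_nb[tis] <- as.integer(round(sth$mean[s] * n_in[s]))
    world$cells$n_cancer_nb[tis] <- as.integer(round(stc$mean[s] * n_in[s]))
  }
  ves <- which(cc$alive & cc$type %in% c("tip", "stalk"))
  if (length(ves)) {
    world$cells$vegf[ves] <- world$fields$vegf$C[cc$site[ves]]
    world$cells$tip_age[ves] <- cc$tip_age[ves] + dt
  }
  invisible(NULL)
}

# Apply the chosen actions of all cell types in one synchronous batch:
# movement/birth proposals are computed for every mover against the
# start-of-step occupancy, all claims are resolved in a single global
# competition (so cancerous claimants beat healthy ones on shared sites),
# and only then are the world mutations applied.
apply_all_actions <- function(world, decisions) {
  cc <- world$cells
  a <- world$config$agent
  births <- 0L; removals <- 0L

  # --- proposal phase: read-only against pristine occupancy -------------
  p_row <- integer(0); p_act <- character(0); p_tgt <- integer(0)
  quiesce_rows <- integer(0)   # blocked proliferation -> absorbing rest
  postpone_rows <- integer(0)  # ineligible proliferation -> delay + 1
  for (d in decisions) {
    ty <- d$type
    movers <- d$rows[d$actions %in% c("migration", "proliferation",
                                      "expansion", "sprout")]
    macts <- d$actions[d$actions %in% c("migration", "proliferation",
                                        "expansion", "sprout")]
    if (length(movers)) {
      bt <- batch_select_targets(world, cc$site[movers], ty)
      prolif <- macts == "proliferation"
      # blocked proliferation: absorbing rest; ineligible: delay + 1
      quiesce_rows <- c(quiesce_rows, movers[prolif & !bt$has_free])
      inel <- prolif & bt$has_free &
        (cc$prolif_clock[movers] < a$cycle_hours |
           cc$oxygen[movers] < a$prolif_o2_min)
      postpone_rows <- c(postpone_rows, movers[inel])
      ok <- !is.na(bt$target) & !(prolif & (!bt$has_free | inel))
      p_row <- c(p_row, movers[ok])
      p_act <- c(p_act, macts[ok])
      p_tgt <- c(p_tgt, bt$target[ok])
    }
    branchers <- d$rows[d$actions == "branch"]
    for (r in branchers) {
      free <- free_moore_sites(world, cc$site[r], ty)
      if (length(free) < 2L) next  # blocked branch: idle this step
      st <- get_nbstats(world, "vegf")
      w <- st$mean[free]
      if (sum(w) <= 0) w <- rep(1, length(free))
      pick <- sample.int(length(free), 2L, prob = w / sum(w))
      p_row <- c(p_row, r, r)
      p_act <- c(p_act, "branch", "branch")
      p_tgt <- c(p_tgt, free[pick])
    }
  }
  np <- length(p_row)

  # --- global competition ----------------------------------------------
  won <- NULL
  if (np > 0L) {
    cl <- data.frame(cell = cc$id[p_row[seq_len(np)]],
                     type = cc$type[p_row[seq_len(np)]],
                     site = p_tgt[seq_len(np)],
                     action = p_act[seq_len(np)])
    won <- resolve_competition(cl, world$lat)
  }

  # --- application: mutate local copies, write back once ---------------
  occ <- world$lat$occ; endo <- world$lat$endo
  site <- cc$site; phen <- cc$phenotype; frozen <- cc$frozen
  alive <- cc$alive
  pclock <- cc$prolif_clock; pdelay <- cc$prolif_delay
  divc <- cc$division_counter; hypc <- cc$hypoxia_counter

  for (d in decisions) {
    dr <- d$rows; da <- d$actions
    ap <- dr[da == "apoptosis"]
    if (length(ap)) { occ[site[ap]] <- 0L; alive[ap] <- FALSE
                      removals <- removals + length(ap) }
    ne <- dr[da == "necrosis"]
    if (length(ne)) { occ[site[ne]] <- -1L; alive[ne] <- FALSE
                      removals <- removals + length(ne) }
    qu <- dr[da == "quiescence"]
    if (length(qu)) { phen[qu] <- "quiescence"; frozen[qu] <- TRUE }
    hy <- dr[da == "hypoxia"]
    if (length(hy)) { phen[hy] <- "hypoxia"; hypc[hy] <- hypc[hy] + 1L }
  }
  if (length(quiesce_rows)) {
    phen[quiesce_rows] <- "quiescence"; frozen[quiesce_rows] <- TRUE
  }
  if (length(postpone_rows)) pdelay[postpone_rows] <- pdelay[postpone_rows] + 1L

  b_type <- character(0); b_site <- integer(0); b_parent <- integer(0)
  b_side <- character(0); b_sprout <- integer(0); b_rethread <- integer(0)
  if (!is.null(won) && nrow(won)) {
    wrow <- match(won$cell, cc$id)
    for (k in seq_len(nrow(won))) {
      r <- wrow[k]; act <- won$action[k]; tgt <- won$site[k]
      ty <- cc$type[r]
      if (act == "migration") {
        occ[site[r]] <- 0L; occ[tgt] <- cc$id[r]; site[r] <- tgt
        phen[r] <- "migration"
      } else if (act == "proliferation") {
        b_type <- c(b_type, ty); b_site <- c(b_site, tgt)
        b_parent <- c(b_parent, 0L); b_side <- c(b_side, "")
        b_sprout <- c(b_sprout, 0L); b_rethread <- c(b_rethread, NA_integer_)
        phen[r] <- "proliferation"; pclock[r] <- 0
        if (ty == "healthy") divc[r] <- divc[r] + 1L
      } else if (act == "expansion") {
        old <- site[r]
        endo[old] <- endo[old] - 1L; endo[tgt] <- endo[tgt] + 1L
        site[r] <- tgt; phen[r] <- "expansion"
        b_type <- c(b_type, "stalk"); b_site <- c(b_site, old)
        b_parent <- c(b_parent, cc$parent[r])
        b_side <- c(b_side, cc$root_side[r])
        b_sprout <- c(b_sprout, cc$sprout_id[r])
        b_rethread <- c(b_rethread, r)  # tip re-parents onto the new stalk
      } else if (act == "sprout") {
        phen[r] <- "sprout"
        b_type <- c(b_type, "stalk"); b_site <- c(b_site, tgt)
        b_parent <- c(b_parent, cc$id[r]); b_side <- c(b_side, cc$root_side[r])
        b_sprout <- c(b_sprout, cc$sprout_id[r])
        b_rethread <- c(b_rethread, NA_integer_)
      } else if (act == "branch") {
        phen[r] <- "branch"
        b_type <- c(b_type, ty); b_site <- c(b_site, tgt)
        b_parent <- c(b_parent, cc$id[r]); b_side <- c(b_side, cc$root_side[r])
        b_sprout <- c(b_sprout, cc$sprout_id[r])
        b_rethread <- c(b_rethread, NA_integer_)
      }
    }
    world$branch_count <- world$branch_count +
      length(unique(won$cell[won$action == "branch"]))
  }

  world$lat$occ <- occ; world$lat$endo <- endo
  cc$site <- site; cc$phenotype <- phen; cc$frozen <- frozen
  cc$alive <- alive; cc$prolif_clock <- pclock; cc$prolif_delay <- pdelay
  cc$division_counter <- divc; cc$hypoxia_counter <- hypc
  world$cells <- cc

  # class annotations for moved endothelial cells
  if (!is.null(won) && nrow(won)) {
    mv <- won$action == "expansion"
    if (any(mv)) {
      wrow <- match(won$cell[mv], world$cells$id)
      tgt <- won$site[mv]
      cls <- ifelse(world$cells$root_side[wrow] == "artery",
                    vessel_classes[["arteriole"]], vessel_classes[["venule"]])
      upd <- world$lat$vessel[tgt] == 0L
      world$lat$vessel[tgt[upd]] <- cls[upd]
    }
  }
  # births (grouped by type to batch the appends)
  for (ty in unique(b_type)) {
    sel <- b_type == ty
    ids <- add_cells(world, ty, b_site[sel], parent = b_parent[sel],
                     root_side = b_side[sel], sprout_id = b_sprout[sel])
    births <- births + length(ids)
    rth <- b_rethread[sel]
    if (any(!is.na(rth)))
      world$cells$parent[rth[!is.na(rth)]] <- ids[!is.na(rth)]
  }
  c(births = births, removals = removals)
}

decision_phase <- function(world, mode) {
  cfg <- world$config
  lp <- cfg$learning
  decisions <- list()
  for (ty in c("healthy", "cancerous", "stalk", "tip")) {
    cc <- world$cells
    rows <- which(cc$alive & !cc$frozen & cc$type == ty)
    if (!length(rows)) {
      finalize_pending(world, ty, NULL, NULL)
      next
    }
    acts <- allowed_actions(ty)
    states <- decision_states(world, rows)
    B <- policy_bias_rows(states, cfg$policy, ty, cfg$agent, lp$bias_strength)
    ens <- world$ensembles[[ty]]
    if (!is.null(ens)) {
      Sm <- as.matrix(states[, state_vars_for(ty), drop = FALSE])
      n <- nrow(Sm); A <- length(acts)
      Srep <- Sm[rep(seq_len(n), times = A), , drop = FALSE]
      arep <- rep(acts, each = n)
      qv <- predict_q(ens, Srep, arep)
      Q <- matrix(qv, nrow = n, ncol = A, dimnames = list(NULL, acts))
    } else {
      Q <- matrix(0, nrow = length(rows), ncol = length(acts),
                  dimnames = list(NULL, acts))
    }
    qmax <- apply(Q, 1, max)
    finalize_pending(world, ty, cc$id[rows], qmax)
    if (mode == "test" && !is.null(ens)) {
      M <- Q
      M[B <= 0] <- -Inf
      allbad <- !is.finite(apply(M, 1, max))
      if (any(allbad)) M[allbad, ] <- Q[allbad, ]
      pick <- max.col(M, ties.method = "random")
    } else {
      # shifted-Q proportional sampling times the policy-bias prior; with
      # all-zero Q (cold start) this reduces to the bias prior alone
      W <- (Q - pmin(row_mins(Q), 0) + lp$q_floor_eps) * B
      pick <- sample_rows(W)
    }
    chosen <- acts[pick]
    q_taken <- Q[cbind(seq_along(pick), pick)]
    decisions[[ty]] <- list(type = ty, rows = rows, actions = chosen,
                            states = states, q_taken = q_taken,
                            ids = cc$id[rows])
  }
  counts <- apply_all_actions(world, decisions)
  if (mode == "train") {
    for (ty in intersect(names(decisions), lp$enabled_types)) {
      d <- decisions[[ty]]
      # reward from the post-action condition; removed cells keep their
      # decision-time state (their terminal condition)
      post <- d$states
      alive_now <- world$cells$alive[d$rows]
      if (any(alive_now))
        post[alive_now, ] <- decision_states(world, d$rows[alive_now])
      rew <- total_reward_rows(post, cfg$policy, ty)
      world$pending[[ty]] <- list(
        ids = d$ids,
        states = as.matrix(d$states[, state_vars_for(ty), drop = FALSE]),
        actions = d$actions, q = d$q_taken, rewards = rew)
    }
  }
  counts
}

# Complete last step's experiences now that this step's Q probes exist:
# q <- (1-eta) q + eta (r + gamma max_a' Q(s', a')); admit when r > theta.
finalize_pending <- function(world, ty, ids_now, qmax_now) {
  p <- world$pending[[ty]]
  if (is.null(p)) return(invisible(NULL))
  lp <- world$config$learning
  mnq <- numeric(length(p$ids))
  if (!is.null(ids_now)) {
    m <- match(p$ids, ids_now)
    mnq[!is.na(m)] <- qmax_now[m[!is.na(m)]]
  }
  qn <- q_update(p$q, p$rewards, mnq, lp$eta, lp$gamma_disc)
  w <- world$windows[[ty]]
  if (!is.null(w))
    world$windows[[ty]] <- admit_batch(w, p$states, p$actions, qn, p$rewards,
                                       lp$theta, world$step)
  world$pending[[ty]] <- NULL
  invisible(NULL)
}

# Hard physiological limits, applied to every live tissue cell (quiescence
# bars a return to active phenotypes, not death): glucose below the dead
# threshold, hypoxia beyond the counter limit, or a committed death signal
# kill the cell outright (rules 2, 5, 8); additionally a hypoxic healthy
# cell has only a small chance of surviving each hour (rule 5), while
# hypoxia-adapted cancer cells endure until the counter limit.
env_mortality <- function(world) {
  cc <- world$cells
  a <- world$config$agent
  rows <- which(cc$alive & cc$type %in% c("healthy", "cancerous"))
  if (!length(rows)) return(0L)
  lethal <- cc$hypoxia_counter[rows] > a$hypoxia_counter_limit |
    cc$glucose[rows] < a$glucose_dead |
    cc$death_signal[rows] >= ds_threshold()
  frail <- cc$type[rows] == "healthy" & cc$hypoxia_counter[rows] >= 2L
  lethal <- lethal |
    (frail & runif(length(rows)) < a$hypoxia_death_prob)
  doomed <- rows[lethal]
  if (!length(doomed)) return(0L)
  healthy <- doomed[cc$type[doomed] == "healthy"]
  cancer <- doomed[cc$type[doomed] == "cancerous"]
  world$lat$occ[cc$site[healthy]] <- 0L
  world$lat$occ[cc$site[cancer]] <- -1L  # necrotic debris
  world$cells$alive[doomed] <- FALSE
  length(doomed)
}

trace_row <- function(world, births, removals) {
  cc <- world$cells
  lat <- world$lat
  live <- cc$alive
  nec <- sum(lat$occ == -1L)
  canc <- sum(live & cc$type == "cancerous")
  vessel_sites <- sum(lat$vessel > 0L)
  data.frame(
    step = world$step,
    healthy = sum(live & cc$type == "healthy"),
    cancerous = canc,
    necrotic = nec,
    tumor_burden = canc + nec,
    tip = sum(live & cc$type == "tip"),
    stalk = sum(live & cc$type == "stalk"),
    quiescent_cancer = sum(live & cc$type == "cancerous" & cc$frozen),
    tot_oxygen = sum(world$fields$oxygen$C),
    tot_glucose = sum(world$fields$glucose$C),
    tot_tgfa = sum(world$fields$tgfa$C),
    tot_tnfa = sum(world$fields$tnfa$C),
    tot_vegf = sum(world$fields$vegf$C),
    vessel_sites = vessel_sites,
    vessel_length_um = vessel_sites * lat$dS,
    branch_count = world$branch_count,
    perfused_sites = sum(lat$perfused),
    free_sites = sum(lat$occ == 0L & lat$endo == 0L),
    active_cells = sum(live & !cc$frozen),
    births = births,
    removals = removals
  )
}

#' Advance the world by one macro step
#'
#' One hour of model time: field diffusion (with stable sub-stepping),
#' signaling integration and ligand consumption, per-cell state refresh,
#' the phenotype decision and its synchronous application, sprout
#' initiation, and the perfusion update.
#'
#' @param world a world environment.
#' @param mode `"train"` or `"test"`.
#' @return invisibly, the appended trace row.
#' @export
step_world <- function(world, mode = "train") {
  cfg <- world$config
  dt <- cfg$run$dt_hours
  world$step <- world$step + 1L
  if (is.null(world$n_inbounds))
    world$n_inbounds <- rowSums(world$lat$nb > 0L)
  occ <- site_occupancy(world$lat, world$cells)
  for (sp in names(world$fields))
    world$fields[[sp]] <- advance_field(world$fields[[sp]], world$lat, dt,
                                        occ, cfg$agent$necrotic_uptake)
  signaling_phase(world, dt)
  refresh_nbstats(world)
  refresh_states(world, dt)
  counts <- decision_phase(world, mode)
  counts[["removals"]] <- counts[["removals"]] + env_mortality(world)
  counts[["births"]] <- counts[["births"]] + initiate_sprouts(world)
  update_perfusion(world)
  # flow-induced stabilization: endothelial cells of a perfused vessel stop
  # remodeling (they behave as mature phalanx cells)
  cc <- world$cells
  stab <- which(cc$alive & !cc$frozen & cc$type %in% c("tip", "stalk") &
                world$lat$perfused[cc$site])
  if (length(stab)) world$cells$frozen[stab] <- TRUE
  if (mode == "train") maybe_refit(world)
  tr <- trace_row(world, counts[["births"]], counts[["removals"]])
  world$trace[[length(world$trace) + 1L]] <- tr
  invisible(tr)
}

maybe_refit <- function(world) {
  lp <- world$config$learning
  if (world$step %% lp$refit_every != 0L) return(invisible(NULL))
  for (ty in lp$enabled_types) {
    w <- world$windows[[ty]]
    if (is.null(w) || window_size(w) < max(lp$min_window, 10L)) next
    world$ensembles[[ty]] <- fit_ensemble(
      w, ranges = lp$svr_ranges, pop = lp$nsga_pop,
      generations = lp$nsga_generations,
      seed = stream_seed(world$config$run$seed,
                         paste0("refit_", ty, "_", world$step)),
      action_levels = allowed_actions(ty),
      min_size = max(lp$min_window, 10L), folds = lp$cv_folds)
  }
  invisible(NULL)
}

#' Run the simulation
#'
#' Initializes the world and executes the macro-step loop for the
#' configured horizon (or until no empty site remains for tissue cells),
#' in train mode (proportional action sampling, Q updates, experience
#' admission, periodic ensemble refits) or test mode (greedy argmax over a
#' supplied or previously trained ensemble). All randomness derives from
#' the config seed; the same config and seed reproduce the identical trace.
#'
#' @param config an `oncosim_config`.
#' @param mode `"train"` or `"test"`.
#' @param steps horizon override (default `config$run$horizon`).
#' @param ensembles optional named list of fitted ensembles per cell type
#'   (test mode).
#' @param out_dir optional run directory; when given, the resolved config,
#'   seed record, trace table, experience dataset and periodic snapshots
#'   are written there.
#' @return an `oncosim_run` list: `trace` (data.frame), `world`, `windows`,
#'   `ensembles`, `config`.
#' @export
run_simulation <- function(config, mode = c("train", "test"), steps = NULL,
                           ensembles = NULL, out_dir = NULL) {
  mode <- match.arg(mode)
  validate_config(config)
  steps <- if (is.null(steps)) config$run$horizon else steps
  world <- initialize_world(config)
  if (!is.null(ensembles)) world$ensembles <- ensembles
  for (ty in config$learning$enabled_types)
    world$windows[[ty]] <- new_experience_window(config$learning$window,
                                                state_vars_for(ty))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(config, file.path(out_dir, "config.yaml"))
    writeLines(c(paste("seed:", config$run$seed), paste("mode:", mode)),
               file.path(out_dir, "run_info.txt"))
    export_snapshot(world, file.path(out_dir, "snapshot_000.tsv"))
  }
  set.seed(stream_seed(config$run$seed, paste0("run_", mode)))
  status <- "completed"
  err <- tryCatch({
    for (t in seq_len(steps)) {
      tr <- step_world(world, mode)
      if (!is.null(out_dir) && t %% config$run$snapshot_every == 0L)
        export_snapshot(world,
                        file.path(out_dir, sprintf("snapshot_%03d.tsv", t)))
      if (tr$free_sites == 0L && tr$active_cells == 0L) {
        # true fixed point: the lattice is full and nothing can ever act
        status <- "lattice_full"
        break
      }
    }
    NULL
  }, error = function(e) e)
  trace <- if (length(world$trace)) do.call(rbind, world$trace)
           else trace_row(world, 0L, 0L)[0, ]
  res <- list(trace = trace, world = world, windows = world$windows,
              ensembles = world$ensembles, config = config, mode = mode,
              status = if (is.null(err)) status else "error")
  class(res) <- "oncosim_run"
  if (!is.null(out_dir)) {
    export_timeseries(trace, file.path(out_dir, "trace.tsv"))
    for (ty in names(world$windows))
      export_dataset(world$windows[[ty]],
                     file.path(out_dir, paste0("dataset_", ty, ".tsv")))
    writeLines(c(paste("status:", res$status),
                 if (!is.null(err)) paste("error:", conditionMessage(err)),
                 paste("files:", paste(list.files(out_dir), collapse = " "))),
               file.path(out_dir, "manifest.txt"))
  }
  if (!is.null(err)) stop(err)
  res
}

#' @rdname run_simulation
#' @param n_steps number of macro steps.
#' @export
run_train_phase <- function(config, n_steps = NULL, out_dir = NULL)
  run_simulation(config, "train", steps = n_steps, out_dir = out_dir)

#' @rdname run_simulation
#' @export
run_test_phase <- function(config, ensembles = NULL, n_steps = NULL,
                           out_dir = NULL)
  run_simulation(config, "test", steps = n_steps, ensembles = ensembles,
                 out_dir = out_dir)

#' @export
print.oncosim_run <- function(x, ...) {
  cat(sprintf("<oncosim_run> mode=%s steps=%d status=%s\n", x$mode,
              nrow(x$trace), x$status))
  if (nrow(x$trace)) {
    last <- tail(x$trace, 1)
    cat(sprintf("  final: %d healthy, %d cancerous (+%d necrotic), %d tip, %d stalk, %d branches\n",
                last$healthy, last$cancerous, last$necrotic, last$tip,
                last$stalk, last$branch_count))
  }
  invisible(x)
}

#' Export / import the per-step trace table
#' @param trace trace data.frame from [run_simulation()].
#' @param path file path (tab-separated, with a schema header line).
#' @return `path` / the re-imported data.frame.
#' @export
export_timeseries <- function(trace, path) {
  stopifnot(is.data.frame(trace))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", TRACE_SCHEMA), con)
  suppressWarnings(write.table(trace, con, sep = "\t", row.names = FALSE,
                               quote = FALSE))
  invisible(path)
}

#' @rdname export_timeseries
#' @export
import_timeseries <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#")
}

#' Export a lattice/world snapshot
#'
#' One row per non-trivial site: 0-based coordinates, occupant kind,
#' occupant phenotype, vessel annotation and perfusion flag, plus the five
#' local field concentrations.
#'
#' @param world a world environment.
#' @param path output path (tab-separated).
#' @return `path`, invisibly.
#' @export
export_snapshot <- function(world, path) {
  lat <- world$lat
  cc <- world$cells
  occ_kind <- rep("empty", lat$n)
  occ_kind[lat$occ == -1L] <- "necrotic"
  phen <- rep("", lat$n)
  live <- which(cc$alive)
  occ_kind[cc$site[live[cc$type[live] %in% c("healthy", "cancerous")]]] <-
    cc$type[live[cc$type[live] %in% c("healthy", "cancerous")]]
  phen[cc$site[live]] <- cc$phenotype[live]
  endo_kind <- ifelse(lat$endo > 0L | lat$vessel > 0L,
                      names(vessel_classes)[lat$vessel + 1L], "")
  keep <- which(occ_kind != "empty" | lat$vessel > 0L | lat$endo > 0L)
  xyz <- index_to_coords(lat, keep)
  df <- data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   occupant = occ_kind[keep], phenotype = phen[keep],
                   vessel = endo_kind[keep], endo_count = lat$endo[keep],
                   perfused = lat$perfused[keep],
                   oxygen = world$fields$oxygen$C[keep],
                   glucose = world$fields$glucose$C[keep],
                   tgfa = world$fields$tgfa$C[keep],
                   tnfa = world$fields$tnfa$C[keep],
                   vegf = world$fields$vegf$C[keep])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# oncolattice-snapshot-v1 step=", world$step), con)
  suppressWarnings(write.table(df, con, sep = "\t", row.names = FALSE,
                               quote = FALSE))
  invisible(path)
}

#' Export / import the experience dataset
#'
#' The self-generated learning dataset: one row per admitted experience
#' with the named state variables (layout versioned in the header line),
#' action, Q value, reward and macro step. An empty window produces a
#' header-only file.
#'
#' @param window an [new_experience_window()].
#' @param path file path.
#' @return `path` / the restored window.
#' @export
export_dataset <- function(window, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", DATASET_SCHEMA, " state=",
                    paste(window$state_vars, collapse = ","),
                    " capacity=", window$capacity), con)
  df <- as.data.frame(window$state)
  df$action <- window$action
  df$q <- window$q
  df$reward <- window$reward
  df$step <- window$step
  suppressWarnings(write.table(df, con, sep = "\t", row.names = FALSE,
                               quote = FALSE))
  invisible(path)
}

#' @rdname export_dataset
#' @export
import_dataset <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!grepl(DATASET_SCHEMA, hdr, fixed = TRUE))
    stop("not an oncolattice dataset: ", path, call. = FALSE)
  vars <- strsplit(sub(".*state=([^ ]+).*", "\\1", hdr), ",")[[1]]
  cap <- as.integer(sub(".*capacity=([0-9]+).*", "\\1", hdr))
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  w <- new_experience_window(cap, vars)
  if (nrow(df)) {
    w$state <- as.matrix(df[, vars, drop = FALSE])
    colnames(w$state) <- vars
    w$action <- as.character(df$action)
    w$q <- df$q
    w$reward <- df$reward
    w$step <- as.integer(df$step)
  }
  w
}
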