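#' Allowed actions per cell type
#'
#' The phenotype repertoire of each agent type: cancerous cells can undergo
#' hypoxia, necrosis, migration, proliferation and quiescence; healthy cells
#' apoptosis, migration, proliferation and quiescence; stalk cells
#' quiescence, branch and sprout; tip cells quiescence, branch and
#' expansion.
#'
#' @param celltype `"healthy"`, `"cancerous"`, `"tip"` or `"stalk"`.
#' @return character vector of action names.
#' @export
allowed_actions <- function(celltype) {
  switch(celltype,
    cancerous = c("hypoxia", "necrosis", "migration", "proliferation",
                  "quiescence"),
    healthy = c("apoptosis", "migration", "proliferation", "quiescence"),
    stalk = c("quiescence", "branch", "sprout"),
    tip = c("quiescence", "branch", "expansion"),
    stop("unknown cell type: ", celltype, call. = FALSE))
}

relevant_species <- function(celltype) {
  if (celltype %in% c("healthy", "cancerous")) c("oxygen", "glucose")
  else "vegf"
}

nb_stats_of <- function(field, lattice)
  cpp_nb_stats(field$C, lattice$nb)

#' Site-selection candidate condition
#'
#' A candidate site qualifies when, for any relevant nutrient (oxygen or
#' glucose for tissue cells, VEGF for vessel cells), the maximum
#' concentration over the candidate's Moore neighborhood exceeds the
#' neighborhood mean by more than three neighborhood standard deviations
#' (population sd, in-bounds neighbors only).
#'
#' @param site 0-based coordinates.
#' @param fields named list of `oncosim_field`s (by species).
#' @param celltype the selecting cell's type.
#' @param lattice the lattice.
#' @return logical.
#' @export
candidate_condition <- function(site, fields, celltype, lattice) {
  i <- coords_to_index(lattice, site)
  for (sp in relevant_species(celltype)) {
    st <- nb_stats_of(fields[[sp]], lattice)
    if (st$max[i] - st$mean[i] > 3 * st$sd[i]) return(TRUE)
  }
  FALSE
}

#' Site-selection probabilities
#'
#' Each candidate is weighted by the sum, over the relevant nutrients, of
#' its Moore-neighborhood mean concentration; probabilities are the
#' normalized weights. If every weight is zero the fallback is uniform.
#'
#' @param candidates matrix of 0-based candidate coordinates (or vector of
#'   1-based linear indices with `linear = TRUE`).
#' @inheritParams candidate_condition
#' @param linear interpret `candidates` as linear indices.
#' @return numeric probabilities summing to 1.
#' @export
selection_probabilities <- function(candidates, fields, celltype, lattice,
                                    linear = FALSE) {
  idx <- if (linear) as.integer(candidates)
         else coords_to_index(lattice, candidates)
  stopifnot(length(idx) >= 1L)
  w <- numeric(length(idx))
  for (sp in relevant_species(celltype)) {
    st <- nb_stats_of(fields[[sp]], lattice)
    w <- w + st$mean[idx]
  }
  if (sum(w) <= 0) return(rep(1 / length(w), length(w)))
  w / sum(w)
}

# ---------------------------------------------------------------------------
# World construction and mutation. The world is an environment so agent and
# lattice state can be updated in place by the macro-step loop.

empty_cells <- function() {
  list(id = integer(0), type = character(0), site = integer(0),
       phenotype = character(0), alive = logical(0), frozen = logical(0),
       oxygen = numeric(0), glucose = numeric(0),
       division_counter = integer(0), prolif_delay = integer(0),
       prolif_clock = numeric(0), hypoxia_counter = integer(0),
       plcg = numeric(0), tnfa = numeric(0), death_signal = numeric(0),
       vegf = numeric(0), tip_age = numeric(0),
       parent = integer(0), root_side = character(0), sprout_id = integer(0),
       sig_egfr1 = numeric(0), sig_egfr2 = numeric(0),
       sig_tnf1 = numeric(0), sig_tnf2 = numeric(0))
}

add_cells <- function(world, type, sites, parent = 0L, root_side = "",
                      sprout_id = 0L) {
  n <- length(sites)
  if (n == 0L) return(integer(0))
  parent <- rep(as.integer(parent), length.out = n)
  root_side <- rep(root_side, length.out = n)
  sprout_id <- rep(as.integer(sprout_id), length.out = n)
  cc <- world$cells
  ids <- world$next_id + seq_len(n) - 1L
  world$next_id <- world$next_id + n
  cc$id <- c(cc$id, ids)
  cc$type <- c(cc$type, rep(type, n))
  cc$site <- c(cc$site, as.integer(sites))
  cc$phenotype <- c(cc$phenotype, rep("quiescence", n))
  cc$alive <- c(cc$alive, rep(TRUE, n))
  cc$frozen <- c(cc$frozen, rep(FALSE, n))
  for (f in c("oxygen", "glucose", "prolif_clock", "plcg", "tnfa",
              "death_signal", "vegf", "tip_age", "sig_egfr1", "sig_egfr2",
              "sig_tnf1", "sig_tnf2"))
    cc[[f]] <- c(cc[[f]], numeric(n))
  for (f in c("division_counter", "prolif_delay", "hypoxia_counter"))
    cc[[f]] <- c(cc[[f]], integer(n))
  cc$parent <- c(cc$parent, parent)
  cc$root_side <- c(cc$root_side, root_side)
  cc$sprout_id <- c(cc$sprout_id, sprout_id)
  world$cells <- cc
  # lattice occupancy
  if (type %in% c("healthy", "cancerous")) {
    world$lat$occ[sites] <- ids
  } else {
    world$lat$endo[sites] <- world$lat$endo[sites] + 1L
    cls <- ifelse(root_side == "artery", vessel_classes[["arteriole"]],
                  vessel_classes[["venule"]])
    upd <- world$lat$vessel[sites] == 0L
    world$lat$vessel[sites[upd]] <- cls[upd]
  }
  ids
}

cell_row <- function(world, id) {
  # ids are assigned in append order, so row == id unless that ever changes
  cc <- world$cells
  if (id >= 1L && id <= length(cc$id) && cc$id[id] == id) return(id)
  which(cc$id == id)
}

#' Initialize the simulation world
#'
#' Builds the lattice, parent vasculature, initial cell population and
#' initial fields from a validated configuration:
#' \itemize{
#'   \item eight parent vessels as vertical lines spanning the lattice: four
#'     arteries on the mid-face lines and four veins on the vertical edges
#'     (or swapped, per `geometry$arteries_at`), always perfused;
#'   \item cancer cells seeded in a central sphere of radius
#'     `agent$seed_radius_um` with per-site probability
#'     `agent$init_p_cancer`; healthy cells elsewhere with probability
#'     `agent$init_p_healthy`;
#'   \item oxygen and glucose initialized as Gaussian-decay profiles peaking
#'     at the parent vessel lines; VEGF, TGF-alpha and TNF-alpha start at 0.
#' }
#' All random draws come from the `"init"` stream of the master seed.
#'
#' @param config an `oncosim_config`.
#' @return a world environment with the lattice (`$lat`), agents
#'   (`$cells`), fields (`$fields`), config and bookkeeping counters.
#' @export
initialize_world <- function(config) {
  validate_config(config)
  g <- config$geometry
  lat <- new_lattice(g$nx, g$ny, g$nz, g$dS, g$r_art, g$r_cap)
  world <- new.env(parent = emptyenv())
  world$config <- config
  world$lat <- lat
  world$cells <- empty_cells()
  world$next_id <- 1L
  world$step <- 0L
  world$branch_count <- 0L
  world$next_sprout_id <- 1L
  world$trace <- list()
  world$pending <- list()
  world$windows <- list()
  world$ensembles <- list()
  world$clamp_log <- 0L

  # parent vasculature: vertical lines through the whole z extent
  cx <- g$nx %/% 2L; cy <- g$ny %/% 2L
  faces <- rbind(c(cx, 0L), c(cx, g$ny - 1L), c(0L, cy), c(g$nx - 1L, cy))
  edges <- rbind(c(0L, 0L), c(0L, g$ny - 1L), c(g$nx - 1L, 0L),
                 c(g$nx - 1L, g$ny - 1L))
  if (identical(g$arteries_at, "faces")) {
    art_xy <- faces; vein_xy <- edges
  } else {
    art_xy <- edges; vein_xy <- faces
  }
  # avoid artery/vein collisions on degenerate small lattices
  key <- function(m) paste(m[, 1], m[, 2])
  vein_xy <- vein_xy[!key(vein_xy) %in% key(art_xy), , drop = FALSE]
  zline <- 0:(g$nz - 1L)
  line_sites <- function(xy) {
    coords_to_index(lat, cbind(rep(xy[1], g$nz), rep(xy[2], g$nz), zline))
  }
  art_sites <- unlist(lapply(seq_len(nrow(art_xy)),
                             function(i) line_sites(art_xy[i, ])))
  vein_sites <- unlist(lapply(seq_len(nrow(vein_xy)),
                              function(i) line_sites(vein_xy[i, ])))
  world$lat$vessel[art_sites] <- vessel_classes[["artery"]]
  world$lat$vessel[vein_sites] <- vessel_classes[["vein"]]
  world$lat$endo[c(art_sites, vein_sites)] <- 4L
  world$lat$perfused[c(art_sites, vein_sites)] <- TRUE
  world$parent_lines <- nrow(art_xy) + nrow(vein_xy)

  with_stream(config$run$seed, "init", {
    # cancer seed sphere, then healthy tissue elsewhere
    ctr <- (c(g$nx, g$ny, g$nz) - 1) / 2
    xyz <- index_to_coords(lat, seq_len(lat$n))
    d2 <- (xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2 + (xyz[, 3] - ctr[3])^2
    r_seed <- config$agent$seed_radius_um / g$dS
    in_seed <- d2 <= r_seed^2
    open <- world$lat$endo == 0L & world$lat$occ == 0L
    cand <- which(in_seed & open)
    take <- cand[runif(length(cand)) < config$agent$init_p_cancer]
    add_cells(world, "cancerous", take)
    cand_h <- which(!in_seed & open)
    take_h <- cand_h[runif(length(cand_h)) < config$agent$init_p_healthy]
    add_cells(world, "healthy", take_h)
  })

  # fields: oxygen/glucose as Gaussian-decay profiles around vessel lines
  all_xy <- rbind(art_xy, vein_xy)
  xyz <- index_to_coords(lat, seq_len(lat$n))
  dmin2 <- rep(Inf, lat$n)
  for (i in seq_len(nrow(all_xy)))
    dmin2 <- pmin(dmin2, (xyz[, 1] - all_xy[i, 1])^2 +
                         (xyz[, 2] - all_xy[i, 2])^2)
  sig <- config$agent$nutrient_init_sigma
  prof <- pmax(config$agent$nutrient_init_amp * exp(-dmin2 / (2 * sig^2)),
               config$agent$nutrient_init_floor)
  world$fields <- list(
    oxygen = new_field("oxygen", lat, config$fields$oxygen,
                       pmin(prof, config$fields$oxygen$rho_art)),
    glucose = new_field("glucose", lat, config$fields$glucose,
                        pmin(prof, config$fields$glucose$rho_art)),
    tgfa = new_field("tgfa", lat, config$fields$tgfa, 0),
    tnfa = new_field("tnfa", lat, config$fields$tnfa, 0),
    vegf = new_field("vegf", lat, config$fields$vegf, 0)
  )
  world
}

free_moore_sites <- function(world, site, celltype) {
  nbs <- world$lat$nb[site, ]
  nbs <- nbs[nbs > 0L]
  occ <- world$lat$occ[nbs]
  if (celltype %in% c("healthy", "cancerous"))
    nbs[occ == 0L & world$lat$endo[nbs] == 0L]
  else
    nbs[occ == 0L & world$lat$endo[nbs] < 4L]
}

# Neighborhood field statistics, cached for the duration of one macro step
# (fields only change in the field phase).
get_nbstats <- function(world, sp) {
  st <- world$nbstats[[sp]]
  if (is.null(st)) {
    st <- nb_stats_of(world$fields[[sp]], world$lat)
    if (is.null(world$nbstats)) world$nbstats <- list()
    world$nbstats[[sp]] <- st
  }
  st
}

refresh_nbstats <- function(world) {
  world$nbstats <- list()
  world$selcache <- list()
  for (sp in names(world$fields)) get_nbstats(world, sp)
}

# Per-site qualification flag and selection weight for a cell class,
# cached for the macro step: pass = any relevant nutrient with
# max - mean > 3 sd over the site's neighborhood; weight = summed
# neighborhood means.
site_selection_fields <- function(world, celltype) {
  cls <- if (celltype %in% c("healthy", "cancerous")) "tissue" else "vessel"
  cache <- world$selcache[[cls]]
  if (!is.null(cache)) return(cache)
  n <- world$lat$n
  pass <- rep(FALSE, n)
  w <- numeric(n)
  for (sp in relevant_species(celltype)) {
    st <- get_nbstats(world, sp)
    pass <- pass | (st$max - st$mean > 3 * st$sd)
    w <- w + st$mean
  }
  cache <- list(pass = pass, w = w)
  if (is.null(world$selcache)) world$selcache <- list()
  world$selcache[[cls]] <- cache
  cache
}

# Vectorized site selection for a batch of movers of one cell type:
# returns one target per input site (NA when no reachable site) plus the
# has-free flag, drawing one uniform variate per mover.
batch_select_targets <- function(world, sites, celltype) {
  lat <- world$lat
  m <- length(sites)
  M <- lat$nb[sites, , drop = FALSE]
  valid <- M > 0L
  Mi <- ifelse(valid, M, 1L)
  freem <- if (celltype %in% c("healthy", "cancerous"))
    valid & lat$occ[Mi] == 0L & lat$endo[Mi] == 0L
  else
    valid & lat$occ[Mi] == 0L & lat$endo[Mi] < 4L
  dim(freem) <- dim(M)
  has_free <- rowSums(freem) > 0L
  sel <- site_selection_fields(world, celltype)
  passm <- freem & matrix(sel$pass[Mi], nrow = m)
  use_pass <- rowSums(passm) > 0L
  mask <- freem
  mask[use_pass, ] <- passm[use_pass, , drop = FALSE]
  W <- mask * matrix(sel$w[Mi], nrow = m)
  zero <- has_free & rowSums(W) <= 0
  if (any(zero)) W[zero, ] <- mask[zero, , drop = FALSE]  # uniform fallback
  tot <- rowSums(W)
  u <- runif(m) * tot
  cum <- W
  for (j in seq_len(ncol(W))[-1]) cum[, j] <- cum[, j] + cum[, j - 1]
  pick <- 1L + rowSums(cum < u & tot > 0)
  pick[pick > ncol(W)] <- ncol(W)
  tgt <- M[cbind(seq_len(m), pick)]
  tgt[!has_free] <- NA_integer_
  list(target = tgt, has_free = has_free)
}

# Candidate pool + probabilistic pick for one cell (the Eq.1/Eq.2 path):
# restrict to qualifying candidates when any qualify, rank the pool by the
# neighborhood-mean weights, draw one.
select_target_site <- function(world, site, celltype) {
  free <- free_moore_sites(world, site, celltype)
  if (!length(free)) return(NA_integer_)
  sps <- relevant_species(celltype)
  pass <- rep(FALSE, length(free))
  w <- numeric(length(free))
  for (sp in sps) {
    st <- get_nbstats(world, sp)
    pass <- pass | (st$max[free] - st$mean[free] > 3 * st$sd[free])
    w <- w + st$mean[free]
  }
  pool <- if (any(pass)) free[pass] else free
  pw <- if (any(pass)) w[pass] else w
  if (length(pool) == 1L) return(pool)
  if (sum(pw) <= 0) pw <- rep(1, length(pool))
  pool[sample.int(length(pool), 1L, prob = pw / sum(pw))]
}

remove_cell <- function(world, row, necrotic = FALSE) {
  s <- world$cells$site[row]
  ty <- world$cells$type[row]
  if (ty %in% c("healthy", "cancerous")) {
    world$lat$occ[s] <- if (necrotic) -1L else 0L
  } else {
    world$lat$endo[s] <- max(0L, world$lat$endo[s] - 1L)
  }
  world$cells$alive[row] <- FALSE
}

move_cell <- function(world, row, target) {
  s <- world$cells$site[row]
  ty <- world$cells$type[row]
  if (ty %in% c("healthy", "cancerous")) {
    world$lat$occ[s] <- 0L
    world$lat$occ[target] <- world$cells$id[row]
  } else {
    world$lat$endo[s] <- max(0L, world$lat$endo[s] - 1L)
    world$lat$endo[target] <- world$lat$endo[target] + 1L
    cls <- if (world$cells$root_side[row] == "artery")
      vessel_classes[["arteriole"]] else vessel_classes[["venule"]]
    if (world$lat$vessel[target] == 0L) world$lat$vessel[target] <- cls
  }
  world$cells$site[row] <- as.integer(target)
}

#' Apply one phenotype action to one cell
#'
#' Executes the action's world mutation semantics:
#' \describe{
#'   \item{apoptosis}{(healthy) the cell becomes inactive and is removed;
#'     its site is freed.}
#'   \item{necrosis}{(cancerous) the site is permanently marked with
#'     necrotic debris; no cell may ever enter it again.}
#'   \item{migration}{the cell moves to a Moore site chosen by the
#'     candidate condition and selection probabilities; with no reachable
#'     site it stays put.}
#'   \item{proliferation}{one daughter is placed by the same site-selection
#'     path (the mother stays); a healthy mother's division counter
#'     increments. With every Moore site occupied the cell instead enters
#'     quiescence (absorbing). Division also requires the cell-cycle clock
#'     and minimum oxygen; otherwise the attempt only increments the
#'     proliferation time delay.}
#'   \item{quiescence}{absorbing resting state: the cell never chooses
#'     another phenotype afterwards.}
#'   \item{hypoxia}{(cancerous) increments the hypoxia counter and moves the
#'     cell onto the high-VEGF production schedule.}
#'   \item{branch}{(tip/stalk) two offspring of the parent's type in two
#'     free VEGF-selected neighbor sites; with fewer than two free sites the
#'     cell idles this step (transient quiescence, logged).}
#'   \item{expansion}{(tip) the tip advances to a VEGF-selected site and
#'     leaves a new stalk cell in its former site.}
#'   \item{sprout}{(stalk) a stalk daughter at the VEGF-selected neighbor
#'     site.}
#' }
#'
#' @param world a world environment from [initialize_world()].
#' @param id cell id.
#' @param action an action in `allowed_actions()` of the cell's type.
#' @return invisibly, a list describing the mutation (`births`, `removed`,
#'   `moved`, `outcome`).
#' @export
apply_phenotype <- function(world, id, action) {
  row <- cell_row(world, id)
  if (!length(row) || !world$cells$alive[row])
    stop("no live cell with id ", id, call. = FALSE)
  ty <- world$cells$type[row]
  if (!action %in% allowed_actions(ty))
    stop(sprintf("action '%s' not allowed for type '%s'", action, ty),
         call. = FALSE)
  out <- list(births = integer(0), removed = FALSE, moved = FALSE,
              outcome = action)
  s <- world$cells$site[row]
  a <- world$config$agent

  if (action == "apoptosis") {
    remove_cell(world, row)
    out$removed <- TRUE
  } else if (action == "necrosis") {
    remove_cell(world, row, necrotic = TRUE)
    out$removed <- TRUE
  } else if (action == "quiescence") {
    world$cells$phenotype[row] <- "quiescence"
    world$cells$frozen[row] <- TRUE
  } else if (action == "hypoxia") {
    world$cells$phenotype[row] <- "hypoxia"
    world$cells$hypoxia_counter[row] <- world$cells$hypoxia_counter[row] + 1L
  } else if (action == "migration") {
    tgt <- select_target_site(world, s, ty)
    if (!is.na(tgt)) {
      move_cell(world, row, tgt)
      out$moved <- TRUE
      world$cells$phenotype[row] <- "migration"
    } else {
      out$outcome <- "stationary"
    }
  } else if (action == "proliferation") {
    free <- free_moore_sites(world, s, ty)
    if (!length(free)) {
      world$cells$phenotype[row] <- "quiescence"
      world$cells$frozen[row] <- TRUE
      out$outcome <- "quiescence"
    } else if (world$cells$prolif_clock[row] < a$cycle_hours ||
               world$cells$oxygen[row] < a$prolif_o2_min) {
      world$cells$prolif_delay[row] <- world$cells$prolif_delay[row] + 1L
      out$outcome <- "postponed"
    } else {
      tgt <- select_target_site(world, s, ty)
      out$births <- add_cells(world, ty, tgt)
      world$cells$phenotype[row] <- "proliferation"
      world$cells$prolif_clock[row] <- 0
      if (ty == "healthy")
        world$cells$division_counter[row] <-
          world$cells$division_counter[row] + 1L
    }
  } else if (action == "branch") {
    free <- free_moore_sites(world, s, ty)
    if (length(free) < 2L) {
      out$outcome <- "blocked_branch"
    } else {
      st <- get_nbstats(world, "vegf")
      w <- st$mean[free]
      if (sum(w) <= 0) w <- rep(1, length(free))
      pick <- sample.int(length(free), 2L, prob = w / sum(w))
      out$births <- add_cells(world, ty, free[pick],
                              parent = id,
                              root_side = world$cells$root_side[row],
                              sprout_id = world$cells$sprout_id[row])
      world$cells$phenotype[row] <- "branch"
      world$branch_count <- world$branch_count + 1L
    }
  } else if (action == "expansion") {
    tgt <- select_target_site(world, s, ty)
    if (is.na(tgt)) {
      out$outcome <- "stationary"
    } else {
      old <- s
      move_cell(world, row, tgt)
      out$moved <- TRUE
      out$births <- add_cells(world, "stalk", old,
                              parent = world$cells$parent[row],
                              root_side = world$cells$root_side[row],
                              sprout_id = world$cells$sprout_id[row])
      world$cells$parent[row] <- out$births[1]
      world$cells$phenotype[row] <- "expansion"
    }
  } else if (action == "sprout") {
    tgt <- select_target_site(world, s, ty)
    if (is.na(tgt)) {
      out$outcome <- "stationary"
    } else {
      out$births <- add_cells(world, "stalk", tgt, parent = id,
                              root_side = world$cells$root_side[row],
                              sprout_id = world$cells$sprout_id[row])
      world$cells$phenotype[row] <- "sprout"
    }
  }
  invisible(out)
}

#' Vessel lineage tree
#'
#' The sprout lineage graph: every tip/stalk cell with its parent pointer
#' (0 for sprout roots anchored on a parent vessel), lineage side, sprout
#' id and perfusion state.
#'
#' @param world a world environment.
#' @return data.frame with one row per live endothelial cell.
#' @export
vessel_tree <- function(world) {
  cc <- world$cells
  k <- which(cc$alive & cc$type %in% c("tip", "stalk"))
  data.frame(id = cc$id[k], type = cc$type[k], site = cc$site[k],
             parent = cc$parent[k], root_side = cc$root_side[k],
             sprout_id = cc$sprout_id[k],
             perfused = world$lat$perfused[cc$site[k]])
}

#' Update vessel perfusion flags
#'
#' A sprout becomes perfused ("active") when it lies on a connected path
#' between the arterial and the venous side: sprout segments are linked to
#' their own root side and, through Moore adjacency, to parent vessels and
#' to segments of other sprouts; every sprout whose connectivity component
#' contains both the arterial and the venous supernode is marked perfused
#' (blood can circulate), all others unperfused. Parent vessels are always
#' perfused. Recomputed from scratch, so removing a connecting segment
#' reverts the path to unperfused.
#'
#' @param world a world environment.
#' @return invisibly, the number of perfused sprout segments.
#' @export
update_perfusion <- function(world) {
  lat <- world$lat
  cc <- world$cells
  endo <- which(cc$alive & cc$type %in% c("tip", "stalk"))
  # reset sprout-site perfusion (keep parent vessels perfused)
  sprout_sites <- lat$vessel %in%
    vessel_classes[c("arteriole", "venule", "capillary")]
  world$lat$perfused[sprout_sites] <- FALSE
  if (!length(endo)) return(invisible(0L))

  sid <- cc$sprout_id[endo]
  usid <- sort(unique(sid))
  # union-find over sprouts + two supernodes (artery = n+1, vein = n+2)
  nnode <- length(usid) + 2L
  ART <- length(usid) + 1L; VEIN <- length(usid) + 2L
  up <- seq_len(nnode)
  find <- function(i) { while (up[i] != i) i <- up[i]; i }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) up[rj] <<- ri
  }
  node_of <- match(sid, usid)
  # root side links
  side_of <- cc$root_side[endo][match(usid, sid)]
  for (k in seq_along(usid))
    unite(k, if (side_of[k] == "artery") ART else VEIN)
  # adjacency links, vectorized over segments: each segment contributes
  # (its sprout, neighboring sprout/parent-vessel) edges
  site_sprout <- integer(lat$n)
  site_sprout[cc$site[endo]] <- node_of
  M <- lat$nb[cc$site[endo], , drop = FALSE]
  valid <- M > 0L
  Mi <- ifelse(valid, M, 1L)
  vc <- matrix(lat$vessel[Mi] * valid, nrow = nrow(M))
  art_adj <- rowSums(vc == vessel_classes[["artery"]]) > 0L
  vein_adj <- rowSums(vc == vessel_classes[["vein"]]) > 0L
  other <- matrix(site_sprout[Mi] * valid, nrow = nrow(M))
  pairs <- cbind(rep(node_of, 26L), as.vector(other))
  pairs <- pairs[pairs[, 2] > 0L & pairs[, 1] != pairs[, 2], , drop = FALSE]
  pairs <- unique(pairs)
  for (nd in unique(node_of[art_adj])) unite(nd, ART)
  for (nd in unique(node_of[vein_adj])) unite(nd, VEIN)
  if (nrow(pairs))
    for (k in seq_len(nrow(pairs))) unite(pairs[k, 1], pairs[k, 2])
  art_root <- find(ART)
  perf_sprout <- vapply(seq_along(usid),
                        function(k) find(k) == art_root && find(VEIN) == art_root,
                        logical(1))
  perf_rows <- endo[perf_sprout[node_of]]
  world$lat$perfused[cc$site[perf_rows]] <- TRUE
  invisible(length(perf_rows))
}

# Spawn new tip cells from perfused parent-vessel walls where local VEGF
# exceeds the sprouting threshold (classic sprouting angiogenesis
# initiation; sprouts inherit the parent's side: arteriole from arteries,
# venule from veins).
initiate_sprouts <- function(world) {
  lat <- world$lat
  a <- world$config$agent
  vegf <- world$fields$vegf$C
  if (is.null(world$sprouted)) world$sprouted <- logical(lat$n)
  parents <- which(lat$vessel %in% vessel_classes[c("artery", "vein")] &
                   vegf > a$vegf_sprout_threshold & !world$sprouted)
  if (!length(parents)) return(invisible(0L))
  go <- parents[runif(length(parents)) < a$sprout_prob]
  n_new <- 0L
  st <- get_nbstats(world, "vegf")
  for (s in go) {
    free <- free_moore_sites(world, s, "tip")
    if (!length(free)) next
    w <- st$mean[free]
    if (sum(w) <= 0) w <- rep(1, length(free))
    tgt <- if (length(free) == 1L) free else
      free[sample.int(length(free), 1L, prob = w / sum(w))]
    side <- if (lat$vessel[s] == vessel_classes[["artery"]]) "artery" else "vein"
    add_cells(world, "tip", tgt, parent = 0L, root_side = side,
              sprout_id = world$next_sprout_id)
    world$next_sprout_id <- world$next_sprout_id + 1L
    world$sprouted[s] <- TRUE
    n_new <- n_new + 1L
  }
  invisible(n_new)
}
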