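test_that("action repertoires match the cell-type table", {
  expect_setequal(allowed_actions("cancerous"),
                  c("hypoxia", "necrosis", "migration", "proliferation",
                    "quiescence"))
  expect_setequal(allowed_actions("healthy"),
                  c("apoptosis", "migration", "proliferation", "quiescence"))
  expect_false(any(c("necrosis", "hypoxia") %in% allowed_actions("healthy")))
  expect_setequal(allowed_actions("stalk"), c("quiescence", "branch", "sprout"))
  expect_true("sprout" %in% allowed_actions("stalk"))
  expect_false("expansion" %in% allowed_actions("stalk"))
  expect_setequal(allowed_actions("tip"), c("quiescence", "branch", "expansion"))
  expect_error(allowed_actions("fibroblast"), "unknown")
})

field_set <- function(lat, oxygen = 0, glucose = 0, vegf = 0) {
  p <- default_config()$fields
  list(oxygen = new_field("oxygen", lat, p$oxygen, oxygen),
       glucose = new_field("glucose", lat, p$glucose, glucose),
       tgfa = new_field("tgfa", lat, p$tgfa, 0),
       tnfa = new_field("tnfa", lat, p$tnfa, 0),
       vegf = new_field("vegf", lat, p$vegf, vegf))
}

test_that("the candidate condition compares max - mean against 3 sigma", {
  lat <- new_lattice(5, 5, 5)
  # homogeneous neighborhood: 0 > 0 fails
  flds <- field_set(lat, oxygen = 1, glucose = 1)
  expect_false(candidate_condition(c(2, 2, 2), flds, "cancerous", lat))
  # direct arithmetic oracle on a constructed asymmetric neighborhood:
  # one neighbor at 10, the other 25 at 1
  center <- c(2, 2, 2)
  nbs <- moore_neighbors(center, lat)
  ox <- rep(1, lat$n)
  ox[coords_to_index(lat, nbs[1, , drop = FALSE])] <- 10
  flds2 <- field_set(lat, oxygen = ox, glucose = 0)
  vals <- c(10, rep(1, 25))
  oracle <- (max(vals) - mean(vals)) >
    3 * sqrt(mean(vals^2) - mean(vals)^2)
  expect_identical(candidate_condition(center, flds2, "cancerous", lat),
                   oracle)
  # vessel cells read VEGF only: an oxygen hotspot does not qualify them
  expect_false(candidate_condition(center, flds2, "tip", lat))
  vg <- rep(0.1, lat$n)
  vg[coords_to_index(lat, nbs[1, , drop = FALSE])] <- 5
  flds3 <- field_set(lat, vegf = vg)
  expect_true(candidate_condition(center, flds3, "tip", lat))
})

test_that("selection probabilities are normalized neighborhood-mean weights", {
  lat <- new_lattice(7, 3, 3)
  # construct two candidates whose oxygen neighborhood means are 3:1
  ox <- numeric(lat$n)
  c1 <- c(1, 1, 1); c2 <- c(5, 1, 1)
  n1 <- moore_neighbors(c1, lat); n2 <- moore_neighbors(c2, lat)
  ox[coords_to_index(lat, n1)] <- 3
  ox[coords_to_index(lat, n2)] <- 1
  flds <- field_set(lat, oxygen = ox, glucose = 0)
  p <- selection_probabilities(rbind(c1, c2), flds, "cancerous", lat)
  expect_equal(p, c(0.75, 0.25))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # permutation equivariance
  expect_equal(selection_probabilities(rbind(c2, c1), flds, "cancerous", lat),
               c(0.25, 0.75))
  # single candidate: probability one; all-zero weights: uniform fallback
  expect_equal(selection_probabilities(rbind(c1), flds, "cancerous", lat), 1)
  flds0 <- field_set(lat, oxygen = 0, glucose = 0)
  expect_equal(selection_probabilities(rbind(c1, c2), flds0, "cancerous", lat),
               c(0.5, 0.5))
})

world_with_one_cell <- function(type = "cancerous", n = 7, site = NULL) {
  cfg <- tiny_config(n = n, seed = 5,
                     agent = list(init_p_cancer = 0, init_p_healthy = 0))
  w <- initialize_world(cfg)
  if (is.null(site)) site <- coords_to_index(w$lat, c(3, 3, 3))
  oncolattice:::add_cells(w, type, site)
  oncolattice:::refresh_nbstats(w)
  w
}

test_that("apoptosis frees the site and removes the cell", {
  w <- world_with_one_cell("healthy")
  id <- w$cells$id[1]
  s <- w$cells$site[1]
  apply_phenotype(w, id, "apoptosis")
  expect_identical(w$lat$occ[s], 0L)
  expect_false(w$cells$alive[1])
  expect_error(apply_phenotype(w, id, "apoptosis"), "no live cell")
})

test_that("necrosis leaves a permanent blocking marker", {
  w <- world_with_one_cell("cancerous")
  s <- w$cells$site[1]
  apply_phenotype(w, w$cells$id[1], "necrosis")
  expect_identical(w$lat$occ[s], -1L)
  expect_false(can_occupy(w$lat, s, "cancerous", linear = TRUE))
  expect_false(can_occupy(w$lat, s, "tip", linear = TRUE))
})

test_that("disallowed actions are refused", {
  w <- world_with_one_cell("healthy")
  expect_error(apply_phenotype(w, w$cells$id[1], "necrosis"), "not allowed")
})

test_that("proliferation places one daughter and falls back to quiescence when walled in", {
  w <- world_with_one_cell("cancerous")
  w$fields$oxygen$C[] <- 1  # ample oxygen
  w$cells$oxygen[1] <- 1
  w$cells$prolif_clock[1] <- 100
  oncolattice:::refresh_nbstats(w)
  set.seed(3)
  out <- apply_phenotype(w, w$cells$id[1], "proliferation")
  expect_length(out$births, 1L)
  expect_identical(sum(w$cells$alive), 2L)
  expect_identical(w$cells$type[2], "cancerous")
  # daughter sits in the mother's Moore neighborhood; mother stayed
  expect_true(w$cells$site[2] %in% w$lat$nb[w$cells$site[1], ])

  # fully surrounded: phenotype converts to (absorbing) quiescence
  w2 <- world_with_one_cell("cancerous")
  w2$fields$oxygen$C[] <- 1
  w2$cells$oxygen[1] <- 1
  w2$cells$prolif_clock[1] <- 100
  nbs <- w2$lat$nb[w2$cells$site[1], ]
  oncolattice:::add_cells(w2, "healthy", nbs[nbs > 0L])
  oncolattice:::refresh_nbstats(w2)
  out2 <- apply_phenotype(w2, w2$cells$id[1], "proliferation")
  expect_identical(out2$outcome, "quiescence")
  expect_true(w2$cells$frozen[1])
  expect_identical(sum(w2$cells$type == "cancerous"), 1L)

  # insufficient oxygen: the attempt only increments the delay
  w3 <- world_with_one_cell("cancerous")
  w3$fields$oxygen$C[] <- 0
  w3$cells$oxygen[1] <- 0
  w3$cells$prolif_clock[1] <- 100
  oncolattice:::refresh_nbstats(w3)
  out3 <- apply_phenotype(w3, w3$cells$id[1], "proliferation")
  expect_identical(out3$outcome, "postponed")
  expect_identical(w3$cells$prolif_delay[1], 1L)
})

test_that("healthy divisions increment the division counter", {
  w <- world_with_one_cell("healthy")
  w$fields$oxygen$C[] <- 1
  w$cells$oxygen[1] <- 1
  w$cells$prolif_clock[1] <- 100
  oncolattice:::refresh_nbstats(w)
  set.seed(4)
  apply_phenotype(w, w$cells$id[1], "proliferation")
  expect_identical(w$cells$division_counter[1], 1L)
})

test_that("migration moves along the nutrient-weighted selection path", {
  w <- world_with_one_cell("cancerous")
  # put all the oxygen mass on one side so the chosen site is deterministic
  tgt <- coords_to_index(w$lat, c(5, 3, 3))
  w$fields$oxygen$C[] <- 0
  w$fields$oxygen$C[w$lat$nb[tgt, ]] <- 10
  oncolattice:::refresh_nbstats(w)
  set.seed(5)
  before <- w$cells$site[1]
  out <- apply_phenotype(w, w$cells$id[1], "migration")
  expect_true(out$moved)
  expect_identical(w$lat$occ[before], 0L)
  expect_identical(w$lat$occ[w$cells$site[1]], w$cells$id[1])
})

test_that("tip expansion advances the tip and leaves a stalk cell behind", {
  w <- world_with_one_cell("tip")
  w$cells$root_side[1] <- "artery"
  w$cells$sprout_id[1] <- 1L
  w$fields$vegf$C[] <- 0.5
  oncolattice:::refresh_nbstats(w)
  old <- w$cells$site[1]
  set.seed(6)
  out <- apply_phenotype(w, w$cells$id[1], "expansion")
  expect_true(out$moved)
  expect_identical(w$cells$type[2], "stalk")
  expect_identical(w$cells$site[2], old)           # stalk fills the wake
  expect_identical(w$cells$parent[1], w$cells$id[2])  # lineage rethreaded
  expect_identical(w$lat$endo[old], 1L)
  expect_identical(w$lat$endo[w$cells$site[1]], 1L)
})

test_that("branch delivers two offspring in two free sites, else idles", {
  w <- world_with_one_cell("tip")
  w$cells$root_side[1] <- "artery"
  w$fields$vegf$C[] <- 0.5
  oncolattice:::refresh_nbstats(w)
  set.seed(7)
  out <- apply_phenotype(w, w$cells$id[1], "branch")
  expect_length(out$births, 2L)
  expect_identical(w$branch_count, 1L)
  expect_true(all(w$cells$type[2:3] == "tip"))
  # walled-in tip cannot branch and idles this step (not absorbed)
  w2 <- world_with_one_cell("stalk", site = NULL)
  nbs <- w2$lat$nb[w2$cells$site[1], ]
  oncolattice:::add_cells(w2, "healthy", nbs[nbs > 0L])
  oncolattice:::refresh_nbstats(w2)
  out2 <- apply_phenotype(w2, w2$cells$id[1], "branch")
  expect_identical(out2$outcome, "blocked_branch")
  expect_false(w2$cells$frozen[1])
})

test_that("stalk sprouting creates a stalk daughter at the VEGF-selected site", {
  w <- world_with_one_cell("stalk")
  w$cells$root_side[1] <- "vein"
  w$cells$sprout_id[1] <- 3L
  w$fields$vegf$C[] <- 0.4
  oncolattice:::refresh_nbstats(w)
  set.seed(8)
  out <- apply_phenotype(w, w$cells$id[1], "sprout")
  expect_length(out$births, 1L)
  expect_identical(w$cells$type[2], "stalk")
  expect_identical(w$cells$root_side[2], "vein")
  expect_identical(w$cells$sprout_id[2], 3L)
  # venule class inherited onto the new site
  expect_identical(w$lat$vessel[w$cells$site[2]],
                   unname(vessel_classes[["venule"]]))
})

test_that("perfusion activates exactly when a sprout path connects artery to vein side", {
  cfg <- tiny_config(n = 8, agent = list(init_p_cancer = 0,
                                         init_p_healthy = 0))
  w <- initialize_world(cfg)
  # artery line passes through (0, cy) with cy = 4; vein line through (0, 0):
  # build a straight artery-rooted sprout at x = 0 from y = 3 down to y = 2,
  # which leaves a one-site gap to the vein's Moore neighborhood
  z <- 3
  path_sites <- coords_to_index(w$lat, cbind(c(0, 0), c(3, 2), c(z, z)))
  oncolattice:::add_cells(w, "stalk", path_sites, parent = 0L,
                          root_side = "artery", sprout_id = 1L)
  update_perfusion(w)
  expect_false(any(w$lat$perfused[path_sites]))  # not yet touching the vein
  # extend the tip to y = 1: inside the Moore neighborhood of the vein line
  tipsite <- coords_to_index(w$lat, c(0, 1, z))
  oncolattice:::add_cells(w, "tip", tipsite, parent = 0L,
                          root_side = "artery", sprout_id = 1L)
  update_perfusion(w)
  expect_true(all(w$lat$perfused[path_sites]))   # whole path perfused
  # removing the connecting segment reverts the path (graph connectivity)
  tip_row <- which(w$cells$site == tipsite & w$cells$alive)
  oncolattice:::remove_cell(w, tip_row[1])
  update_perfusion(w)
  expect_false(any(w$lat$perfused[setdiff(path_sites, tipsite)]))
})

test_that("world initialization realizes the documented geometry and seeding", {
  cfg <- tiny_config(n = 20, seed = 2)
  w <- initialize_world(cfg)
  # exactly eight parent vessel lines spanning z
  expect_identical(w$parent_lines, 8L)
  nart <- sum(w$lat$vessel == vessel_classes[["artery"]])
  nvein <- sum(w$lat$vessel == vessel_classes[["vein"]])
  expect_identical(nart, 4L * 20L)
  expect_identical(nvein, 4L * 20L)
  expect_true(all(w$lat$perfused[w$lat$vessel > 0L]))
  # seed sphere: radius 60 um = 3 sites; all cancer cells inside it
  ctr <- (c(20, 20, 20) - 1) / 2
  canc <- which(w$cells$type == "cancerous")
  xyz <- index_to_coords(w$lat, w$cells$site[canc])
  d <- sqrt(rowSums(sweep(xyz, 2, ctr)^2))
  expect_true(all(d <= 3 + 1e-9))
  # fields: oxygen peaks at the vessels, VEGF/TGFa/TNFa start at zero
  expect_true(all(w$fields$vegf$C == 0) && all(w$fields$tnfa$C == 0))
  vess <- which(w$lat$vessel > 0L)
  expect_gt(mean(w$fields$oxygen$C[vess]), mean(w$fields$oxygen$C))
})

test_that("seed-sphere occupancy frequency matches the seeding probability", {
  # Monte-Carlo frequency oracle over repeated initializations
  cfg <- tiny_config(n = 10)
  sphere_sites <- local({
    w <- initialize_world(cfg)
    ctr <- (c(10, 10, 10) - 1) / 2
    xyz <- index_to_coords(w$lat, seq_len(w$lat$n))
    d2 <- rowSums(sweep(xyz, 2, ctr)^2)
    open <- w$lat$endo == 0L
    sum(d2 <= 3^2 & open)
  })
  fracs <- vapply(1:100, function(s) {
    w <- initialize_world(tiny_config(n = 10, seed = s))
    sum(w$cells$type == "cancerous") / sphere_sites
  }, numeric(1))
  se <- sqrt(0.7 * 0.3 / (sphere_sites * 100))
  expect_lt(abs(mean(fracs) - 0.7), 4 * se)
})

test_that("zero seeding probabilities give vessels-only tissue", {
  w <- initialize_world(tiny_config(agent = list(init_p_cancer = 0,
                                                 init_p_healthy = 0)))
  expect_identical(length(w$cells$id), 0L)
  expect_gt(sum(w$lat$vessel > 0L), 0L)
})

test_that("every endothelial cell keeps an unbroken chain to a parent vessel", {
  cfg <- tiny_config(n = 14, horizon = 40,
                     agent = list(sprout_prob = 0.5,
                                  vegf_sprout_threshold = 0))
  r <- run_simulation(cfg, "train", steps = 40)
  vt <- vessel_tree(r$world)
  if (nrow(vt)) {
    lat <- r$world$lat
    for (k in seq_len(nrow(vt))) {
      node <- vt[k, ]
      seen <- 0L
      while (node$parent != 0L && seen < 1e4) {
        up <- vt[vt$id == node$parent, ]
        expect_identical(nrow(up), 1L)
        node <- up
        seen <- seen + 1L
      }
      # a root sprout segment must neighbor its parent vessel line
      nbs <- lat$nb[node$site, ]
      nbs <- nbs[nbs > 0L]
      expect_true(any(lat$vessel[nbs] %in%
                        vessel_classes[c("artery", "vein")]))
    }
  } else succeed("no sprouts formed at this horizon")
})
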