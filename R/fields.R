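#' Concentration fields
#'
#' Each of the five molecular species (oxygen, glucose, TGF-alpha,
#' TNF-alpha, VEGF) is a scalar concentration field over the lattice,
#' evolved by an explicit finite-difference scheme on the 26-neighbor Moore
#' stencil with no-flux (reflecting) boundaries: a missing neighbor mirrors
#' the center value and contributes zero to the Laplacian.
#'
#' Per macro step the update applies, per site,
#' diffusion `D * dt/dS^2 * (sum_nb C - 26 C)`, phenotype-dependent cellular
#' uptake, vessel-wall exchange `dt/dS^2 * 2 pi R Pe (rho - C)` at perfused
#' vessel sites, constant production (TGF-alpha/TNF-alpha at tissue-cell
#' sites, VEGF at cancer-cell sites), and first-order VEGF decay. Negative
#' excursions are clamped to zero and counted in the field's `clamped`
#' tally.
#'
#' @param species one of `"oxygen"`, `"glucose"`, `"tgfa"`, `"tnfa"`,
#'   `"vegf"`.
#' @param lattice an `oncosim_lattice`.
#' @param params the per-species parameter list (see [config]).
#' @param init initial concentration: a scalar or a vector of length
#'   `lattice$n`.
#' @return an `oncosim_field` list with elements `species`, `C`, `params`,
#'   `clamped`.
#' @export
new_field <- function(species, lattice, params, init = 0) {
  stopifnot(species %in% c("oxygen", "glucose", "tgfa", "tnfa", "vegf"))
  C <- rep_len(as.numeric(init), lattice$n)
  if (length(init) == lattice$n) C <- as.numeric(init)
  stopifnot(all(is.finite(C)), all(C >= 0))
  structure(list(species = species, C = C, params = params, clamped = 0L),
            class = "oncosim_field")
}

#' Discrete 26-neighbor Laplacian at one site
#'
#' The stencil value `sum over the Moore neighborhood of C  -  26 * C(site)`,
#' with out-of-bounds neighbors mirroring the center value (no-flux
#' convention), so a uniform field has Laplacian 0 everywhere, including on
#' the boundary.
#'
#' @param field an `oncosim_field`.
#' @param site 0-based coordinates `c(x, y, z)`.
#' @param lattice the lattice the field lives on.
#' @return scalar stencil value.
#' @export
laplacian26 <- function(field, site, lattice) {
  i <- coords_to_index(lattice, site)
  nbs <- lattice$nb[i, ]
  s <- sum(ifelse(nbs > 0L, field$C[nbs], field$C[i]))
  s - 26 * field$C[i]
}

field_laplacian_all <- function(C, nb) cpp_nb_sum26(C, nb) - 26 * C

#' Site occupancy summary for the field solver
#'
#' Builds the per-site cell-type and phenotype code vectors the uptake and
#' source schedules need. Codes: type 0 = none, 1 = healthy, 2 = cancerous,
#' 3 = necrotic debris; phenotype 1..5 = proliferation, migration,
#' quiescence, hypoxia, necrosis (0 = not applicable).
#'
#' @param lattice an `oncosim_lattice`.
#' @param cells optional agent table (see [initialize_world()]); when `NULL`
#'   only necrotic markers are reported.
#' @return list with integer vectors `type` and `phen` of length `lattice$n`.
#' @export
site_occupancy <- function(lattice, cells = NULL) {
  type <- integer(lattice$n)
  phen <- integer(lattice$n)
  type[lattice$occ == -1L] <- 3L
  phen[lattice$occ == -1L] <- 5L
  if (!is.null(cells)) {
    live <- which(cells$alive & cells$type %in% c("healthy", "cancerous"))
    s <- cells$site[live]
    type[s] <- ifelse(cells$type[live] == "healthy", 1L, 2L)
    phen[s] <- match(cells$phenotype[live],
                     c("proliferation", "migration", "quiescence",
                       "hypoxia", "necrosis"), nomatch = 0L)
  }
  list(type = type, phen = phen)
}

# Per-site linear-removal (a) and constant-source (b) coefficients for one
# sub-step of length dt. The uptake schedule for oxygen/glucose is
# beta_c / {1, 2, 4, 6, 8} across cancer phenotypes {proliferation,
# migration, quiescence, hypoxia, necrosis}; the VEGF production schedule is
# phi_c / {1, 2, 4, 6, 8} across {necrosis, hypoxia, quiescence, migration,
# proliferation}.
field_coeffs <- function(field, lattice, dt, occ = NULL,
                         necrotic_uptake = TRUE) {
  n <- lattice$n
  p <- field$params
  a <- numeric(n)
  b <- numeric(n)
  dS <- lattice$dS
  if (is.null(occ)) occ <- site_occupancy(lattice)
  sp <- field$species

  vess <- lattice$perfused & lattice$vessel > 0L
  Rsite <- numeric(n)
  art_side <- lattice$vessel %in% vessel_classes[c("artery", "arteriole")]
  Rsite[vess & art_side] <- lattice$r_art
  Rsite[vess & !art_side] <- lattice$r_cap

  if (sp %in% c("oxygen", "glucose")) {
    zeta <- numeric(n)
    sched <- c(1, 1 / 2, 1 / 4, 1 / 6, 1 / 8)
    cancer <- occ$type == 2L
    zeta[cancer] <- p$beta_c * sched[occ$phen[cancer]]
    zeta[occ$type == 1L] <- p$alpha_n
    if (necrotic_uptake) zeta[occ$type == 3L] <- p$beta_c / 8
    a <- a + dt * zeta
    perm <- (dt / dS^2) * 2 * pi * Rsite * p$Pe
    rho <- ifelse(art_side, p$rho_art, p$rho_cap)
    a <- a + perm
    b <- b + perm * rho
  } else if (sp %in% c("tgfa", "tnfa")) {
    # consumed by the signaling layer, not here; produced by tissue cells
    b[occ$type %in% c(1L, 2L)] <- dt * p$SO
  } else if (sp == "vegf") {
    perm <- (dt / dS^2) * 2 * pi * Rsite * p$Pe
    a <- a + perm + dt * p$omega
    sched <- c(1 / 8, 1 / 6, 1 / 4, 1 / 2, 1)  # proliferation ... necrosis
    prod_sites <- occ$type %in% c(2L, 3L) & occ$phen > 0L
    b[prod_sites] <- dt * p$phi_c * sched[occ$phen[prod_sites]]
  }
  list(a = a, b = b, lambda = p$D * dt / dS^2)
}

step_field <- function(field, lattice, dt, occ = NULL,
                       necrotic_uptake = TRUE) {
  co <- field_coeffs(field, lattice, dt, occ, necrotic_uptake)
  if (co$lambda > 1 / 26 + 1e-12)
    stop(sprintf("field '%s': D*dt/dS^2 = %.4g violates the 1/26 stability bound; use resolve_substep()",
                 field$species, co$lambda), call. = FALSE)
  res <- cpp_diffuse_substep(field$C, lattice$nb, co$lambda, co$a, co$b)
  field$C <- res$C
  field$clamped <- field$clamped + res$clamped
  field
}

#' One explicit sub-step of a nutrient field (oxygen, glucose, TGF-alpha,
#' TNF-alpha)
#'
#' Applies diffusion, phenotype-dependent uptake (oxygen/glucose only;
#' TGF-alpha/TNF-alpha are consumed by the signaling layer instead), and the
#' vessel-wall / constant production source terms over one step of length
#' `dt`, which must satisfy the explicit stability bound
#' `D * dt / dS^2 <= 1/26` (see [resolve_substep()]).
#'
#' @inheritParams laplacian26
#' @param dt sub-step duration (hours).
#' @param occ site occupancy from [site_occupancy()] (`NULL` = no cells).
#' @param necrotic_uptake whether necrotic debris consumes at `beta_c / 8`
#'   (the schedule as written; set `FALSE` to zero it).
#' @return the updated field.
#' @export
step_nutrient <- function(field, lattice, dt, occ = NULL,
                          necrotic_uptake = TRUE) {
  stopifnot(field$species %in% c("oxygen", "glucose", "tgfa", "tnfa"))
  step_field(field, lattice, dt, occ, necrotic_uptake)
}

#' One explicit sub-step of the VEGF field
#'
#' Applies diffusion, endothelial uptake at perfused vessel sites, the
#' cancer-cell production schedule (highest for necrotic/hypoxic cells), and
#' first-order decay.
#'
#' @inheritParams step_nutrient
#' @return the updated field.
#' @export
step_vegf <- function(field, lattice, dt, occ = NULL) {
  stopifnot(field$species == "vegf")
  step_field(field, lattice, dt, occ)
}

#' Advance a field over one macro step with automatic sub-stepping
#'
#' Splits the macro step into the minimal number of stable sub-steps (see
#' [resolve_substep()]) and applies [step_nutrient()] / [step_vegf()]
#' repeatedly. Biology coefficients (occupancy, perfusion) are held fixed
#' across the sub-steps of one macro step.
#'
#' @inheritParams step_nutrient
#' @param dt_macro macro step duration (hours).
#' @return the updated field.
#' @export
advance_field <- function(field, lattice, dt_macro, occ = NULL,
                          necrotic_uptake = TRUE) {
  ss <- resolve_substep(field$params, lattice$dS, dt_macro)
  co <- field_coeffs(field, lattice, ss$dt_diff, occ, necrotic_uptake)
  for (k in seq_len(ss$n_sub)) {
    res <- cpp_diffuse_substep(field$C, lattice$nb, co$lambda, co$a, co$b)
    field$C <- res$C
    field$clamped <- field$clamped + res$clamped
  }
  field
}

#' Field as a 3D array
#'
#' @param field an `oncosim_field`.
#' @param lattice the lattice it lives on.
#' @return numeric array with dimensions `(nx, ny, nz)`.
#' @export
field_array <- function(field, lattice) {
  array(field$C, dim = lattice$dims)
}
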