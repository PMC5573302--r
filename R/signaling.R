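#' @title Sub-cellular signaling layer
#' @name signaling
#' @description
#' Each tissue cell runs two receptor pathways at sub-hour resolution:
#' the EGFR pathway (local TGF-alpha in, PLC-gamma out), whose readout
#' arbitrates the migrate-vs-proliferate preference, and the TNF pathway
#' (local TNF-alpha in, death signal out). Both consume their ligand from
#' the local field; the consumed amounts are reported back so the field
#' coupling is conservative.
#'
#' Pathway models are pluggable: a model is a list with elements
#' \describe{
#'   \item{n_state}{number of per-cell state variables.}
#'   \item{state0}{basal state vector.}
#'   \item{derivs}{`function(S, L, p)` returning dS/dt for a state matrix
#'     `S` (cells x states) and ligand vector `L`, vectorized across cells.}
#'   \item{readout}{index of the output state (PLC-gamma / death signal).}
#'   \item{consumption}{`function(S, L, p)` ligand consumption rate
#'     (field units per hour), vectorized.}
#'   \item{params}{named parameter list.}
#' }
#' Use [register_pathway()] to add a model and select it by name. The
#' shipped `"surrogate"` model is a mass-action receptor-binding step with a
#' saturating (Hill) activation of the readout and first-order readout
#' turnover; it reproduces the documented input/output contract (monotone,
#' saturating response) without claiming mechanistic pathway kinetics.
NULL

.pathway_registry <- new.env(parent = emptyenv())

surrogate_model <- function(k_on = 20, k_off = 2, k_act = 2, k_dec = 1,
                            K = 0.3, h = 2, k_int = 0.2) {
  p <- list(k_on = k_on, k_off = k_off, k_act = k_act, k_dec = k_dec,
            K = K, h = h, k_int = k_int)
  list(
    n_state = 2L,
    state0 = c(rb = 0, out = 0),
    derivs = function(S, L, p) {
      rb <- S[, 1]; out <- S[, 2]
      hill <- rb^p$h / (p$K^p$h + rb^p$h)
      cbind(p$k_on * L * (1 - rb) - p$k_off * rb,
            p$k_act * hill - p$k_dec * out)
    },
    readout = 2L,
    consumption = function(S, L, p) p$k_int * S[, 1],
    params = p
  )
}

#' Register or fetch a pathway model
#'
#' @param name model name.
#' @param model a pathway model list (see [signaling]); omit to fetch.
#' @return the model, invisibly on registration.
#' @export
register_pathway <- function(name, model = NULL) {
  if (is.null(model)) {
    m <- get0(name, envir = .pathway_registry)
    if (is.null(m)) stop("unknown pathway model: ", name, call. = FALSE)
    return(m)
  }
  stopifnot(is.list(model),
            all(c("n_state", "state0", "derivs", "readout",
                  "consumption", "params") %in% names(model)))
  assign(name, model, envir = .pathway_registry)
  invisible(model)
}

local({
  assign("egfr_surrogate",
         surrogate_model(k_on = 20, k_off = 2, k_act = 2, k_dec = 1,
                         K = 0.3, h = 2, k_int = 0.2),
         envir = .pathway_registry)
  assign("tnf_surrogate",
         surrogate_model(k_on = 20, k_off = 2, k_act = 2, k_dec = 0.5,
                         K = 0.4, h = 2, k_int = 0.1),
         envir = .pathway_registry)
})

#' Integrate a pathway model for a batch of cells over one macro step
#'
#' Fixed-step 4th-order Runge-Kutta vectorized across cells, at a
#' sub-minute internal resolution that is refined automatically with the
#' ligand level (the binding rate sets the fastest time scale). Cells with
#' zero ligand and a basal state are returned unchanged without
#' integration. The local ligand concentration is held constant over the
#' macro step (it was just updated by the field solver); the integrated
#' ligand consumption is capped at the available amount.
#'
#' @param model a pathway model (name or list).
#' @param S state matrix (cells x states); `NULL` starts all cells at the
#'   basal state.
#' @param L ligand concentration per cell (field units, >= 0).
#' @param dt_macro macro step duration in hours.
#' @return list with the updated state matrix `S`, readout vector `out`,
#'   and `consumed` ligand per cell (field units, `<= L`).
#' @export
integrate_pathway <- function(model, S, L, dt_macro = 1) {
  if (is.character(model)) model <- register_pathway(model)
  stopifnot(all(L >= 0), dt_macro > 0)
  n <- length(L)
  if (is.null(S)) S <- matrix(rep(model$state0, each = n), nrow = n)
  stopifnot(nrow(S) == n, ncol(S) == model$n_state)
  consumed <- numeric(n)
  act <- which(L > 0 | rowSums(S) > 1e-12)
  if (length(act)) {
    Sa <- S[act, , drop = FALSE]
    La <- L[act]
    n_steps <- max(30L, min(7200L,
                            ceiling(30 * dt_macro * max(1, max(La)))))
    h <- dt_macro / n_steps
    p <- model$params
    ca <- numeric(length(act))
    for (k in seq_len(n_steps)) {
      k1 <- model$derivs(Sa, La, p)
      k2 <- model$derivs(Sa + h / 2 * k1, La, p)
      k3 <- model$derivs(Sa + h / 2 * k2, La, p)
      k4 <- model$derivs(Sa + h * k3, La, p)
      ca <- ca + h * model$consumption(Sa, La, p)
      Sa <- Sa + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      Sa[Sa < 0] <- 0
    }
    S[act, ] <- Sa
    consumed[act] <- pmin(ca, La)
  }
  list(S = S, out = S[, model$readout], consumed = consumed)
}

#' Advance the EGFR pathway of one cell
#'
#' TGF-alpha in, PLC-gamma out. The readout is monotone non-decreasing in
#' sustained ligand input and saturates at a finite steady state.
#'
#' @param local_tgfa local TGF-alpha concentration (>= 0).
#' @param state per-cell pathway state vector (`NULL` = basal).
#' @param dt_macro macro step in hours.
#' @param model pathway model name (default the shipped surrogate).
#' @return list with `state`, `plcg` (readout) and `consumed` TGF-alpha.
#' @export
integrate_egfr <- function(local_tgfa, state = NULL, dt_macro = 1,
                           model = "egfr_surrogate") {
  S <- if (is.null(state)) NULL else matrix(state, nrow = 1)
  r <- integrate_pathway(model, S, local_tgfa, dt_macro)
  list(state = drop(r$S), plcg = r$out[1], consumed = r$consumed[1])
}

#' Advance the TNF pathway of one cell
#'
#' TNF-alpha in, death signal out; the death signal is monotone
#' non-decreasing in sustained ligand input. Sustained TNF-alpha above the
#' policy threshold drives the death signal past [ds_threshold()] within
#' one macro step at the default calibration.
#'
#' @param local_tnfa local TNF-alpha concentration (>= 0).
#' @inheritParams integrate_egfr
#' @return list with `state`, `death_signal` and `consumed` TNF-alpha.
#' @export
integrate_tnf <- function(local_tnfa, state = NULL, dt_macro = 1,
                          model = "tnf_surrogate") {
  S <- if (is.null(state)) NULL else matrix(state, nrow = 1)
  r <- integrate_pathway(model, S, local_tnfa, dt_macro)
  list(state = drop(r$S), death_signal = r$out[1], consumed = r$consumed[1])
}

#' Death-signal policy threshold
#'
#' The death-signal level treated as "committed to die" by the decision
#' layer, calibrated so that TNF-alpha sustained at the rule-8 concentration
#' threshold for one macro step carries a basal cell across it.
#' @return scalar threshold.
#' @export
ds_threshold <- function() 1.0

#' Migrate-vs-proliferate preference from PLC-gamma
#'
#' A cell whose PLC-gamma strictly exceeds the mean PLC-gamma of all other
#' tissue cells prefers proliferation; otherwise it prefers migration. With
#' a singleton population the comparison is against a mean of 0, so any
#' positive PLC-gamma yields the proliferate preference.
#'
#' @param cell_plcg the cell's PLC-gamma level.
#' @param mean_other_plcg mean PLC-gamma over the other tissue cells.
#' @return `"proliferation"` or `"migration"`.
#' @export
plc_gamma_decision <- function(cell_plcg, mean_other_plcg) {
  if (cell_plcg > mean_other_plcg) "proliferation" else "migration"
}

# Mean-of-others for each cell given the full vector: (sum - x) / (n - 1);
# singleton populations compare against 0.
plcg_mean_others <- function(plcg) {
  n <- length(plcg)
  if (n <= 1L) return(rep(0, n))
  (sum(plcg) - plcg) / (n - 1L)
}
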