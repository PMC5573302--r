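#' @title NSGA-II multi-objective search
#' @name nsga2
#' @description
#' A real-coded elitist non-dominated sorting genetic algorithm:
#' fast non-dominated sorting into Pareto ranks, crowding-distance
#' diversity preservation, binary tournament selection on (rank, crowding),
#' simulated binary crossover (SBX) and polynomial mutation. All objectives
#' are maximized. Written against the standard algorithm description since
#' no multi-objective GA package is available as a dependency.
NULL

dominates <- function(a, b) all(a >= b) && any(a > b)

#' Fast non-dominated sorting
#' @param F objectives matrix (rows = individuals, columns = objectives,
#'   all maximized).
#' @return list of index vectors, one per Pareto front (best first).
#' @export
fast_nondominated_sort <- function(F) {
  n <- nrow(F)
  S <- vector("list", n)
  ncount <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(F[i, ], F[j, ])) S[[i]] <- c(S[[i]], j)
      else if (dominates(F[j, ], F[i, ])) ncount[i] <- ncount[i] + 1L
    }
  }
  fronts <- list()
  cur <- which(ncount == 0L)
  while (length(cur)) {
    fronts <- c(fronts, list(cur))
    nxt <- integer(0)
    for (i in cur) for (j in S[[i]]) {
      ncount[j] <- ncount[j] - 1L
      if (ncount[j] == 0L) nxt <- c(nxt, j)
    }
    cur <- nxt
  }
  fronts
}

#' Crowding distance within one front
#' @param F objectives matrix of the front members.
#' @return numeric vector of crowding distances (boundary points `Inf`).
#' @export
crowding_distance <- function(F) {
  n <- nrow(F)
  if (n <= 2L) return(rep(Inf, n))
  d <- numeric(n)
  for (m in seq_len(ncol(F))) {
    o <- order(F[, m])
    rng <- F[o[n], m] - F[o[1], m]
    d[o[c(1, n)]] <- Inf
    if (rng > 0)
      d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
        (F[o[3:n], m] - F[o[1:(n - 2)], m]) / rng
  }
  d
}

sbx_crossover <- function(p1, p2, lower, upper, eta = 15, pc = 0.9) {
  nv <- length(p1)
  c1 <- p1; c2 <- p2
  if (runif(1) < pc) {
    for (i in seq_len(nv)) {
      if (runif(1) > 0.5 || abs(p1[i] - p2[i]) < 1e-14) next
      u <- runif(1)
      beta <- if (u <= 0.5) (2 * u)^(1 / (eta + 1))
              else (1 / (2 * (1 - u)))^(1 / (eta + 1))
      c1[i] <- 0.5 * ((1 + beta) * p1[i] + (1 - beta) * p2[i])
      c2[i] <- 0.5 * ((1 - beta) * p1[i] + (1 + beta) * p2[i])
    }
  }
  list(pmin(pmax(c1, lower), upper), pmin(pmax(c2, lower), upper))
}

poly_mutation <- function(x, lower, upper, eta = 20, pm = NULL) {
  nv <- length(x)
  if (is.null(pm)) pm <- 1 / nv
  for (i in seq_len(nv)) {
    if (runif(1) >= pm) next
    u <- runif(1)
    delta <- if (u < 0.5) (2 * u)^(1 / (eta + 1)) - 1
             else 1 - (2 * (1 - u))^(1 / (eta + 1))
    x[i] <- x[i] + delta * (upper[i] - lower[i])
  }
  pmin(pmax(x, lower), upper)
}

rank_and_crowd <- function(F) {
  fronts <- fast_nondominated_sort(F)
  rank <- integer(nrow(F))
  crowd <- numeric(nrow(F))
  for (k in seq_along(fronts)) {
    idx <- fronts[[k]]
    rank[idx] <- k
    crowd[idx] <- crowding_distance(F[idx, , drop = FALSE])
  }
  list(rank = rank, crowd = crowd, fronts = fronts)
}

tournament <- function(rank, crowd) {
  n <- length(rank)
  pick <- function() {
    ij <- sample.int(n, 2L, replace = TRUE)
    i <- ij[1]; j <- ij[2]
    if (rank[i] < rank[j]) i
    else if (rank[j] < rank[i]) j
    else if (crowd[i] >= crowd[j]) i else j
  }
  pick()
}

#' Run the NSGA-II search
#'
#' @param eval_fn `function(x)` returning the objective vector (maximized)
#'   for a single real-valued decision vector `x`.
#' @param lower,upper decision-variable bounds.
#' @param pop_size population size (even, >= 4).
#' @param generations number of generations.
#' @param seed optional integer seed for the search's RNG stream.
#' @return list with final decision matrix `X`, objectives `F`, the indices
#'   `front` of the final non-dominated set, and `history`: per-generation
#'   list of the population objectives and first-front objectives.
#' @export
nsga2 <- function(eval_fn, lower, upper, pop_size = 20L, generations = 10L,
                  seed = NULL) {
  stopifnot(length(lower) == length(upper), all(upper >= lower),
            pop_size >= 4L)
  if (!is.null(seed)) set.seed(seed)
  nv <- length(lower)
  pop_size <- as.integer(pop_size + pop_size %% 2L)
  X <- matrix(runif(pop_size * nv, rep(lower, each = pop_size),
                    rep(upper, each = pop_size)), nrow = pop_size)
  F <- t(apply(X, 1, eval_fn))
  if (is.null(dim(F))) F <- matrix(F, nrow = pop_size)
  history <- vector("list", generations)
  for (g in seq_len(generations)) {
    rc <- rank_and_crowd(F)
    kidX <- matrix(NA_real_, nrow = pop_size, ncol = nv)
    for (m in seq_len(pop_size / 2L)) {
      p1 <- X[tournament(rc$rank, rc$crowd), ]
      p2 <- X[tournament(rc$rank, rc$crowd), ]
      ch <- sbx_crossover(p1, p2, lower, upper)
      kidX[2 * m - 1L, ] <- poly_mutation(ch[[1]], lower, upper)
      kidX[2 * m, ] <- poly_mutation(ch[[2]], lower, upper)
    }
    kidF <- t(apply(kidX, 1, eval_fn))
    if (is.null(dim(kidF))) kidF <- matrix(kidF, nrow = pop_size)
    allX <- rbind(X, kidX)
    allF <- rbind(F, kidF)
    rc2 <- rank_and_crowd(allF)
    keep <- integer(0)
    for (fr in rc2$fronts) {
      if (length(keep) + length(fr) <= pop_size) {
        keep <- c(keep, fr)
      } else {
        need <- pop_size - length(keep)
        cd <- crowding_distance(allF[fr, , drop = FALSE])
        keep <- c(keep, fr[order(cd, decreasing = TRUE)[seq_len(need)]])
        break
      }
    }
    X <- allX[keep, , drop = FALSE]
    F <- allF[keep, , drop = FALSE]
    ff <- fast_nondominated_sort(F)[[1]]
    history[[g]] <- list(F = F, front_F = F[ff, , drop = FALSE])
  }
  front <- fast_nondominated_sort(F)[[1]]
  list(X = X, F = F, front = front, history = history)
}

#' 2D hypervolume (maximization)
#'
#' Area dominated by a set of 2-objective points relative to a reference
#' point that every point dominates.
#'
#' @param F two-column objectives matrix.
#' @param ref length-2 reference point (componentwise below all of `F`).
#' @return scalar hypervolume.
#' @export
hypervolume_2d <- function(F, ref) {
  stopifnot(ncol(F) == 2L)
  nd <- fast_nondominated_sort(F)[[1]]
  P <- F[nd, , drop = FALSE]
  P <- P[order(P[, 1], decreasing = TRUE), , drop = FALSE]
  hv <- 0
  y_prev <- ref[2]
  for (i in seq_len(nrow(P))) {
    hv <- hv + (P[i, 1] - ref[1]) * max(0, P[i, 2] - y_prev)
    y_prev <- max(y_prev, P[i, 2])
  }
  hv
}
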