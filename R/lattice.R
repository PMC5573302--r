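#' Create an empty 3D lattice
#'
#' The lattice is the discrete tissue block: a regular grid of sites, each of
#' which may hold one tissue cell (healthy or cancerous), a permanent
#' necrotic-debris marker, or up to four endothelial (vessel) cells sharing
#' the site. Sites additionally carry a vessel annotation (parent artery or
#' vein, arteriole, venule, capillary) and a perfused flag used by the field
#' solver's source terms.
#'
#' Site contents are stored as flat vectors in site-linear order
#' (x fastest, then y, then z):
#' \describe{
#'   \item{occ}{integer; 0 = empty, > 0 = tissue cell id, -1 = necrotic marker.}
#'   \item{endo}{integer endothelial occupant count, 0..4.}
#'   \item{vessel}{integer vessel annotation, see [vessel_classes].}
#'   \item{perfused}{logical, whether blood flows at the site.}
#'   \item{nb}{n x 26 matrix of 1-based Moore-neighbor linear indices,
#'     0 where the neighbor is out of bounds.}
#' }
#'
#' Public coordinates are 0-based integer triples `(x, y, z)`;
#' [coords_to_index()] and [index_to_coords()] convert to and from linear
#' indices.
#'
#' @param nx,ny,nz lattice dimensions in sites.
#' @param dS lattice spacing (micrometers).
#' @param r_art,r_cap arteriole and capillary radii (micrometers), used by
#'   the field solver's vessel source terms.
#' @return an `oncosim_lattice` list.
#' @export
new_lattice <- function(nx, ny, nz, dS = 20, r_art = 6, r_cap = 2) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1, dS > 0, r_cap <= r_art)
  n <- as.integer(nx) * as.integer(ny) * as.integer(nz)
  lat <- list(
    dims = c(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz)),
    n = n,
    dS = dS, r_art = r_art, r_cap = r_cap,
    occ = integer(n),
    endo = integer(n),
    vessel = integer(n),
    perfused = logical(n),
    nb = build_neighbor_index(c(nx, ny, nz))
  )
  class(lat) <- "oncosim_lattice"
  lat
}

#' Vessel annotation codes
#'
#' Integer codes used in the lattice `vessel` vector: 0 none, 1 parent
#' artery, 2 parent vein, 3 arteriole, 4 venule, 5 capillary.
#' @format integer vector of length 6, named.
#' @export
vessel_classes <- c(none = 0L, artery = 1L, vein = 2L, arteriole = 3L,
                    venule = 4L, capillary = 5L)

moore_offsets <- function() {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off[rowSums(abs(off)) > 0, , drop = FALSE]
}

build_neighbor_index <- function(dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  n <- nx * ny * nz
  idx <- seq_len(n) - 1L
  x <- idx %% nx
  y <- (idx %/% nx) %% ny
  z <- idx %/% (nx * ny)
  off <- moore_offsets()
  nb <- matrix(0L, nrow = n, ncol = 26L)
  for (k in seq_len(26L)) {
    xx <- x + off[k, 1]; yy <- y + off[k, 2]; zz <- z + off[k, 3]
    ok <- xx >= 0 & xx < nx & yy >= 0 & yy < ny & zz >= 0 & zz < nz
    lin <- xx + nx * (yy + ny * zz) + 1L
    nb[, k] <- ifelse(ok, lin, 0L)
  }
  storage.mode(nb) <- "integer"
  nb
}

#' Convert 0-based lattice coordinates to linear site indices
#' @param lattice an `oncosim_lattice`.
#' @param xyz integer vector `c(x, y, z)` or a 3-column matrix of 0-based
#'   coordinates.
#' @return 1-based linear site index/indices.
#' @export
coords_to_index <- function(lattice, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  d <- lattice$dims
  if (any(xyz < 0) || any(xyz[, 1] >= d[1] | xyz[, 2] >= d[2] | xyz[, 3] >= d[3]))
    stop("site out of bounds", call. = FALSE)
  as.integer(xyz[, 1] + d[1] * (xyz[, 2] + d[2] * xyz[, 3]) + 1L)
}

#' Convert linear site indices to 0-based coordinates
#' @param lattice an `oncosim_lattice`.
#' @param idx 1-based linear indices.
#' @return integer matrix with columns x, y, z (0-based).
#' @export
index_to_coords <- function(lattice, idx) {
  d <- lattice$dims
  i <- as.integer(idx) - 1L
  cbind(x = i %% d[1], y = (i %/% d[1]) %% d[2], z = i %/% (d[1] * d[2]))
}

#' Moore neighborhood of a site
#'
#' All lattice sites at Chebyshev distance 1 from the given site: 26 for an
#' interior site, fewer on faces, edges and corners (only in-bounds
#' neighbors are returned).
#'
#' @param site 0-based integer coordinates `c(x, y, z)`.
#' @param lattice an `oncosim_lattice`.
#' @return integer matrix of 0-based neighbor coordinates (possibly 0 rows).
#' @examples
#' lat <- new_lattice(3, 3, 3)
#' nrow(moore_neighbors(c(1, 1, 1), lat))  # 26
#' nrow(moore_neighbors(c(0, 0, 0), lat))  # 7
#' @export
moore_neighbors <- function(site, lattice) {
  i <- coords_to_index(lattice, site)
  nbs <- lattice$nb[i, ]
  index_to_coords(lattice, nbs[nbs > 0L])
}

#' Can a cell of the given type occupy a site?
#'
#' A tissue cell (healthy or cancerous) may enter only an empty site; an
#' endothelial cell (tip or stalk) may enter a site with no tissue cell and
#' fewer than four endothelial occupants. A necrotic marker permanently
#' blocks all occupancy.
#'
#' @param lattice an `oncosim_lattice`.
#' @param site 0-based coordinates or (if `linear = TRUE`) a 1-based linear
#'   index.
#' @param celltype one of `"healthy"`, `"cancerous"`, `"tip"`, `"stalk"`.
#' @param linear interpret `site` as a linear index.
#' @return logical.
#' @export
can_occupy <- function(lattice, site, celltype, linear = FALSE) {
  i <- if (linear) as.integer(site) else coords_to_index(lattice, site)
  if (lattice$occ[i] == -1L) return(FALSE)
  if (celltype %in% c("healthy", "cancerous"))
    lattice$occ[i] == 0L && lattice$endo[i] == 0L
  else if (celltype %in% c("tip", "stalk"))
    lattice$occ[i] == 0L && lattice$endo[i] < 4L
  else stop("unknown cell type: ", celltype, call. = FALSE)
}

#' Resolve simultaneous claims on lattice sites
#'
#' All cells propose their moves for a macro step simultaneously; contested
#' sites are then resolved in one batch. When a cancerous and a healthy cell
#' claim the same empty site the cancerous cell wins; among claimants of the
#' same type one winner is drawn uniformly from the current RNG stream.
#' Endothelial claims are granted up to the free endothelial slots of the
#' site (tissue claims, if any, take precedence). Losers stay stationary.
#'
#' @param claims data.frame with columns `cell` (id), `type` (cell type) and
#'   `site` (1-based linear target index).
#' @return the subset of `claims` rows that won their site.
#' @export
resolve_competition <- function(claims, lattice = NULL) {
  n <- nrow(claims)
  if (n == 0L) return(claims)
  keep <- logical(n)
  tissue <- claims$type %in% c("healthy", "cancerous")
  # tissue claims: per contested site, cancerous claimants dominate and a
  # uniform random key breaks same-type ties in one vectorized pass
  trows <- which(tissue)
  if (length(trows)) {
    pri <- as.integer(claims$type[trows] == "cancerous")
    key <- runif(length(trows))
    # order by site, cancerous claimants first, then the random key
    ord <- trows[order(claims$site[trows], -pri, key)]
    keep[ord[!duplicated(claims$site[ord])]] <- TRUE
  }
  # endothelial claims: up to the free slots per site; sites already won by
  # a tissue claim are off limits
  erows <- which(!tissue)
  if (length(erows)) {
    tissue_won <- unique(claims$site[keep])
    erows <- erows[!claims$site[erows] %in% tissue_won]
    for (s in unique(claims$site[erows])) {
      rows <- erows[claims$site[erows] == s]
      slots <- if (is.null(lattice)) 1L else max(0L, 4L - lattice$endo[s])
      win <- if (length(rows) <= slots) rows else
        rows[sample.int(length(rows), slots)]
      keep[win] <- TRUE
    }
  }
  claims[keep, , drop = FALSE]
}
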