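#' Periodic simulation box
#'
#' The amnioserosa is approximated by a rectangle with periodic boundary
#' conditions in both directions; the long (`Lx`) axis corresponds to the
#' anterior--posterior axis of the embryo.
#'
#' @param Lx,Ly box edge lengths (model length units); both must be positive.
#' @return An object of class `"tissue_box"`: a list with elements `Lx`, `Ly`.
#' @export
tissue_box <- function(Lx, Ly) {
  stopifnot(is.numeric(Lx), is.numeric(Ly), length(Lx) == 1L, length(Ly) == 1L)
  if (!is.finite(Lx) || !is.finite(Ly) || Lx <= 0 || Ly <= 0)
    stop("box dimensions must be positive and finite")
  structure(list(Lx = as.numeric(Lx), Ly = as.numeric(Ly)), class = "tissue_box")
}

#' Construct a tissue state
#'
#' A confluent periodic tiling: vertex positions, counter-clockwise cell
#' cycles, per-cell preferred perimeters and a shared preferred area. All
#' geometry is computed under the minimum-image convention, so cells may
#' straddle the periodic boundaries.
#'
#' @param vertices numeric matrix (V x 2) of vertex positions; stored wrapped
#'   into `[0, Lx) x [0, Ly)`.
#' @param cells list of integer vectors, each a counter-clockwise vertex cycle.
#' @param p0 numeric vector of preferred perimeters, one per cell.
#' @param a0 shared preferred cell area (scalar).
#' @param box a [tissue_box()].
#' @param cell_ids integer identifiers preserved across T2 removals (defaults
#'   to `seq_along(cells)`).
#' @param validate check the trivalent-tiling invariants (degree-3 vertices,
#'   every edge shared by exactly two cells, positive CCW areas summing to
#'   the box area).
#' @return An object of class `"tissue_state"`.
#' @export
tissue_state <- function(vertices, cells, p0, a0, box,
                         cell_ids = seq_along(cells), validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  stopifnot(ncol(vertices) == 2L, is.list(cells), length(p0) == length(cells))
  vertices[, 1] <- vertices[, 1] %% box$Lx
  vertices[, 2] <- vertices[, 2] %% box$Ly
  state <- structure(list(
    vertices = vertices,
    cells = lapply(cells, as.integer),
    p0 = as.numeric(p0),
    a0 = as.numeric(a0),
    box = box,
    alive = rep(TRUE, length(cells)),
    cell_ids = as.integer(cell_ids)
  ), class = "tissue_state")
  if (validate) validate_tissue(state)
  state
}

# flatten cell cycles for the C++ kernels (0-based)
.flat_cells <- function(state) {
  lens <- lengths(state$cells)
  list(starts = as.integer(c(0L, cumsum(lens))),
       verts = as.integer(unlist(state$cells, use.names = FALSE) - 1L))
}

#' Validate tissue invariants
#'
#' Checks trivalence (every vertex in exactly three cell cycles), that each
#' edge is shared by exactly two cells with opposite orientation, the Euler
#' relation on the torus (E = 3V/2, F = V/2), positive cell areas, and that
#' cell areas sum to the box area (confluence) within `tol` relative error.
#'
#' @param state a [tissue_state()].
#' @param tol relative tolerance for the area-sum check.
#' @return Invisibly `TRUE`; errors describe the first violated invariant.
#' @export
validate_tissue <- function(state, tol = 1e-9) {
  V <- nrow(state$vertices)
  degree <- tabulate(unlist(state$cells, use.names = FALSE), nbins = V)
  if (any(degree != 3L))
    stop("vertex degree != 3 at vertices: ",
         paste(utils::head(which(degree != 3L), 5L), collapse = ", "))
  F <- length(state$cells)
  if (2L * F != V) stop("Euler relation violated: expected V = 2F")
  ed <- .directed_edges(state)
  key_fwd <- paste(ed$from, ed$to)
  key_rev <- paste(ed$to, ed$from)
  if (anyDuplicated(key_fwd))
    stop("duplicated directed edge: tiling is not a valid oriented 2-complex")
  if (!all(key_rev %in% key_fwd))
    stop("edge not shared by exactly two cells with opposite orientation")
  geo <- cell_geometry(state)
  if (any(geo$area <= 0))
    stop("non-positive cell area (cycle not CCW?) at cell ",
         which(geo$area <= 0)[1L])
  box_area <- state$box$Lx * state$box$Ly
  if (abs(sum(geo$area) - box_area) > tol * box_area)
    stop(sprintf("cell areas sum to %.12g but box area is %.12g",
                 sum(geo$area), box_area))
  invisible(TRUE)
}

# all directed edges (from, to, cell)
.directed_edges <- function(state) {
  lens <- lengths(state$cells)
  from <- unlist(state$cells, use.names = FALSE)
  to <- unlist(lapply(state$cells, function(cy) c(cy[-1L], cy[1L])),
               use.names = FALSE)
  data.frame(from = from, to = to, cell = rep(seq_along(state$cells), lens))
}

#' Junction table of a tissue
#'
#' Each junction (undirected edge) is shared by exactly two cells. Returns
#' one row per junction with its vertex pair, the adjacent cell pair, and
#' its minimum-image length.
#'
#' @param state a [tissue_state()].
#' @return data frame with columns `v1`, `v2`, `cell_i`, `cell_j`, `length`.
#' @export
tissue_junctions <- function(state) {
  ed <- .directed_edges(state)
  fwd <- ed$from < ed$to
  a <- ed[fwd, ]
  b <- ed[!fwd, ]
  idx <- match(paste(a$from, a$to), paste(b$to, b$from))
  if (anyNA(idx)) stop("unpaired edge: invalid tiling")
  d <- .min_image(state$vertices[a$to, , drop = FALSE] -
                  state$vertices[a$from, , drop = FALSE], state$box)
  data.frame(v1 = a$from, v2 = a$to, cell_i = a$cell, cell_j = b$cell[idx],
             length = sqrt(rowSums(d^2)))
}

.min_image <- function(d, box) {
  d[, 1] <- d[, 1] - box$Lx * round(d[, 1] / box$Lx)
  d[, 2] <- d[, 2] - box$Ly * round(d[, 2] / box$Ly)
  d
}

#' Per-cell areas and perimeters
#'
#' Areas by the shoelace formula on minimum-image unwrapped cycles;
#' perimeters as sums of minimum-image edge lengths.
#'
#' @param state a [tissue_state()].
#' @return data frame with columns `cell`, `area`, `perimeter`.
#' @export
cell_geometry <- function(state) {
  fc <- .flat_cells(state)
  g <- vm_geometry(state$vertices, fc$starts, fc$verts,
                   state$box$Lx, state$box$Ly)
  data.frame(cell = seq_along(state$cells), area = g$area,
             perimeter = g$perimeter)
}

#' Cell shape index
#'
#' The dimensionless elongation measure q = perimeter / sqrt(area). A regular
#' hexagon has q ~= 3.7224; the standard vertex model fluidizes when the mean
#' shape index exceeds about 3.81.
#'
#' @param area,perimeter numeric vectors (recycled to common length).
#' @return numeric vector of shape indices.
#' @export
shape_index <- function(area, perimeter) {
  if (any(!is.finite(area)) || any(area <= 0))
    stop("shape index requires positive areas")
  perimeter / sqrt(area)
}

#' Random periodic Voronoi tissue
#'
#' Standard vertex-model initialization: the Voronoi diagram of `n_cells`
#' uniformly random seed points in a periodic box, computed by replicating
#' the seeds on a 3x3 tile and extracting the central cells. Generic random
#' seeds give a trivalent tiling; degenerate (cocircular) configurations are
#' jittered and retried.
#'
#' @param n_cells number of cells (>= 3).
#' @param box a [tissue_box()].
#' @param seed integer RNG seed; identical seeds give identical tilings.
#' @param p0 preferred perimeter(s) assigned to the cells (default the
#'   perimeter of a regular hexagon of area `a0`).
#' @param a0 preferred cell area.
#' @param max_retries jitter-and-retry attempts for degenerate diagrams.
#' @return A [tissue_state()].
#' @export
build_voronoi_tissue <- function(n_cells, box, seed = 1L,
                                 p0 = NULL, a0 = 1, max_retries = 8L) {
  if (n_cells < 3L) stop("n_cells must be at least 3")
  set.seed(seed)
  pts <- cbind(stats::runif(n_cells, 0, box$Lx),
               stats::runif(n_cells, 0, box$Ly))
  for (try in seq_len(max_retries)) {
    state <- tryCatch(.voronoi_state(pts, box, a0), error = function(e) e)
    if (!inherits(state, "error")) {
      if (is.null(p0)) p0 <- .hex_perimeter(a0)
      state$p0 <- rep_len(as.numeric(p0), n_cells)
      return(state)
    }
    pts <- pts + matrix(stats::rnorm(2 * n_cells, 0, 1e-8 * sqrt(a0)),
                        ncol = 2)
    pts[, 1] <- pts[, 1] %% box$Lx
    pts[, 2] <- pts[, 2] %% box$Ly
  }
  stop("degenerate Voronoi diagram persisted after ", max_retries,
       " jitter retries: ", conditionMessage(state))
}

# perimeter of a regular hexagon with given area
.hex_perimeter <- function(a0 = 1) 6 * sqrt(2 * a0 / (3 * sqrt(3)))

# Periodic Voronoi via Delaunay triangulation of a 3x3 replication.
# Voronoi vertices are identified combinatorially (canonical Delaunay
# triangles modulo lattice shifts), so no coordinate-tolerance dedup is
# needed: each Voronoi vertex is the circumcenter of one canonical triangle.
.voronoi_state <- function(pts, box, a0) {
  n <- nrow(pts)
  shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1))
  allx <- rep(pts[, 1], nrow(shifts)) + rep(shifts[, 1] * box$Lx, each = n)
  ally <- rep(pts[, 2], nrow(shifts)) + rep(shifts[, 2] * box$Ly, each = n)
  dd <- deldir::deldir(allx, ally,
                       rw = c(-box$Lx, 2 * box$Lx, -box$Ly, 2 * box$Ly),
                       suppressMsge = TRUE, round = FALSE)
  tl <- deldir::triang.list(dd)

  vkey <- new.env(parent = emptyenv())
  vpos <- list()
  nv <- 0L
  # per cell: vertex ids and unwrapped corner positions for angular sorting
  cell_v <- vector("list", n)
  cell_x <- vector("list", n)
  cell_y <- vector("list", n)

  circum <- function(P) {
    ax <- P[1, 1]; ay <- P[1, 2]
    bx <- P[2, 1] - ax; by <- P[2, 2] - ay
    cx <- P[3, 1] - ax; cy <- P[3, 2] - ay
    d <- 2 * (bx * cy - by * cx)
    if (abs(d) < 1e-300) stop("degenerate (collinear) Delaunay triangle")
    ux <- (cy * (bx^2 + by^2) - by * (cx^2 + cy^2)) / d
    uy <- (bx * (cx^2 + cy^2) - cx * (bx^2 + by^2)) / d
    c(ax + ux, ay + uy)
  }

  for (tr in tl) {
    pt <- tr$ptNum
    orig <- (pt - 1L) %% n + 1L
    blk <- (pt - 1L) %/% n + 1L
    cen <- which(shifts[blk, 1] == 0 & shifts[blk, 2] == 0)
    if (!length(cen)) next  # no central-copy corner: not needed for any cell
    if (anyDuplicated(orig))
      stop("triangle joins two periodic images of one seed: box too small")
    # canonical form: shifts relative to the smallest original id
    o <- order(orig)
    ds <- shifts[blk, , drop = FALSE][o, , drop = FALSE]
    ds <- sweep(ds, 2L, ds[1L, ], "-")
    key <- paste(orig[o], ds[, 1], ds[, 2], collapse = ";")
    id <- vkey[[key]]
    if (is.null(id)) {
      P <- cbind(pts[orig[o], 1] + ds[, 1] * box$Lx,
                 pts[orig[o], 2] + ds[, 2] * box$Ly)
      nv <- nv + 1L
      id <- nv
      vkey[[key]] <- id
      vpos[[id]] <- circum(P)
    }
    # canonical circumcenter; the shift of the reference (smallest-id) point
    # in THIS triangle instance converts it to instance coordinates
    ref_shift <- shifts[blk, , drop = FALSE][o[1L], ]
    cc <- vpos[[id]] + ref_shift * c(box$Lx, box$Ly)
    for (k in cen) {
      i <- orig[k]
      cell_v[[i]] <- c(cell_v[[i]], id)
      cell_x[[i]] <- c(cell_x[[i]], cc[1])
      cell_y[[i]] <- c(cell_y[[i]], cc[2])
    }
  }

  cells <- vector("list", n)
  for (i in seq_len(n)) {
    if (length(cell_v[[i]]) < 3L) stop("degenerate tile with fewer than 3 vertices")
    ang <- atan2(cell_y[[i]] - pts[i, 2], cell_x[[i]] - pts[i, 1])
    cells[[i]] <- cell_v[[i]][order(ang)]  # CCW
    if (anyDuplicated(cells[[i]])) stop("tile with duplicated vertex")
  }
  vm <- do.call(rbind, vpos)
  vm[, 1] <- vm[, 1] %% box$Lx
  vm[, 2] <- vm[, 2] %% box$Ly
  tissue_state(vm, cells, p0 = rep(.hex_perimeter(a0), n), a0 = a0, box = box)
}

#' Regular hexagonal lattice tissue
#'
#' A periodic honeycomb of `nx` by `ny` regular hexagons of area `a0`. Used
#' as an analytic reference configuration: the lattice is a stationary state
#' of the energy, every cell has shape index 2 sqrt(6) 3^(-1/4) ~= 3.7224.
#'
#' @param nx columns of hexagons; `ny` rows (must be even for periodicity).
#' @param a0 cell area.
#' @param p0 preferred perimeter assigned to every cell (default the regular
#'   hexagon perimeter, the zero-tension value).
#' @return A [tissue_state()].
#' @export
build_hex_tissue <- function(nx, ny, a0 = 1, p0 = NULL) {
  if (ny %% 2L != 0L) stop("ny must be even for a periodic honeycomb")
  s <- sqrt(2 * a0 / (3 * sqrt(3)))  # hexagon side
  w <- sqrt(3) * s
  box <- tissue_box(nx * w, ny * 1.5 * s)
  eps <- 1e-9 * sqrt(box$Lx * box$Ly)
  vkey <- new.env(parent = emptyenv())
  verts <- list()
  nv <- 0L
  getv <- function(x, y) {
    xq <- round((x %% box$Lx) / eps)
    yq <- round((y %% box$Ly) / eps)
    # snap near-box coordinates back to 0
    if (xq >= round(box$Lx / eps)) xq <- 0
    if (yq >= round(box$Ly / eps)) yq <- 0
    key <- paste(xq, yq)
    id <- vkey[[key]]
    if (!is.null(id)) return(id)
    nv <<- nv + 1L
    # store the exact (first-seen) coordinate, only keyed on the grid
    verts[[nv]] <<- c(if (xq == 0) 0 else x %% box$Lx,
                      if (yq == 0) 0 else y %% box$Ly)
    vkey[[key]] <- nv
    nv
  }
  # pointy-top hexagon: vertices at angles 90, 150, ..., 390 degrees
  ang <- pi / 2 + (0:5) * pi / 3
  cells <- vector("list", nx * ny)
  k <- 0L
  for (j in 0:(ny - 1L)) for (i in 0:(nx - 1L)) {
    cx <- (i + 0.5 * (j %% 2L)) * w
    cy <- j * 1.5 * s
    k <- k + 1L
    # reverse for CCW ordering (angles listed clockwise give CW otherwise)
    vx <- cx + s * cos(ang)
    vy <- cy + s * sin(ang)
    area2 <- sum(vx * c(vy[-1], vy[1]) - c(vx[-1], vx[1]) * vy)
    ord <- if (area2 < 0) 6:1 else 1:6
    cells[[k]] <- vapply(ord, function(q) getv(vx[q], vy[q]), integer(1))
  }
  vm <- do.call(rbind, verts)
  if (is.null(p0)) p0 <- 6 * s
  tissue_state(vm, cells, p0 = rep_len(p0, nx * ny), a0 = a0, box = box)
}

#' Write / read a tissue snapshot as JSON
#'
#' Lossless round-trip (full double precision) of a tissue state: box,
#' vertices, cell cycles, preferred perimeters, preferred area and a schema
#' version string.
#'
#' @param state a [tissue_state()].
#' @param path file path.
#' @return `write_tissue_json` returns `path` invisibly; `read_tissue_json`
#'   returns the reconstructed [tissue_state()].
#' @export
write_tissue_json <- function(state, path) {
  doc <- list(
    schema = "vertexclosure/tissue-v1",
    box = list(Lx = state$box$Lx, Ly = state$box$Ly),
    vertices = unname(split(state$vertices, row(state$vertices))),
    cells = lapply(state$cells, as.integer),
    p0 = state$p0,
    a0 = state$a0,
    cell_ids = state$cell_ids
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_tissue_json
#' @export
read_tissue_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "vertexclosure/tissue-v1"))
    stop("unrecognized snapshot schema: ", doc$schema)
  verts <- if (is.list(doc$vertices)) do.call(rbind, doc$vertices) else
    doc$vertices
  cells <- if (is.data.frame(doc$cells)) as.list(as.data.frame(t(doc$cells)))
    else if (is.matrix(doc$cells)) lapply(seq_len(nrow(doc$cells)), function(i) doc$cells[i, ])
    else doc$cells
  tissue_state(verts, cells, p0 = doc$p0, a0 = doc$a0,
               box = tissue_box(doc$box$Lx, doc$box$Ly),
               cell_ids = doc$cell_ids)
}

#' @export
print.tissue_state <- function(x, ...) {
  cat(sprintf(
    "tissue_state: %d cells, %d vertices, box %.4g x %.4g (a0 = %g)\n",
    length(x$cells), nrow(x$vertices), x$box$Lx, x$box$Ly, x$a0))
  invisible(x)
}
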