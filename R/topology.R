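#' T1 transition (neighbor exchange)
#'
#' Reconnects the network across a (short) junction: the two cells that
#' share the junction lose their common edge and their adjacency, while the
#' two cells meeting the junction only at its endpoints become neighbors
#' across a new edge rotated by 90 degrees and set to `post_length`.
#' Trivalence and counter-clockwise orientation are preserved.
#'
#' In the closure protocol this move fires only when a junction shrinks
#' below the T1 threshold length during energy minimization; its complete
#' absence along a trajectory is the signature of solid tissue.
#'
#' @param state a [tissue_state()].
#' @param junction integer vector `c(v1, v2)`: the vertex pair of the edge.
#' @param post_length length of the reconnected edge (default
#'   `1.5 * 0.02 * sqrt(a0)`, one and a half T1 thresholds).
#' @return The flipped [tissue_state()], with attribute `"t1_info"` listing
#'   the four cells involved (as persistent cell ids).
#' @export
t1_flip <- function(state, junction, post_length = NULL) {
  a <- as.integer(junction[1]); b <- as.integer(junction[2])
  if (is.null(post_length)) post_length <- 1.5 * 0.02 * sqrt(state$a0)
  ncell <- length(state$cells)
  has_a <- which(vapply(state$cells, function(cy) a %in% cy, logical(1)))
  has_b <- which(vapply(state$cells, function(cy) b %in% cy, logical(1)))
  both <- intersect(has_a, has_b)
  if (length(both) != 2L)
    stop("vertices ", a, ",", b, " do not bound a junction of two cells")
  # c1 carries the directed edge a->b, c2 the reverse
  dir_ab <- vapply(state$cells[both], function(cy) {
    i <- match(a, cy); cy[if (i == length(cy)) 1L else i + 1L] == b
  }, logical(1))
  if (sum(dir_ab) != 1L) stop("vertices ", a, ",", b, " are not adjacent in the cycles")
  c1 <- both[dir_ab]; c2 <- both[!dir_ab]
  c3 <- setdiff(has_a, both); c4 <- setdiff(has_b, both)
  if (length(c3) != 1L || length(c4) != 1L) stop("network is not trivalent at the junction")
  if (c3 == c4)
    stop("T1 rejected: flip would create a two-sided cell (cells ",
         state$cell_ids[c3], " touch at both endpoints)")
  if (length(state$cells[[c1]]) < 4L || length(state$cells[[c2]]) < 4L)
    stop("T1 rejected: cell ", state$cell_ids[if (length(state$cells[[c1]]) < 4L) c1 else c2],
         " would drop below 3 sides")

  cells <- state$cells
  cells[[c1]] <- setdiff(cells[[c1]], b)
  cells[[c2]] <- setdiff(cells[[c2]], a)
  ins_before <- function(cy, at, val) {
    i <- match(at, cy)
    append(cy, val, after = i - 1L)
  }
  cells[[c3]] <- ins_before(cells[[c3]], a, b)
  cells[[c4]] <- ins_before(cells[[c4]], b, a)

  # place the rotated edge about the old midpoint, choosing the orientation
  # sign that keeps all four affected cells positively oriented
  box <- state$box
  ra <- state$vertices[a, ]
  d <- state$vertices[b, ] - ra
  d <- c(d[1] - box$Lx * round(d[1] / box$Lx), d[2] - box$Ly * round(d[2] / box$Ly))
  mid <- ra + d / 2
  nrm <- c(-d[2], d[1]) / sqrt(sum(d^2))
  base <- state$vertices
  out <- NULL
  for (sgn in c(1, -1)) {
    vt <- base
    vt[a, ] <- (mid + sgn * nrm * post_length / 2) %% c(box$Lx, box$Ly)
    vt[b, ] <- (mid - sgn * nrm * post_length / 2) %% c(box$Lx, box$Ly)
    cand <- state
    cand$vertices <- vt
    cand$cells <- cells
    fcc <- .flat_cells(cand)
    g <- vm_geometry(cand$vertices, fcc$starts, fcc$verts, box$Lx, box$Ly)
    if (all(g$area[c(c1, c2, c3, c4)] > 0)) { out <- cand; break }
  }
  if (is.null(out))
    stop("T1 rejected: no orientation of the rotated edge keeps all cells simple")
  attr(out, "t1_info") <- list(
    vertices = c(a, b),
    lost = state$cell_ids[c(c1, c2)],
    gained = state$cell_ids[c(c3, c4)])
  out
}

#' T2 event: remove a cell (ingression)
#'
#' Collapses a cell to a single trivalent vertex at its centroid, modelling
#' an amnioserosa cell ingressing out of the apical plane. Cells with more
#' than three sides are first reduced to a triangle by T1 moves on their
#' shortest edges (each flip removes one side), so that the final collapse
#' replaces the triangle by one degree-3 vertex and the tiling stays
#' confluent and trivalent throughout.
#'
#' @param state a [tissue_state()].
#' @param cell_id persistent cell identifier (matched against
#'   `state$cell_ids`).
#' @return The reduced [tissue_state()] (one fewer cell), with attribute
#'   `"t2_info"` recording the removed id and any internal T1 flips.
#' @export
t2_remove_cell <- function(state, cell_id) {
  ci <- match(as.integer(cell_id), state$cell_ids)
  if (is.na(ci))
    stop("cell ", cell_id, " does not exist or was already removed")
  if (length(state$cells) <= 3L)
    stop("cannot remove a cell from a tiling of 3 or fewer cells")
  n_internal_t1 <- 0L
  guard <- 0L
  while (length(state$cells[[ci]]) > 3L) {
    guard <- guard + 1L
    if (guard > 64L) stop("T2 failed: could not reduce cell ", cell_id, " to a triangle")
    cy <- state$cells[[ci]]
    nxt <- c(cy[-1L], cy[1L])
    d <- .min_image(state$vertices[nxt, , drop = FALSE] -
                    state$vertices[cy, , drop = FALSE], state$box)
    len <- sqrt(rowSums(d^2))
    done <- FALSE
    for (k in order(len)) {
      res <- tryCatch(t1_flip(state, c(cy[k], nxt[k])), error = function(e) e)
      if (!inherits(res, "error")) {
        state <- res
        n_internal_t1 <- n_internal_t1 + 1L
        done <- TRUE
        break
      }
    }
    if (!done) stop("T2 failed: no admissible T1 on cell ", cell_id)
  }
  tri <- state$cells[[ci]]
  box <- state$box
  # centroid of the triangle, unwrapped about its first vertex
  r1 <- state$vertices[tri[1L], ]
  dd <- .min_image(state$vertices[tri, , drop = FALSE] -
                   matrix(r1, 3L, 2L, byrow = TRUE), box)
  w_pos <- (r1 + colMeans(dd)) %% c(box$Lx, box$Ly)
  verts <- rbind(state$vertices, w_pos)
  w <- nrow(verts)
  cells <- state$cells
  for (j in seq_along(cells)) {
    if (j == ci) next
    cy <- cells[[j]]
    hit <- which(cy %in% tri)
    if (!length(hit)) next
    if (length(hit) != 2L)
      stop("T2 failed: neighbor shares more than one edge with cell ", cell_id)
    if (length(cy) <= 3L)
      stop("T2 failed: neighbor of cell ", cell_id, " would drop below 3 sides")
    keep <- cy[-hit]
    # insert w where the shared pair sat (cycle position of the first hit,
    # accounting for wrap-around of the consecutive pair)
    at <- if (all(c(1L, length(cy)) %in% hit)) length(keep) + 1L else min(hit)
    cells[[j]] <- append(keep, w, after = at - 1L)
  }
  cells[[ci]] <- NULL
  removed_id <- state$cell_ids[ci]
  p0 <- state$p0[-ci]
  ids <- state$cell_ids[-ci]
  # drop the triangle's vertices and remap indices
  keep_v <- setdiff(seq_len(nrow(verts)), tri)
  remap <- integer(nrow(verts))
  remap[keep_v] <- seq_along(keep_v)
  cells <- lapply(cells, function(cy) remap[cy])
  out <- tissue_state(verts[keep_v, , drop = FALSE], cells, p0 = p0,
                      a0 = state$a0, box = box, cell_ids = ids)
  # carry protocol bookkeeping (initial box, initial preferred perimeters)
  if (!is.null(state$box0)) out$box0 <- state$box0
  if (!is.null(state$p0_init)) out$p0_init <- state$p0_init[-ci]
  attr(out, "t2_info") <- list(removed = removed_id,
                               internal_t1 = n_internal_t1)
  out
}
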