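neighbor_pairs <- function(state) {
  jn <- tissue_junctions(state)
  paste(pmin(jn$cell_i, jn$cell_j), pmax(jn$cell_i, jn$cell_j))
}

test_that("T1 flip exchanges neighbors and preserves the tiling invariants", {
  st <- vor36()
  jn <- tissue_junctions(st)
  e <- which.min(jn$length)
  n0 <- neighbor_pairs(st)

  st1 <- t1_flip(st, c(jn$v1[e], jn$v2[e]), post_length = 0.05)
  expect_silent(validate_tissue(st1))
  info <- attr(st1, "t1_info")
  n1 <- neighbor_pairs(st1)
  lost <- paste(min(info$lost), max(info$lost))
  gained <- paste(min(info$gained), max(info$gained))
  expect_true(lost %in% n0 && !(lost %in% n1))
  expect_true(!(gained %in% n0) && gained %in% n1)

  # area conservation through the move
  expect_equal(sum(cell_geometry(st1)$area), st$box$Lx * st$box$Ly,
               tolerance = 1e-9)

  # involution on adjacency: flipping the new edge back restores neighbors
  jn1 <- tissue_junctions(st1)
  e1 <- which(paste(pmin(jn1$cell_i, jn1$cell_j),
                    pmax(jn1$cell_i, jn1$cell_j)) == gained)
  st2 <- t1_flip(st1, c(jn1$v1[e1], jn1$v2[e1]),
                 post_length = jn$length[e])
  expect_setequal(neighbor_pairs(st2), n0)
})

test_that("T1 guards reject degenerate flips", {
  # drive a cell down to three sides by repeated flips, then any flip that
  # would reduce it further is rejected
  st <- vor36()
  target <- which.min(lengths(st$cells))
  guard <- 0L
  while (length(st$cells[[target]]) > 3L && guard < 20L) {
    guard <- guard + 1L
    cy <- st$cells[[target]]
    nxt <- c(cy[-1L], cy[1L])
    for (k in seq_along(cy)) {
      # the target cell holds the directed edge, so an admissible flip
      # removes one of its sides
      cand <- tryCatch(t1_flip(st, c(cy[k], nxt[k]), post_length = 0.05),
                       error = function(err) NULL)
      if (!is.null(cand)) { st <- cand; break }
    }
  }
  expect_equal(length(st$cells[[target]]), 3L)
  cy <- st$cells[[target]]
  expect_error(t1_flip(st, c(cy[1], cy[2])), "3 sides|two-sided")
  # vertex pair that is not an edge
  st <- vor36()
  jn <- tissue_junctions(st)
  non_edge <- setdiff(seq_len(nrow(st$vertices)),
                      c(jn$v1[jn$v1 == 1 | jn$v2 == 1],
                        jn$v2[jn$v1 == 1 | jn$v2 == 1], 1))[1]
  expect_error(t1_flip(st, c(1, non_edge)))
})

test_that("T2 removal keeps the tiling confluent and trivalent", {
  st <- vor36()
  st3 <- st
  for (cid in c(5, 17, 29)) st3 <- t2_remove_cell(st3, cid)
  expect_silent(validate_tissue(st3))
  expect_equal(length(st3$cells), 33L)
  # Euler count: V = 2F after every removal
  expect_equal(nrow(st3$vertices), 66L)
  expect_equal(sum(cell_geometry(st3)$area), st$box$Lx * st$box$Ly,
               tolerance = 1e-9)
  # persistent ids survive removals
  expect_false(any(c(5, 17, 29) %in% st3$cell_ids))
  # removing an already-removed cell errors
  expect_error(t2_remove_cell(st3, 5), "already removed|does not exist")
})

test_that("T2 carries protocol bookkeeping through the rebuild", {
  st <- vor36()
  st$box0 <- st$box
  st$p0_init <- st$p0 * 1.1
  st2 <- t2_remove_cell(st, 7)
  expect_identical(st2$box0, st$box)
  expect_equal(length(st2$p0_init), 35L)
  expect_equal(st2$p0_init, (st$p0 * 1.1)[-7])
})

test_that("a long random T1/T2 sequence never breaks Euler or confluence", {
  st <- build_voronoi_tissue(24, tissue_box(5, 5), seed = 9)
  set.seed(42)
  for (i in 1:12) {
    if (runif(1) < 0.5) {
      jn <- tissue_junctions(st)
      e <- sample.int(nrow(jn), 1)
      st_new <- tryCatch(t1_flip(st, c(jn$v1[e], jn$v2[e]),
                                 post_length = jn$length[e]),
                         error = function(err) NULL)
    } else {
      cid <- sample(st$cell_ids, 1)
      st_new <- tryCatch(t2_remove_cell(st, cid), error = function(err) NULL)
    }
    if (is.null(st_new)) next
    st <- st_new
    expect_silent(validate_tissue(st))
    expect_equal(nrow(st$vertices), 2L * length(st$cells))
  }
})
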