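test_that("build_grid places electrodes on the lattice", {
  g <- build_grid(10, 10, pitch = 0.4)
  expect_equal(length(g$ids), 100)
  expect_equal(max(dist(g$pos)), 9 * 0.4 * sqrt(2))
  expect_equal(g$center, c(x = 1.8, y = 1.8))

  g13 <- build_grid(1, 3, pitch = 0.4)
  expect_equal(unname(g13$pos[, "x"]), c(0, 0.4, 0.8))
  expect_equal(unname(g13$pos[, "y"]), c(0, 0, 0))

  g27 <- build_grid(10, 10, good_mask = mask_27())
  expect_equal(length(g27$ids), 27)

  expect_error(build_grid(2, 2, good_mask = matrix(FALSE, 2, 2)),
               "no usable electrodes")
  expect_error(build_grid(3, 3, good_mask = matrix(TRUE, 2, 2)))
})

test_that("unique_pairs matches brute-force enumeration and worked examples", {
  g27 <- build_grid(10, 10, good_mask = mask_27())
  p27 <- unique_pairs(g27, max_distance = 4)
  expect_equal(nrow(p27), 351)                      # 27*26/2, none discarded
  expect_true(all(p27$distance_mm > 0))
  expect_false(any(duplicated(p27[, c("id_a", "id_b")])))
  expect_true(all(p27$id_a < p27$id_b))             # unordered, one record

  g2 <- build_grid(1, 2)
  expect_equal(nrow(unique_pairs(g2, 4)), 1)
  expect_error(unique_pairs(g2, max_distance = 0), "positive")

  set.seed(41)
  for (dims in list(c(10, 10), c(6, 7), c(4, 4))) {
    m <- matrix(runif(prod(dims)) > 0.25, dims[1], dims[2])
    if (sum(m) < 2) next
    g <- build_grid(dims[1], dims[2], good_mask = m)
    for (maxd in c(1.0, 2.5, 4.0)) {
      expect_equal(nrow(unique_pairs(g, maxd)), brute_force_pairs(g, maxd))
    }
  }
  # full 10x10 at 4 mm against the double loop
  g <- build_grid(10, 10)
  expect_equal(nrow(unique_pairs(g, 4)), brute_force_pairs(g, 4))
})

test_that("distance bins are tolerant to lattice floating-point error", {
  d <- c(sqrt(0.4^2), 0.4 * sqrt(2), 1.2 + 1e-9, 2.4000001, 5)
  b <- assign_distance_bins(d)
  expect_equal(b, c("(0,0.4]", "(0.4,1.2]", "(0.4,1.2]", "(1.2,2.4]", NA))
})

test_that("csd_eligible finds interior electrodes with four good neighbours", {
  expect_equal(csd_eligible(build_grid(3, 3)), 5L)
  expect_equal(length(csd_eligible(build_grid(10, 10))), 64)

  # knocking out one interior electrode removes its four neighbours
  m <- matrix(TRUE, 10, 10)
  m[5, 5] <- FALSE
  g <- build_grid(10, 10, good_mask = m)
  elig <- csd_eligible(g)
  brute <- Filter(function(id) {
    r <- (id - 1) %/% 10 + 1; c <- (id - 1) %% 10 + 1
    if (r %in% c(1, 10) || c %in% c(1, 10) || !m[r, c]) return(FALSE)
    all(m[r - 1, c], m[r + 1, c], m[r, c - 1], m[r, c + 1])
  }, g$ids)
  expect_equal(elig, as.integer(brute))
  expect_false(any(c(35L, 44L, 46L, 55L) %in% elig)) # the four neighbours
  # eligible set is a subset of good electrodes, never on the boundary
  expect_true(all(elig %in% g$ids))
  rows <- (elig - 1) %/% 10 + 1; cols <- (elig - 1) %% 10 + 1
  expect_true(all(rows > 1 & rows < 10 & cols > 1 & cols < 10))
})

test_that("bipolar virtual electrodes sit at pair midpoints", {
  # L-configuration: real electrodes at (0,0), (0,0.4), (0.4,0) mm
  m <- matrix(FALSE, 2, 2)
  m[1, 1] <- TRUE; m[1, 2] <- TRUE; m[2, 1] <- TRUE
  g <- build_grid(2, 2, good_mask = m)
  v <- bipolar_virtual_grid(g, max_distance = 0.4)
  expect_equal(length(v$ids), 2)
  expect_equal(sort(v$pos[, "x"] + 1i * v$pos[, "y"]),
               sort(c(0.2 + 0i, 0 + 0.2i)))
  expect_equal(as.numeric(dist(v$pos)), 0.2 * sqrt(2))

  # single pair -> one virtual electrode at the midpoint
  g2 <- build_grid(1, 2)
  v2 <- bipolar_virtual_grid(g2)
  expect_equal(nrow(v2$pos), 1)
  expect_equal(unname(v2$pos[1, ]), c(0.2, 0))

  # 27 electrodes, 4 mm cutoff, unrestricted -> 351 virtual electrodes
  g27 <- build_grid(10, 10, good_mask = mask_27())
  v27 <- bipolar_virtual_grid(g27, max_distance = 4)
  expect_equal(length(v27$ids), 351)

  # center-out ordering: minuend nearer the grid centre
  g3 <- build_grid(3, 3)
  v3 <- bipolar_virtual_grid(g3, max_distance = 0.4)
  ctr <- g3$center
  for (i in seq_along(v3$ids)) {
    dm <- sum((g3$pos[match(v3$minuend[i], g3$ids), ] - ctr)^2)
    ds <- sum((g3$pos[match(v3$subtrahend[i], g3$ids), ] - ctr)^2)
    expect_lte(dm, ds + 1e-12)
  }
})

test_that("restricted bipolar matching uses each real electrode at most once", {
  g <- build_grid(4, 4)
  v <- bipolar_virtual_grid(g, max_distance = 4, restricted = TRUE)
  used <- c(v$minuend, v$subtrahend)
  expect_false(any(duplicated(used)))
  expect_equal(length(v$ids), 8)            # perfect matching on 16 electrodes
  # deterministic: rebuilding gives the identical matching
  v2 <- bipolar_virtual_grid(g, max_distance = 4, restricted = TRUE)
  expect_identical(v$minuend, v2$minuend)
  expect_identical(v$subtrahend, v2$subtrahend)
})

test_that("shared-component flags follow the referenced-signal algebra", {
  # three collinear electrodes: V1-V2 and V2-V3 share V2; square pairs do not
  g <- build_grid(1, 3)
  v <- bipolar_virtual_grid(g, max_distance = 0.4)
  pv <- flag_shared_components(unique_pairs(v, 4), v)
  expect_true(all(pv$shared_component))
  expect_equal(unique(pv$shared_kind), "bipolar-shared-electrode")

  gs <- build_grid(2, 2)
  vs <- bipolar_virtual_grid(gs, max_distance = 0.4)  # 4 side pairs
  pvs <- flag_shared_components(unique_pairs(vs, 4), vs)
  # opposite sides of the square share no electrode
  opp <- abs(pvs$distance_mm - 0.4) < 1e-6
  expect_false(any(pvs$shared_component[opp]))
  # adjacent sides share a corner
  expect_true(all(pvs$shared_component[!opp]))

  expect_error(flag_shared_components(unique_pairs(gs, 4), gs),
               "bipolar-virtual or csd")
})

test_that("CSD shared flags match the symbolic expansion on a 6x6 grid", {
  g <- build_grid(6, 6)
  cg <- csd_grid(g)
  pairs <- flag_shared_components(unique_pairs(cg, 10), cg)
  terms <- csd_term_sets(g)
  names(terms) <- as.character(csd_eligible(g))
  for (i in seq_len(nrow(pairs))) {
    ov <- length(intersect(terms[[as.character(pairs$id_a[i])]],
                           terms[[as.character(pairs$id_b[i])]])) > 0
    expect_equal(pairs$shared_component[i], ov,
                 info = paste("pair", pairs$id_a[i], pairs$id_b[i]))
  }
  # distance classes: 1 pitch adjacent, sqrt(2) diagonal, 2 pitches
  expect_equal(sort(unique(pairs$shared_kind[pairs$shared_component])),
               c("csd-adjacent", "csd-diagonal", "csd-two-pitch"))
  three <- abs(pairs$distance_mm - 3 * 0.4) < 1e-6
  expect_false(any(pairs$shared_component[three]))
})
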