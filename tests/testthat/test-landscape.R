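test_that("NK landscapes are reproducible, bounded and respect epistasis degree", {
  L1 <- nk_landscape(6, 2, seed = 11)
  L2 <- nk_landscape(6, 2, seed = 11)
  expect_identical(L1$fitness, L2$fitness)
  expect_true(all(L1$fitness >= 0 & L1$fitness <= 1))
  expect_false(identical(L1$fitness, nk_landscape(6, 2, seed = 12)$fitness))
  # k = 0: the fitness change from flipping one trait is background-free
  L0 <- nk_landscape(5, 0, seed = 3)
  for (i in 1:5) {
    mask <- 2^(5 - i)
    idx <- 0:31
    lower <- idx[bitwAnd(idx, mask) == 0]
    delta <- L0$fitness[bitwXor(lower, mask) + 1] - L0$fitness[lower + 1]
    expect_equal(max(delta) - min(delta), 0, tolerance = 1e-12)
  }
  expect_error(nk_landscape(4, 5, seed = 1), "k")
})

test_that("NK fitness is the mean of cyclic-window component values", {
  # hand evaluation on a fixed 3-trait, k = 1 table set
  tables <- matrix(c(
    0.10, 0.20, 0.30, 0.40,  # phi_1(s1, s2): 00 01 10 11
    0.05, 0.15, 0.25, 0.35,  # phi_2(s2, s3)
    0.50, 0.60, 0.70, 0.80   # phi_3(s3, s1), wraps around
  ), nrow = 3, byrow = TRUE)
  F <- culturedyn:::nk_fitness(tables, 3, 1)
  # state (1,0,1): phi_1(1,0)=0.30, phi_2(0,1)=0.15, phi_3(1,1)=0.80
  expect_equal(F[state_encode(c(1, 0, 1)) + 1], (0.30 + 0.15 + 0.80) / 3)
  # state (0,0,0): first column of every table
  expect_equal(F[1], (0.10 + 0.05 + 0.50) / 3)
  # state (1,1,1): last column of every table
  expect_equal(F[8], (0.40 + 0.35 + 0.80) / 3)
})

test_that("thresholding zeroes weak states and is idempotent", {
  L <- nk_landscape(6, 1, seed = 21)
  t0 <- apply_threshold(L, 0)
  expect_equal(t0$fitness, L$fitness)
  expect_equal(sum(t0$incompatible), 0)
  thi <- apply_threshold(L, max(L$fitness))
  expect_true(all(thi$incompatible))
  # m-th smallest fitness knocks out exactly m states (sort-and-count oracle)
  for (m in c(1, 24, 63)) {
    th <- threshold_for_count(L, m)
    expect_equal(th, sort(L$fitness)[m])
    expect_equal(sum(apply_threshold(L, th)$incompatible), m)
  }
  expect_equal(threshold_for_count(L, 0), 0)
  expect_true(all(apply_threshold(L, threshold_for_count(L, 64))$incompatible))
  expect_error(threshold_for_count(L, 65), "2\\^n")
  expect_error(apply_threshold(L, -0.1), "f_th")
  # idempotence: re-applying the piecewise rule changes nothing
  Lth <- apply_threshold(L, 0.4)
  expect_equal(apply_threshold(Lth, 0)$fitness, Lth$fitness)
})

test_that("interpolation is linear in tau and freezes the incompatible set", {
  pair <- landscape_pair(6, 1, seed = 31, incompatible_count = 24)
  expect_equal(sum(pair$incompatible), 24)
  f0 <- interpolate_fitness(pair, 0)
  f1 <- interpolate_fitness(pair, 1)
  expect_equal(f0, pair$F0$fitness)
  fm <- interpolate_fitness(pair, 0.5)
  expect_equal(fm[!pair$incompatible],
               ((f0 + f1) / 2)[!pair$incompatible])
  # exact linearity between arbitrary grid points
  fa <- interpolate_fitness(pair, 0.2)
  fb <- interpolate_fitness(pair, 0.7)
  fc <- interpolate_fitness(pair, 0.45)
  expect_equal(fc, fa + (0.45 - 0.2) * (fb - fa) / (0.7 - 0.2),
               tolerance = 1e-12)
  # incompatible states stay at zero for every tau
  for (tau in c(0, 0.3, 0.77, 1)) {
    expect_true(all(interpolate_fitness(pair, tau)[pair$incompatible] == 0))
  }
  expect_error(interpolate_fitness(pair, 1.2), "tau")
  # reproducible as a unit from the master seed
  pair2 <- landscape_pair(6, 1, seed = 31, incompatible_count = 24)
  expect_identical(pair$F1$fitness, pair2$F1$fitness)
})

test_that("landscape similarity is the kernel similarity of fitness vectors", {
  L1 <- nk_landscape(6, 1, seed = 41)
  L2 <- nk_landscape(6, 1, seed = 42)
  expect_equal(landscape_similarity(L1, L1), 1)
  s <- landscape_similarity(L1, L2)
  expect_lt(s, 1)
  expect_gt(s, 0)
  expect_error(landscape_similarity(L1$fitness, numeric(64)), "undefined")
})

test_that("strict local maxima census: additive landscapes have one peak", {
  for (seed in 1:100) {
    expect_length(local_maxima(nk_landscape(6, 0, seed = seed)), 1)
  }
  # the global argmax is always a local maximum in the tie-free case
  for (seed in 1:20) {
    L <- nk_landscape(6, 5, seed = seed)
    expect_true((which.max(L$fitness) - 1L) %in% local_maxima(L))
  }
  # strong epistasis makes multiple peaks the norm
  n_peaks <- vapply(1:100, function(seed) {
    length(local_maxima(nk_landscape(6, 5, seed = seed)))
  }, integer(1))
  expect_gt(mean(n_peaks > 1), 0.5)
  # constant fitness: all ties, no strict maximum
  expect_warning(lm0 <- local_maxima(rep(0.5, 16)), "Tied")
  expect_length(lm0, 0)
})

test_that("landscape tables round-trip through delimited files", {
  pair <- landscape_pair(5, 1, seed = 51, incompatible_count = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_landscape(pair, path)
  back <- read_landscape(path, rescale = FALSE)
  expect_equal(back$F0$fitness, pair$F0$fitness, tolerance = 1e-12)
  expect_equal(back$F1$fitness, pair$F1$fitness, tolerance = 1e-12)
  expect_equal(back$incompatible, pair$incompatible)
  expect_equal(back$viable, pair$viable)
  # user tables are rescaled by the joint maximum by default
  rescaled <- read_landscape(path)
  top <- max(pair$F0$fitness, pair$F1$fitness)
  expect_equal(max(rescaled$F0$fitness, rescaled$F1$fitness), 1)
  expect_equal(rescaled$F0$fitness, pair$F0$fitness / top)
})

test_that("hypercube graph export carries fitness and population attributes", {
  L <- nk_landscape(4, 1, seed = 61)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_hypercube_graph(L$fitness, path, x = rep(1 / 16, 16))
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 16)
  expect_equal(igraph::ecount(g), 4 * 16 / 2)
  expect_equal(sort(igraph::V(g)$fitness), sort(L$fitness))
})
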