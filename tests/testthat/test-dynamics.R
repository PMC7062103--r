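test_that("the adoption sigmoid honours its anchors and reflection identity", {
  for (beta in c(0.1, 1, 5, 20)) {
    expect_equal(adoption_prob(0.37, 0.37, beta), 0.5)
    expect_equal(adoption_prob(0, 0.5, beta), 0)
    expect_equal(adoption_prob(0.5, 0, beta), 1)
    expect_equal(adoption_prob(0, 0, beta), 0)
  }
  set.seed(1)
  for (rep in 1:50) {
    f1 <- runif(1); f2 <- runif(1); beta <- runif(1, 0.05, 10)
    expect_equal(adoption_prob(f1, f2, beta) + adoption_prob(f2, f1, beta), 1,
                 tolerance = 1e-12)
    expect_equal(adoption_prob(f1, f2, beta),
                 oracle_G(f1, f2, beta), tolerance = 1e-12)
  }
  # extreme ratios stay finite and ordered
  expect_equal(adoption_prob(1, 1e-300, 5), 1)
  expect_equal(adoption_prob(1e-300, 1, 5), 0, tolerance = 1e-15)
  expect_error(adoption_prob(0.5, 0.5, 0), "beta")
})

test_that("homophily weight is normalized to a unit maximum", {
  for (case in list(c(6, 1), c(6, 2), c(6, 5), c(10, 3))) {
    n <- case[1]; alpha <- case[2]
    opt <- stats::optimize(homophily_weight, c(0, n), n = n, alpha = alpha,
                           maximum = TRUE)
    expect_equal(opt$objective, 1, tolerance = 1e-9)
    expect_equal(opt$maximum, n / (1 + alpha), tolerance = 1e-4)
  }
  # no homophily: weight reduces to the trait-mismatch probability d/n
  expect_equal(homophily_weight(0:6, 6, 0), (0:6) / 6)
  # strong homophily on six traits: single-trait difference is most influential
  expect_equal(which.max(homophily_weight(0:6, 6, 5)) - 1L, 1L)
  expect_equal(homophily_weight(0, 8, 3), 0)
  expect_error(homophily_weight(7, 6, 1), "\\[0, n\\]")
})

test_that("fluxes match a hand-expanded two-trait system", {
  sys <- oracle_system(2)
  F <- sys$fitness
  p <- dynamics_params(lambda = 0.7, mu = 0.05, beta = 1.3, alpha = 0.8)
  set.seed(2)
  x <- runif(4); x <- x / sum(x)
  W <- function(d) oracle_W(d, 2, p$alpha)
  G <- function(a, b) oracle_G(a, b, p$beta)
  # inflow into state 00 (index 0), written out term by term:
  # trait 1 donors sit at 10; influencers hold first trait 0: states 00, 01
  # trait 2 donors sit at 01; influencers hold second trait 0: states 00, 10
  in0 <-
    (p$lambda * (W(1) * x[1] + W(2) * x[2]) + p$mu) * x[3] * G(F[1], F[3]) +
    (p$lambda * (W(1) * x[1] + W(2) * x[3]) + p$mu) * x[2] * G(F[1], F[2])
  expect_equal(contagion_inflow(0, x, F, p), in0, tolerance = 1e-14)
  # outflow from 00: influencers hold the flipped trait value
  out0 <-
    (p$lambda * (W(1) * x[3] + W(2) * x[4]) + p$mu) * x[1] * G(F[3], F[1]) +
    (p$lambda * (W(1) * x[2] + W(2) * x[4]) + p$mu) * x[1] * G(F[2], F[1])
  expect_equal(contagion_outflow(0, x, F, p), out0, tolerance = 1e-14)
  # no donors: all mass already on the state itself
  ind <- c(1, 0, 0, 0)
  expect_equal(contagion_inflow(0, ind, F, p), 0)
  # no mass, no outflow
  expect_equal(contagion_outflow(1, c(1, 0, 0, 0), F, p), 0)
  # uniform fitness turns every sigmoid factor into 1/2
  p0 <- dynamics_params(lambda = 1, mu = 0, beta = 2, alpha = 0)
  W0 <- function(d) oracle_W(d, 2, 0)
  Fu <- rep(0.5, 4)
  expect_equal(contagion_outflow(0, x, Fu, p0),
               0.5 * (W0(1) * x[3] + W0(2) * x[4]) * x[1] +
               0.5 * (W0(1) * x[2] + W0(2) * x[4]) * x[1])
})

test_that("the balance equation conserves mass and matches the flux sums", {
  set.seed(3)
  for (n in c(2, 3, 4)) {
    L <- nk_landscape(n, min(n, 2), seed = n)
    p <- dynamics_params(beta = 1.5, alpha = 1)
    x <- runif(2^n); x <- x / sum(x)
    r <- population_rhs(x, L$fitness, p)
    expect_lt(abs(sum(r)), 1e-12)
    io <- vapply(0:(2^n - 1), function(s) {
      contagion_inflow(s, x, L$fitness, p) -
        contagion_outflow(s, x, L$fitness, p)
    }, numeric(1))
    expect_equal(r, io, tolerance = 1e-12)
    # and both agree with the independent naive oracle
    expect_equal(r, oracle_rhs(x, L$fitness, p$lambda, p$mu, p$beta,
                               oracle_tables(n, p$alpha)),
                 tolerance = 1e-12)
  }
})

test_that("pure-contagion mass on an additive peak is absorbing", {
  L <- nk_landscape(4, 0, seed = 9)
  peak <- which.max(L$fitness)
  x <- numeric(16); x[peak] <- 1
  p <- dynamics_params(lambda = 1, mu = 0)
  expect_equal(population_rhs(x, L$fitness, p), numeric(16))
})

test_that("equilibria satisfy detailed balance when transmission is off", {
  # with lambda = 0 single-trait moves balance at x proportional to F^beta
  st <- integrator_settings(tol = 1e-6)
  for (seed in 1:3) {
    L <- nk_landscape(3, 1, seed = seed)
    for (beta in c(0.5, 2)) {
      eq <- integrate_to_equilibrium(
        "uniform", L$fitness, dynamics_params(lambda = 0, mu = 1, beta = beta),
        st
      )
      ref <- L$fitness^beta / sum(L$fitness^beta)
      expect_lt(max(abs(eq$x - ref)), 1e-6)
      expect_equal(population_rhs(ref, L$fitness,
                                  dynamics_params(lambda = 0, mu = 1,
                                                  beta = beta)),
                   numeric(8), tolerance = 1e-12)
    }
  }
})

test_that("a flat landscape leaves the uniform population stationary", {
  f <- rep(0.5, 16)
  out <- integrate_population(uniform_population(f), f, dynamics_params(),
                              time = 50)
  expect_equal(out$x, rep(1 / 16, 16), tolerance = 1e-10)
})

test_that("log-variable integration conserves mass and positivity", {
  pair <- landscape_pair(4, 1, seed = 13, incompatible_count = 3)
  f <- interpolate_fitness(pair, 0.4)
  raw <- culturedyn:::run_integrator("uniform", f, dynamics_params(),
                                     integrator_settings(), viable = pair$viable,
                                     fixed_time = 1e4, renormalize = FALSE)
  expect_lt(abs(sum(raw$x) - 1), 1e-6)
  expect_true(all(raw$x[pair$viable + 1] > 0))
  expect_true(all(raw$x[pair$incompatible] == 0))
})

test_that("equilibration reports convergence diagnostics and errors", {
  L <- nk_landscape(3, 1, seed = 5)
  eq <- integrate_to_equilibrium("uniform", L$fitness, dynamics_params())
  expect_s3_class(eq, "culture_equilibrium")
  expect_true(eq$converged)
  expect_lt(eq$residual, 1e-4)
  expect_equal(sum(eq$x), 1, tolerance = 1e-12)
  # residual at the reported equilibrium is small in the original variables
  expect_lt(max(abs(population_rhs(eq$x, L$fitness, dynamics_params()))), 1e-5)
  expect_error(
    integrate_to_equilibrium("uniform", L$fitness, dynamics_params(),
                             integrator_settings(max_time = 100, tol = 1e-12)),
    class = "culturedyn_nonconvergence"
  )
  err <- rlang::catch_cnd(
    integrate_to_equilibrium("uniform", L$fitness, dynamics_params(),
                             integrator_settings(max_time = 100, tol = 1e-12))
  )
  expect_true(is.numeric(err$residual))
  expect_length(err$x, 8)
})

test_that("initial populations are validated", {
  pair <- landscape_pair(3, 1, seed = 6, incompatible_count = 2)
  f <- interpolate_fitness(pair, 0)
  bad <- rep(1 / 8, 8) # mass on incompatible states
  expect_error(integrate_to_equilibrium(bad, f, dynamics_params()),
               "incompatible")
  zero <- uniform_population(f)
  zero[pair$viable[1] + 1] <- 0
  expect_error(integrate_to_equilibrium(zero, f, dynamics_params()),
               "strictly positive")
})

test_that("raising guided variation pulls equilibria toward the fitness profile", {
  pair <- landscape_pair(4, 1, seed = 7)
  f <- pair$F0$fitness
  mu_frac <- c(0.001, 0.01, 0.1, 0.5, 0.9)
  sims <- vapply(mu_frac, function(w) {
    eq <- integrate_to_equilibrium(
      "uniform", f, dynamics_params(lambda = 1 - w, mu = w, beta = 1)
    )
    kernel_similarity(eq$x, f) # beta = 1: target profile is F itself
  }, numeric(1))
  expect_true(all(diff(sims) > 0))
  expect_gt(sims[length(sims)], 0.999)
})

test_that("trajectories agree with an independent direct-in-x integrator", {
  # cross-check of the compiled log-variable RK4 against the naive oracle
  # at a tenth of the step, on the fixed two- and three-trait systems
  for (n in c(2, 3)) {
    sys <- oracle_system(n)
    p <- dynamics_params(beta = 1, alpha = 0)
    x0 <- rep(1 / 2^n, 2^n)
    ref <- oracle_integrate(x0, sys$fitness, p$lambda, p$mu, p$beta, p$alpha,
                            checkpoints = c(20, 100), dt = 0.01)
    for (tp in c(20, 100)) {
      got <- integrate_population(x0, sys$fitness, p, time = tp)
      want <- ref[[as.character(tp)]]
      expect_lt(max(abs(got$x - want / sum(want))), 1e-6)
    }
  }
})
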