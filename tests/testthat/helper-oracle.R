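# Independent, naively coded reference implementations used as oracles.
# These deliberately avoid the package's engine machinery: fluxes are written
# as literal sums over traits and backgrounds, and the reference integrator
# steps the balance equations directly in x (no log transform).

oracle_G <- function(f_new, f_old, beta) {
  if (f_new == 0 && f_old == 0) return(0)
  if (f_old == 0) return(1)
  if (f_new == 0) return(0)
  r <- (f_new / f_old)^beta
  r / (1 + r)
}

oracle_W <- function(d, n, alpha) {
  norm <- if (alpha == 0) 1 else (1 + alpha)^(1 + alpha) / alpha^alpha
  (d / n) * (1 - d / n)^alpha * norm
}

oracle_hamming <- function(a, b, n) {
  sum(as.integer(intToBits(bitwXor(a, b)))[seq_len(n)])
}

# precompute, for every (state, trait), the flip state, the influencer set
# (states sharing the relevant trait value) and their homophily weights
oracle_tables <- function(n, alpha) {
  N <- 2^n
  states <- 0:(N - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    mask <- bitwShiftL(1L, n - i) # trait i is the i-th most significant bit
    per_state <- lapply(states, function(s) {
      sf <- bitwXor(s, mask)
      # inflow into s over trait i: donors at sf, influencers share s's bit
      peers_in <- states[bitwAnd(states, mask) == bitwAnd(s, mask)]
      w_in <- vapply(peers_in, function(t) {
        oracle_W(oracle_hamming(sf, t, n), n, alpha)
      }, numeric(1))
      # outflow from s over trait i: influencers share sf's bit
      peers_out <- states[bitwAnd(states, mask) == bitwAnd(sf, mask)]
      w_out <- vapply(peers_out, function(t) {
        oracle_W(oracle_hamming(s, t, n), n, alpha)
      }, numeric(1))
      list(sf = sf, peers_in = peers_in + 1L, w_in = w_in,
           peers_out = peers_out + 1L, w_out = w_out)
    })
    out[[i]] <- per_state
  }
  out
}

oracle_rhs <- function(x, fitness, lambda, mu, beta, tabs) {
  n <- length(tabs)
  N <- length(x)
  dx <- numeric(N)
  for (s in 0:(N - 1L)) {
    infl <- 0
    outfl <- 0
    for (i in seq_len(n)) {
      tb <- tabs[[i]][[s + 1L]]
      g_in <- oracle_G(fitness[s + 1L], fitness[tb$sf + 1L], beta)
      g_out <- oracle_G(fitness[tb$sf + 1L], fitness[s + 1L], beta)
      infl <- infl +
        (lambda * sum(tb$w_in * x[tb$peers_in]) + mu) * x[tb$sf + 1L] * g_in
      outfl <- outfl +
        (lambda * sum(tb$w_out * x[tb$peers_out]) + mu) * x[s + 1L] * g_out
    }
    dx[s + 1L] <- infl - outfl
  }
  dx
}

# plain RK4 directly in x; returns the states at the requested checkpoints
oracle_integrate <- function(x0, fitness, lambda, mu, beta, alpha,
                             checkpoints, dt) {
  n <- round(log2(length(x0)))
  tabs <- oracle_tables(n, alpha)
  x <- x0
  t <- 0
  out <- list()
  for (tp in sort(checkpoints)) {
    nsteps <- round((tp - t) / dt)
    for (s in seq_len(nsteps)) {
      k1 <- oracle_rhs(x, fitness, lambda, mu, beta, tabs)
      k2 <- oracle_rhs(x + dt / 2 * k1, fitness, lambda, mu, beta, tabs)
      k3 <- oracle_rhs(x + dt / 2 * k2, fitness, lambda, mu, beta, tabs)
      k4 <- oracle_rhs(x + dt * k3, fitness, lambda, mu, beta, tabs)
      x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    t <- tp
    out[[as.character(tp)]] <- x
  }
  out
}

# brute-force Hamming-kernel inner product (double loop over state pairs)
oracle_inner <- function(x, y) {
  n <- round(log2(length(x)))
  total <- 0
  for (s in 0:(length(x) - 1L)) {
    for (t in 0:(length(y) - 1L)) {
      total <- total + x[s + 1L] * (n - oracle_hamming(s, t, n)) * y[t + 1L]
    }
  }
  total
}
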