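# Independent oracles used by the test suite. Everything here is deliberately
# written without reference to the package's engine internals: brute-force
# enumeration, direct matrix exponentiation, and naive Monte Carlo.

# --- Lambert W by plain Newton iteration (oracle for lambert_w0) -----------
newton_lambert <- function(x, tol = 1e-14) {
  vapply(x, function(xi) {
    w <- if (xi < 1) xi else log(xi + 1)
    for (i in 1:200) {
      f <- w * exp(w) - xi
      w1 <- w - f / (exp(w) * (1 + w))
      if (abs(w1 - w) < tol * max(1, abs(w1))) return(w1)
      w <- w1
    }
    w
  }, numeric(1))
}

# --- exact master equation for the constant-N engine on a tiny lattice -----
# State space: per-LEF head positions, nested or disjoint, all sites
# distinct. Returns a list with the state table and the generator matrix.
enumerate_states_1 <- function(L) {
  out <- list()
  for (l in 1:(L - 1)) for (r in (l + 1):L) out[[length(out) + 1]] <- c(l, r)
  do.call(rbind, out)
}

enumerate_states_2 <- function(L) {
  out <- list()
  for (l1 in 1:(L - 1)) for (r1 in (l1 + 1):L) {
    for (l2 in 1:(L - 1)) for (r2 in (l2 + 1):L) {
      s <- c(l1, r1, l2, r2)
      if (anyDuplicated(s)) next
      # exclude crossing configurations (unreachable by the dynamics)
      nested <- (l1 < l2 && r2 < r1) || (l2 < l1 && r1 < r2)
      disjoint <- r1 < l2 || r2 < l1
      if (!nested && !disjoint) next
      out[[length(out) + 1]] <- s
    }
  }
  do.call(rbind, out)
}

# generator for N = 1 or 2 LEFs, constant-N mode, uncoupled heads
master_generator <- function(states, L, v, tau) {
  n_lef <- ncol(states) / 2
  key <- apply(states, 1, paste, collapse = ",")
  idx <- setNames(seq_along(key), key)
  S <- nrow(states)
  Q <- matrix(0, S, S)
  add <- function(i, to, rate) {
    j <- idx[[paste(to, collapse = ",")]]
    Q[i, j] <<- Q[i, j] + rate
  }
  for (i in seq_len(S)) {
    st <- states[i, ]
    occ <- st
    for (k in seq_len(n_lef)) {
      l <- st[2 * k - 1]
      r <- st[2 * k]
      if (l - 1 >= 1 && !((l - 1) %in% occ)) {
        to <- st; to[2 * k - 1] <- l - 1
        add(i, to, v)
      }
      if (r + 1 <= L && !((r + 1) %in% occ)) {
        to <- st; to[2 * k] <- r + 1
        add(i, to, v)
      }
      # dissociation + uniform rebinding at a free adjacent pair
      others <- st[setdiff(seq_along(st), c(2 * k - 1, 2 * k))]
      pairs <- list()
      for (p in 1:(L - 1)) {
        if (!(p %in% others) && !((p + 1) %in% others)) {
          pairs[[length(pairs) + 1]] <- p
        }
      }
      for (p in pairs) {
        to <- st
        to[2 * k - 1] <- p
        to[2 * k] <- p + 1
        add(i, to, (1 / tau) / length(pairs))
      }
    }
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  list(states = states, key = key, Q = Q)
}

# distribution at time t from a point initial condition
master_distribution <- function(gen, init_key, t) {
  p0 <- as.numeric(gen$key == init_key)
  as.numeric(p0 %*% as.matrix(Matrix::expm(Matrix::Matrix(gen$Q * t))))
}

state_key <- function(state) {
  b <- state[state$bound, ]
  paste(as.vector(t(as.matrix(b[order(b$lef_id), c("left", "right")]))),
        collapse = ",")
}

# --- naive CTMC simulation of the immigration-death process ----------------
# immigration at rate lam, per-individual death at rate mu; counts visits to
# the empty state per unit time (the extinction flux), starting from the
# stationary Poisson occupancy.
simulate_extinction_flux <- function(lam, mu, t_total) {
  n <- rpois(1, lam / mu)
  t <- 0
  hits <- 0
  while (t < t_total) {
    rate <- lam + n * mu
    t <- t + rexp(1, rate)
    if (t >= t_total) break
    if (runif(1) < lam / rate) {
      n <- n + 1
    } else {
      n <- n - 1
      if (n == 0) hits <- hits + 1
    }
  }
  hits / t_total
}
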