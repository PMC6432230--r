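# Shared fixture builders: all test states are constructed in code.

# A state with one straight filament of size j plus an optional extra set of
# free monomers at given positions (rows of `extra`).
make_filament_state <- function(params, j = 2, L0 = 20, rho1 = 0,
                                extra = NULL, vseed = 1) {
  st <- build_initial_state(params, L0 = L0, rho1 = rho1, j0 = j)
  if (!is.null(extra)) {
    extra <- matrix(extra, ncol = 3)
    st$pos <- rbind(st$pos, extra)
    set.seed(vseed)
    v <- if (params$kBT > 0) {
      matrix(stats::rnorm(3 * nrow(extra), 0, sqrt(params$kBT / params$M)),
             ncol = 3)
    } else {
      matrix(0, nrow(extra), 3)
    }
    st$vel <- rbind(st$vel, v)
    st$n_idx <- c(st$n_idx, rep(0L, nrow(extra)))
    st$k_idx <- c(st$k_idx, rep(0L, nrow(extra)))
  }
  st
}

# exact Ornstein-Uhlenbeck sampler for ACF-fitting oracles
make_ou_series <- function(n, tau, sigma, dt, seed = 1) {
  set.seed(seed)
  a <- exp(-dt / tau)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sigma)
  innov <- stats::rnorm(n - 1, 0, sigma * sqrt(1 - a^2))
  for (i in 2:n) x[i] <- a * x[i - 1] + innov[i - 1]
  x
}

# block-averaged standard error (duplicated small utility for tests)
block_se_ref <- function(x, block) {
  nb <- floor(length(x) / block)
  bm <- vapply(seq_len(nb), function(b) {
    mean(x[((b - 1) * block + 1):(b * block)])
  }, numeric(1))
  stats::sd(bm) / sqrt(nb)
}
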