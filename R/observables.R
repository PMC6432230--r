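#' Crossover and relative filament size indices
#'
#' For a wall at `L` and a filament with seed offset `h_n`, the crossover
#' index `z_n = 1 + floor((L - h_n)/d)` is the size of the longest
#' filament that does not touch the wall; the relative index of a
#' filament of size `i_n` is `m = i_n - z_n`.  `m >= 0` flags a filament
#' pressing on the wall, `m <= -1` one that does not interact with it.
#'
#' @param L Wall position(s).
#' @param h_n Seed longitudinal offset(s).
#' @param d Monomer size.
#' @return `crossover_index`: integer `z_n`.
#' @examples
#' crossover_index(47.0, 0)            # 48
#' relative_index(48, 48)              # 0: strong wall contact
#' relative_index(26, crossover_index(26.5, 0.4375))  # -1
#' @export
crossover_index <- function(L, h_n, d = 1) {
  stopifnot(all(L > h_n))
  as.integer(1 + floor((L - h_n) / d))
}

#' @rdname crossover_index
#' @param i_n Filament size(s).
#' @param z_n Crossover index/indices.
#' @return `relative_index`: integer `m`.
#' @export
relative_index <- function(i_n, z_n) {
  as.integer(i_n - z_n)
}

#' Relative-size resolved reaction rates
#'
#' Converts raw counters into the residence-weighted rate estimators:
#' at each time step and for each filament the residence counter of the
#' current `m` grows by one; attempts and successes are tagged with the
#' pre-event `m`.  Dividing by residence time (`Q_m` steps times `h`)
#' gives the attempt rates `U_m^att`, `W_m^att` and the effective rates
#' `U_m`, `W_m`.  The plateau of `W_m` at sufficiently negative `m` is
#' the bulk depolymerization rate `W0`; `U_m/W_m` at the plateau equals
#' the imposed reduced density `rho_hat1`.
#'
#' @param counters Counter data.frame from [run_segment()] /
#'   [merge_counters()].
#' @param params An `ot_params` (supplies the time step `h`).
#' @return A data.frame per `m`: normalized residence fraction `Q`,
#'   attempt and effective rates for both directions (in `1/tauD`).
#' @export
rate_table <- function(counters, params) {
  stopifnot(nrow(counters) > 0)
  tot <- sum(counters$Q)
  time_m <- counters$Q * params$h
  data.frame(
    m = counters$m,
    Q = counters$Q / tot,
    U_att = counters$U_att / time_m,
    U = counters$U_succ / time_m,
    W_att = counters$W_att / time_m,
    W = counters$W_succ / time_m,
    n_U = counters$U_succ, n_W = counters$W_succ)
}

#' Plateau (bulk) rates from counters
#'
#' Pools successes and residence time over the non-interacting region
#' (`m <= m_max`) to estimate the bulk effective rates and their ratio.
#'
#' @param counters Counter data.frame.
#' @param params An `ot_params`.
#' @param m_max_W,m_max_U Largest `m` included in the depolymerization /
#'   polymerization plateau.  The wall is soft (cutoff `s_c ~ 1.2 d`), so
#'   `m = -1` already feels weak interference and a monomer arriving at a
#'   tip with `m = -2` lands in the skin: the clean plateaus are `m <= -2`
#'   for depolymerization and `m <= -3` for polymerization.
#' @return A list with `W0`, `U0`, their counts and Poisson standard
#'   errors, and the ratio `U0/W0` with its error.
#' @export
plateau_rates <- function(counters, params, m_max_W = -2, m_max_U = -3) {
  w <- counters$m <= m_max_W
  u <- counters$m <= m_max_U
  tw <- sum(counters$Q[w]) * params$h
  tu <- sum(counters$Q[u]) * params$h
  nw <- sum(counters$W_succ[w])
  nu_ <- sum(counters$U_succ[u])
  W0 <- nw / tw
  U0 <- nu_ / tu
  ratio <- U0 / W0
  list(W0 = W0, W0_se = sqrt(nw) / tw, n_W = nw,
       U0 = U0, U0_se = sqrt(nu_) / tu, n_U = nu_,
       ratio = ratio,
       ratio_se = ratio * sqrt(1 / max(nw, 1) + 1 / max(nu_, 1)))
}

#' Fitted slope of the relative size distribution
#'
#' Weighted linear fit of `log Q_m` against `m` over the non-interacting
#' branch; detailed balance predicts `Q_{m+1}/Q_m = rho_hat1`, so the
#' fitted `exp(slope)` estimates the imposed reduced density.
#'
#' @param counters Counter data.frame.
#' @param m_range Range of `m` used in the fit.
#' @return A list with `slope`, its standard error and `rho_hat1_fit =
#'   exp(slope)`.
#' @export
qm_slope <- function(counters, m_range = c(-6, -1)) {
  sel <- counters$m >= m_range[1] & counters$m <= m_range[2] & counters$Q > 0
  if (sum(sel) < 2) stop("not enough occupied m values in the fit range")
  m <- counters$m[sel]
  q <- counters$Q[sel]
  fit <- stats::lm(log(q) ~ m, weights = q)
  slope <- unname(coef(fit)[2])
  se <- summary(fit)$coefficients[2, 2]
  list(slope = slope, slope_se = se, rho_hat1_fit = exp(slope))
}

#' Wall position histogram with Gaussian reference
#'
#' Normalized histogram of the sampled wall positions together with the
#' rigid-filament theory curve `P(L) ~ exp(-beta(-F_H L + kappa_T
#' L^2/2))`, a Gaussian with mean `L_H` and width `sigma_H`.  The default
#' bin of 0.1 d resolves the monomer-scale oscillations expected for a
#' single filament.
#'
#' @param L Numeric vector of wall positions (equilibrated trace).
#' @param params An `ot_params`.
#' @param bin Bin width.
#' @return A data.frame with bin centers `L`, the empirical `density`
#'   and the `gaussian` reference.
#' @export
wall_histogram <- function(L, params, bin = 0.1) {
  if (length(L) == 0) stop("empty trace")
  br <- seq(floor(min(L) / bin) * bin, max(L) + bin, by = bin)
  h <- graphics::hist(L, breaks = br, plot = FALSE)
  hill <- hill_theory(params$Nf, params$kappa_T, params$rho_hat1,
                      params$d, params$kBT)
  g <- stats::dnorm(h$mids, mean = hill$LH, sd = hill$sigma_H)
  data.frame(L = h$mids, density = h$density, gaussian = g)
}

#' Autocorrelation function of fluctuations
#'
#' Unbiased estimator of `C_AA(t) = <dA(t) dA(0)>` with `dA = A - <A>`:
#' `C_k = sum_i dA_i dA_{i+k} / (N - k)`.
#'
#' @param x Stationary series (uniform stride).
#' @param dt Time between samples (`tauD`); lags are reported in `tauD`.
#' @param lag_max Largest lag (in samples); default `length(x)/4`.
#' @return A data.frame with `lag` (time) and `acf` (covariance units).
#' @export
acf_fluct <- function(x, dt = 1, lag_max = floor(length(x) / 4)) {
  n <- length(x)
  stopifnot(n > 4, lag_max < n)
  dx <- x - mean(x)
  cc <- vapply(0:lag_max, function(k) {
    sum(dx[1:(n - k)] * dx[(1 + k):n]) / (n - k)
  }, numeric(1))
  data.frame(lag = (0:lag_max) * dt, acf = cc)
}

#' Exponential fit of an autocorrelation function
#'
#' Fits `a exp(-t/tau)` (one component) or `a1 exp(-t/tau1) + a2
#' exp(-t/tau2)` (two components) to an ACF by least squares.  The fit
#' window is chosen automatically: an initial relaxation time comes from
#' a log-linear regression over the positive head of the ACF, the window
#' is then set to three times that estimate and the fit repeated once.
#'
#' @param acf_df Data.frame from [acf_fluct()].
#' @param n_components 1 or 2.
#' @param window Optional fixed fit window (time); overrides the
#'   automatic choice.
#' @return A list with `amplitudes`, `times`, the fit window, and the
#'   fitted curve evaluated on the ACF lags.  Fit failure (a
#'   non-decaying ACF) raises an error.
#' @export
fit_exponentials <- function(acf_df, n_components = 1, window = NULL) {
  stopifnot(n_components %in% c(1, 2))
  lag <- acf_df$lag
  val <- acf_df$acf
  if (val[1] <= 0) stop("ACF has non-positive variance at lag 0")

  tau_guess <- function(win) {
    sel <- lag <= win & val > 0
    if (sum(sel) < 3) stop("ACF does not decay: cannot fit exponentials")
    fit <- stats::lm(log(val[sel]) ~ lag[sel])
    tau <- -1 / coef(fit)[2]
    if (!is.finite(tau) || tau <= 0)
      stop("ACF does not decay: cannot fit exponentials")
    unname(tau)
  }

  # initial window: first crossing below 5% of the variance (or the end)
  below <- which(val < 0.05 * val[1])
  win0 <- if (length(below) > 0) lag[below[1]] else max(lag)
  tau0 <- tau_guess(win0)
  win <- if (is.null(window)) min(3 * tau0, max(lag)) else window

  sel <- lag <= win
  df <- data.frame(t = lag[sel], y = val[sel])
  if (n_components == 1) {
    fit <- minpack.lm::nlsLM(y ~ a * exp(-t / tau), data = df,
                             start = list(a = val[1], tau = tau0),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- coef(fit)
    amps <- unname(cf["a"]); taus <- unname(cf["tau"])
  } else {
    fit <- minpack.lm::nlsLM(
      y ~ a1 * exp(-t / tau1) + a2 * exp(-t / tau2), data = df,
      start = list(a1 = val[1] / 2, tau1 = tau0 / 10,
                   a2 = val[1] / 2, tau2 = tau0),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    cf <- coef(fit)
    ord <- order(c(cf["tau1"], cf["tau2"]))
    amps <- unname(c(cf["a1"], cf["a2"])[ord])
    taus <- unname(c(cf["tau1"], cf["tau2"])[ord])
  }
  if (any(taus <= 0)) stop("exponential fit returned non-positive time")
  list(amplitudes = amps, times = taus, window = win,
       fitted = stats::predict(fit, newdata = data.frame(t = lag)))
}

# block-averaged standard error of the mean; block length in samples
block_se <- function(x, block) {
  nb <- floor(length(x) / block)
  if (nb < 2) return(NA_real_)
  bm <- vapply(seq_len(nb), function(b) {
    mean(x[((b - 1) * block + 1):(b * block)])
  }, numeric(1))
  stats::sd(bm) / sqrt(nb)
}

#' Equilibrium summary of a production run
#'
#' Computes the standard table of static equilibrium averages: wall
#' position `<L>` and `sigma_L`, bundle mean size `<I> = sum_n j_n / Nf`,
#' single-filament size `<i>`, longitudinal (`<X>`) and transverse
#' (`<Rperp>`) end-to-end components, free monomer count `<N1>`, the
#' bundle force on the wall `<F_bun>`, `<F_bun^2>` and the consistency
#' estimate `kappa_T <L>`, with block-averaged standard errors.  If
#' counters are available, the relative-size distribution slope
#' ([qm_slope()]) and the plateau rates ([plateau_rates()]) are added.
#' A drift warning is attached when the first- and second-half means of
#' `L` differ by more than three combined standard errors.
#'
#' @param run An `ot_run`, or a trace data.frame.
#' @param counters Optional counter data.frame (taken from the run if
#'   given one).
#' @param params An `ot_params` (taken from the run if given one).
#' @param block Block length (in samples) for standard errors; default
#'   aims at a few blocks per relaxation time estimate.
#' @return A list of class `ot_summary`.
#' @export
equilibrium_summary <- function(run, counters = NULL, params = NULL,
                                block = NULL) {
  if (inherits(run, "ot_run")) {
    trace <- run$trace
    counters <- run$counters
    params <- run$params
  } else {
    trace <- run
    if (is.null(params)) stop("params required when passing a raw trace")
  }
  if (nrow(trace) < 2) {
    stop("trace too short for an equilibrium summary")
  }
  Nf <- params$Nf
  jn <- as.matrix(trace[paste0("j_", seq_len(Nf))])
  Xn <- as.matrix(trace[paste0("X_", seq_len(Nf))])
  Rn <- as.matrix(trace[paste0("Rperp_", seq_len(Nf))])
  I <- rowMeans(jn)

  if (is.null(block)) block <- max(2, floor(nrow(trace) / 25))
  mstat <- function(x) {
    c(mean = mean(x), sd = stats::sd(x), se = block_se(x, block))
  }
  out <- list(
    n_samples = nrow(trace),
    t_span = diff(range(trace$t)),
    L = mstat(trace$L),
    I = mstat(I),
    i = c(mean = mean(jn), sd = stats::sd(as.vector(jn)),
          se = block_se(I, block)),
    X = c(mean = mean(Xn), sd = stats::sd(as.vector(Xn)),
          se = block_se(rowMeans(Xn), block)),
    R_perp = c(mean = mean(Rn), sd = stats::sd(as.vector(Rn)),
               se = block_se(rowMeans(Rn), block)),
    N1 = mstat(trace$N1),
    F_bun = mstat(trace$F_bun),
    F_bun2 = c(mean = mean(trace$F_bun^2), sd = stats::sd(trace$F_bun^2),
               se = block_se(trace$F_bun^2, block)),
    F_wm = mstat(trace$F_wm),
    kT_L = params$kappa_T * mean(trace$L),
    pA = chamber2_pressure(params)$pA,
    block = block)

  # stationarity check: compare first and second half means of L
  half <- floor(nrow(trace) / 2)
  m1 <- mean(trace$L[1:half]); m2 <- mean(trace$L[(half + 1):nrow(trace)])
  se1 <- block_se(trace$L[1:half], block)
  se2 <- block_se(trace$L[(half + 1):nrow(trace)], block)
  cse <- sqrt(se1^2 + se2^2)
  out$drift <- is.finite(cse) && abs(m1 - m2) > 3 * cse

  if (!is.null(counters) && nrow(counters) > 0) {
    out$qm <- tryCatch(qm_slope(counters), error = function(e) NULL)
    out$rates <- tryCatch(plateau_rates(counters, params),
                          error = function(e) NULL)
  }
  class(out) <- "ot_summary"
  out
}

#' @export
print.ot_summary <- function(x, ...) {
  f <- function(v) sprintf("%.4g (sd %.3g, se %.2g)", v["mean"], v["sd"],
                           v["se"])
  cat(sprintf("Equilibrium summary over %d samples (%.4g tauD)%s\n",
              x$n_samples, x$t_span,
              if (isTRUE(x$drift)) "  [WARNING: drift detected]" else ""))
  cat("  <L>      =", f(x$L), "d\n")
  cat("  <I>      =", f(x$I), " <i> =", f(x$i), "\n")
  cat("  <X>      =", f(x$X), "d   <Rperp> =", f(x$R_perp), "d\n")
  cat("  <N1>     =", f(x$N1), "\n")
  cat(sprintf("  <F_bun>  = %.4g kBT/d   <F_bun^2> = %.4g   kappa_T<L> = %.4g\n",
              x$F_bun["mean"], x$F_bun2["mean"], x$kT_L))
  cat(sprintf("  <F_wm>   = %.4g kBT/d   pA = %.4g kBT/d\n",
              x$F_wm["mean"], x$pA))
  if (!is.null(x$qm)) {
    cat(sprintf("  Qm slope (m <= -1): rho_hat1_fit = %.3f +- %.3f\n",
                x$qm$rho_hat1_fit, x$qm$rho_hat1_fit * x$qm$slope_se))
  }
  if (!is.null(x$rates)) {
    cat(sprintf("  plateau rates: W0 = %.4f +- %.4f, U0 = %.4f +- %.4f, U0/W0 = %.3f\n",
                x$rates$W0, x$rates$W0_se, x$rates$U0, x$rates$U0_se,
                x$rates$ratio))
  }
  invisible(x)
}
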