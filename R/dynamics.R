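#' Advance the system by a time segment
#'
#' Integrates the coupled Langevin equations of all mobile monomers (3D)
#' and of the wall (1D) with the two-Gaussian stochastic velocity-Verlet
#' scheme, interleaved with Poisson-clocked Monte Carlo events: per
#' filament, polymerization and depolymerization attempts at rate `nu`
#' each, and reservoir insertion/deletion attempts at rate `nu_GC`.
#' Events execute at the first step boundary at or after their scheduled
#' Poisson time, in scheduled-time order.
#'
#' @param state An `ot_state` (modified copy returned).
#' @param params An `ot_params`.
#' @param duration Segment length in `tauD`.
#' @param mobile_wall Integrate the wall coordinate?  If `FALSE` the wall
#'   is held fixed at `state$L` (growth phase / parked wall) but still
#'   repels monomers.
#' @param reactions Enable (de)polymerization moves.
#' @param reservoir Enable grand-canonical exchange moves.
#' @param include_pA Apply the second-chamber mean pressure force `-p A`
#'   to the mobile wall; defaults to `mobile_wall`.
#' @param trace_stride Record the state trace every this many steps
#'   (0 = no trace).
#' @param counters Accumulate per-`m` residence/attempt/success counters.
#' @param max_size Stop the segment early when any filament reaches this
#'   size (0 = never); used by bulk-rate measurement protocols.
#' @param xhist_stride If positive, accumulate a histogram of free-monomer
#'   `x` positions every this many steps (bin width `xhist_bin`).
#' @param xhist_bin Bin width of the optional `x` histogram.
#' @param log_attempts Log every reaction attempt in the event table (not
#'   only accepted events); heavy at the default attempt rate, meant for
#'   short diagnostic segments.
#'
#' @return A list with the advanced `state`, the `trace` data.frame
#'   (`t`, `L`, `L_dot`, `N1`, energy terms, wall force components, and
#'   per-filament `j_n`, `X_n`, `Rperp_n` columns), the `counters`
#'   data.frame (per relative size `m`: residence steps `Q`, attempt and
#'   success counts both ways), the reservoir tallies `gc`, the accepted
#'   reaction `events`, the optional `xhist`, and `steps` actually done.
#' @examples
#' p <- simulation_params(Nf = 1, A = 9, nu = 100)
#' s <- build_initial_state(p, L0 = 10)
#' out <- run_segment(s, p, duration = 0.05, trace_stride = 100)
#' tail(out$trace)
#' @export
run_segment <- function(state, params, duration, mobile_wall = TRUE,
                        reactions = TRUE, reservoir = TRUE,
                        include_pA = mobile_wall, trace_stride = 0L,
                        counters = TRUE, max_size = 0L,
                        xhist_stride = 0L, xhist_bin = 0.05,
                        log_attempts = FALSE) {
  stopifnot(inherits(state, "ot_state"), inherits(params, "ot_params"),
            duration > 0)
  control <- list(mobile_wall = mobile_wall, reactions = reactions,
                  reservoir = reservoir, include_pA = include_pA,
                  counters = counters, trace_stride = as.integer(trace_stride),
                  max_size = as.integer(max_size),
                  xhist_bin = xhist_bin,
                  xhist_stride = as.integer(xhist_stride),
                  log_attempts = log_attempts)
  out <- cpp_run_segment(unclass(state), unclass(params), control, duration)
  st <- out$state
  class(st) <- "ot_state"

  trace <- as.data.frame(out$trace)
  if (nrow(trace) > 0) {
    Nf <- params$Nf
    for (n in seq_len(Nf)) {
      trace[[paste0("j_", n)]] <- out$per_fil$j[[n]]
      trace[[paste0("X_", n)]] <- out$per_fil$X[[n]]
      trace[[paste0("Rperp_", n)]] <- out$per_fil$R_perp[[n]]
    }
  }
  counters_df <- as.data.frame(out$counters)
  events <- as.data.frame(out$events)

  list(state = st, trace = trace, counters = counters_df,
       gc = out$gc, events = events, xhist = out$xhist,
       steps = out$steps, stopped_early = isTRUE(out$stopped_early))
}

#' Merge per-m counter tables
#'
#' @param ... Counter data.frames as returned by [run_segment()].
#' @return A single counter data.frame summed over the inputs.
#' @export
merge_counters <- function(...) {
  tabs <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (length(tabs) == 0) {
    return(data.frame(m = integer(), Q = numeric(), U_att = numeric(),
                      U_succ = numeric(), W_att = numeric(),
                      W_succ = numeric()))
  }
  all <- do.call(rbind, tabs)
  agg <- stats::aggregate(all[c("Q", "U_att", "U_succ", "W_att", "W_succ")],
                          by = list(m = all$m), FUN = sum)
  agg[order(agg$m), ]
}

#' Three-phase optical-trap simulation
#'
#' Runs the full protocol: (1) growth of the filaments from bare seeds
#' against a wall held fixed at `L0` (by default the rigid-filament
#' mean trap length `L_H` of [hill_theory()]), (2) equilibration with
#' the mobile wall released, (3) production with trace and counter
#' accumulation.
#'
#' @param params An `ot_params`.
#' @param t_grow,t_equil,t_prod Phase durations in `tauD`.
#' @param L0 Fixed wall position of the growth phase (default `L_H`).
#' @param j0 Initial filament size(s) passed to [build_initial_state()];
#'   sizes near the expected equilibrium shorten the growth phase.
#' @param trace_stride Production trace stride in steps.
#' @param state Optional starting state (resume); default is a fresh
#'   [build_initial_state()].
#' @return An object of class `ot_run`: list with `params`, the phase
#'   durations, the production `trace`, `counters`, `events`, `gc`
#'   tallies, and the final `state`.
#' @export
ot_simulate <- function(params, t_grow, t_equil, t_prod,
                        L0 = NULL, j0 = 2L, trace_stride = 400L,
                        state = NULL) {
  if (is.null(L0)) {
    L0 <- hill_theory(params$Nf, params$kappa_T, params$rho_hat1,
                      params$d, params$kBT)$LH
  }
  if (is.null(state)) state <- build_initial_state(params, L0 = L0, j0 = j0)
  grow <- NULL
  if (t_grow > 0) {
    grow <- run_segment(state, params, t_grow, mobile_wall = FALSE,
                        trace_stride = trace_stride, counters = FALSE)
    state <- grow$state
  }
  if (t_equil > 0) {
    eq <- run_segment(state, params, t_equil, mobile_wall = TRUE,
                      trace_stride = trace_stride, counters = FALSE)
    state <- eq$state
  } else {
    eq <- NULL
  }
  prod <- run_segment(state, params, t_prod, mobile_wall = TRUE,
                      trace_stride = trace_stride, counters = TRUE)
  out <- list(params = params,
              phases = list(t_grow = t_grow, t_equil = t_equil,
                            t_prod = t_prod, L0 = L0,
                            trace_stride = trace_stride),
              grow_trace = if (!is.null(grow)) grow$trace,
              equil_trace = if (!is.null(eq)) eq$trace,
              trace = prod$trace, counters = prod$counters,
              events = prod$events, gc = prod$gc, state = prod$state)
  class(out) <- "ot_run"
  out
}

#' @export
print.ot_run <- function(x, ...) {
  cat(sprintf("ot_run: Nf = %d, kappa_T = %g, rho_hat1 = %g\n",
              x$params$Nf, x$params$kappa_T, x$params$rho_hat1))
  cat(sprintf("  phases: grow %g + equil %g + production %g tauD\n",
              x$phases$t_grow, x$phases$t_equil, x$phases$t_prod))
  if (nrow(x$trace) > 0) {
    cat(sprintf("  production: %d samples, <L> = %.3f d, %d reaction events\n",
                nrow(x$trace), mean(x$trace$L), nrow(x$events)))
  }
  invisible(x)
}

#' @export
summary.ot_run <- function(object, ...) {
  equilibrium_summary(object, ...)
}

#' @export
plot.ot_run <- function(x, which = c("trace", "histogram"), ...) {
  which <- match.arg(which)
  if (which == "trace") {
    plot(x$trace$t, x$trace$L, type = "l", xlab = "t [tauD]",
         ylab = "L [d]", main = "Wall position", ...)
  } else {
    h <- wall_histogram(x$trace$L, x$params)
    plot(h$L, h$density, type = "s", xlab = "L [d]", ylab = "P(L)",
         main = "Wall position distribution", ...)
    lines(h$L, h$gaussian, col = 2)
  }
  invisible(x)
}
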