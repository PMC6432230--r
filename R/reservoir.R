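#' Mean pressure of the second chamber
#'
#' The simulation treats only the primary chamber explicitly; the free
#' monomer solution on the far side of the mobile wall acts through its
#' mean pressure, the ideal-gas pressure at the imposed chemical
#' potential: `p(mu1, T) = (kBT/d^3) exp(mu1*/kBT) = kBT rho1`.  The wall
#' equation of motion receives the constant force `-p A`.
#'
#' @param params An [simulation_params()] object.
#' @return A list with `p` (pressure, `kBT/d^3`) and `pA` (force on the
#'   wall, `kBT/d`).
#' @examples
#' chamber2_pressure(simulation_params())  # pA = 2.30 kBT/d at defaults
#' @export
chamber2_pressure <- function(params) {
  p <- params$kBT * params$rho1
  list(p = p, pA = p * params$A)
}

#' Reservoir acceptance summary
#'
#' Condenses the grand-canonical move tallies of one or more segments.
#'
#' @param ... `gc` lists as returned by [run_segment()].
#' @return A list with attempt/acceptance counts by move type, the
#'   overall acceptance fraction, and the count of moves auto-refused
#'   because the monomer was chemically reactive.
#' @export
gc_summary <- function(...) {
  gcs <- list(...)
  tot <- function(f) sum(vapply(gcs, function(g) g[[f]], numeric(1)))
  ins_att <- tot("ins_att"); ins_acc <- tot("ins_acc")
  del_att <- tot("del_att"); del_acc <- tot("del_acc")
  ref <- tot("refuse_reactive")
  att <- ins_att + del_att
  list(ins_att = ins_att, ins_acc = ins_acc,
       del_att = del_att, del_acc = del_acc,
       refuse_reactive = ref,
       acceptance = if (att > 0) (ins_acc + del_acc) / att else NA_real_)
}
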