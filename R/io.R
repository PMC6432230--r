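#' Read and write flat key-value configuration files
#'
#' The configuration format is flat `key = value` lines (one per key,
#' `#` comments allowed); keys match the [simulation_params()] argument
#' names exactly.  Unknown keys raise an error naming the key.
#'
#' @param path File path.
#' @return `read_config()`: an `ot_params` built from the file over the
#'   defaults.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  known <- names(formals(simulation_params))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  args <- lapply(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) v else num
  })
  names(args) <- keys
  do.call(simulation_params, args)
}

#' @rdname read_config
#' @param params An `ot_params` to serialize.
#' @export
write_config <- function(params, path) {
  keys <- c("d", "kBT", "M", "Mw", "zeta", "zeta_w", "ks", "kappa_bend",
            "eps0", "eps_w", "kappa_T", "A", "Nf", "rho_hat1", "nu",
            "nu_GC", "h", "r_c", "seed")
  lines <- vapply(keys, function(k) {
    sprintf("%s = %.17g", k, as.numeric(params[[k]]))
  }, character(1))
  writeLines(c("# actinotrap configuration (reduced units)", lines), path)
  invisible(path)
}

#' Read and write numeric log tables
#'
#' All numeric logs (state traces, counter tables, rate tables, event
#' logs, ACFs) are tab-separated files with a commented header line;
#' the round trip is lossless at full double precision.
#'
#' @param df A data.frame.
#' @param path File path.
#' @export
write_trace <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(names(df), collapse = "\t")), con)
  utils::write.table(format(df, digits = 17, scientific = NA, trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  header <- readLines(path, n = 1)
  cols <- strsplit(sub("^#\\s*", "", header), "\t")[[1]]
  if (length(cols) == 0) stop("empty or headerless log file: ", path)
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = cols)
  df
}

#' Write a coordinate snapshot in XYZ format
#'
#' One frame per call; the element tag encodes the monomer role:
#' `S` seed, `F` filament, `M` free monomer, `W` a marker bead at the
#' mobile wall position on the box axis.
#'
#' @param state An `ot_state`.
#' @param path Output file; appended to when `append = TRUE`.
#' @param append Append as an additional frame.
#' @export
write_xyz <- function(state, path, append = FALSE) {
  role <- ifelse(state$n_idx == 0L, "M",
                 ifelse(state$k_idx <= 2L, "S", "F"))
  n <- nrow(state$pos) + 1L
  lines <- c(
    as.character(n),
    sprintf("t= %.6f L= %.6f", state$t, state$L),
    sprintf("%s %.8f %.8f %.8f", role, state$pos[, 1], state$pos[, 2],
            state$pos[, 3]),
    sprintf("W %.8f %.8f %.8f", state$L, 0, 0))
  if (append) cat(lines, file = path, sep = "\n", append = TRUE)
  else writeLines(lines, path)
  invisible(path)
}

#' Checkpoint a run state to a text file
#'
#' Serializes the full `ot_state` (coordinates, velocities, topology,
#' wall, clock, pending Poisson event times and the RNG stream states)
#' as JSON with full double precision; [read_checkpoint()] restores an
#' identical state, so a resumed run continues the uninterrupted
#' trajectory exactly.
#'
#' @param state An `ot_state`.
#' @param path File path (`.json`).
#' @export
write_checkpoint <- function(state, path) {
  # doubles are stored as %.17g strings: exact round trip for IEEE doubles,
  # which jsonlite's numeric output (15 significant digits) cannot guarantee
  num <- function(x) sprintf("%.17g", as.numeric(x))
  obj <- list(
    checkpoint_version = 1L,
    pos = num(state$pos), vel = num(state$vel),
    n_idx = state$n_idx, k_idx = state$k_idx,
    hn = num(state$hn), seed_y = num(state$seed_y),
    seed_z = num(state$seed_z),
    L = num(state$L), L_dot = num(state$L_dot), t = num(state$t),
    rng = paste(sprintf("%02x", as.integer(state$rng)), collapse = ""),
    next_reaction = num(state$next_reaction), next_gc = num(state$next_gc))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$checkpoint_version)) {
    stop("not an actinotrap checkpoint: ", path)
  }
  nm <- length(obj$n_idx)
  st <- list(
    pos = matrix(as.numeric(obj$pos), nm, 3),
    vel = matrix(as.numeric(obj$vel), nm, 3),
    n_idx = as.integer(obj$n_idx), k_idx = as.integer(obj$k_idx),
    hn = as.numeric(obj$hn), seed_y = as.numeric(obj$seed_y),
    seed_z = as.numeric(obj$seed_z),
    L = as.numeric(obj$L), L_dot = as.numeric(obj$L_dot),
    t = as.numeric(obj$t),
    rng = as.raw(strtoi(substring(obj$rng, seq(1, 255, 2),
                                  seq(2, 256, 2)), 16L)),
    next_reaction = suppressWarnings(as.numeric(obj$next_reaction)),
    next_gc = suppressWarnings(as.numeric(obj$next_gc)))
  class(st) <- "ot_state"
  st
}

#' Run manifest
#'
#' Records the resolved parameters, master seed, package version, start
#' and stop times and the inventory of output files of a run, so that a
#' run directory is self-describing and reproducible.
#'
#' @param params An `ot_params`.
#' @param files Named character vector: file path by role.
#' @param path Output JSON path.
#' @param extra Optional named list of extra fields (phase durations...).
#' @export
write_manifest <- function(params, files, path, extra = list()) {
  obj <- c(list(
    package = "actinotrap",
    version = as.character(utils::packageVersion("actinotrap")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = params$seed,
    params = unclass(params)[!vapply(unclass(params), is.null, logical(1))],
    files = as.list(files)), extra)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
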