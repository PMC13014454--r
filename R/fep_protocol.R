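# ---------------------------------------------------------------------------
# Alchemical protocol: sigmoidal lambda schedule, replicate seeds, and
# per-window input manifests.
# ---------------------------------------------------------------------------

#' Sigmoidally distributed lambda schedule
#'
#' Generates `n` windows lambda_k = 0.5 * (1 + tanh(s * x_k) / tanh(s)) for
#' x_k uniform on \[-1, 1\], so windows are densest near the end states 0
#' and 1 and sparsest near the midpoint 0.5, where phase-space overlap
#' between adjacent windows is easiest. The schedule always contains 0,
#' 0.5 and 1 exactly and is symmetric about 0.5; the two legs proceed
#' independently from the shared midpoint toward each end state.
#'
#' @param n odd number of windows, >= 3 (default 101).
#' @param steepness sigmoid steepness s > 0 (default 2.0).
#' @return object of class `lambda_schedule`: sorted `values`, plus
#'   `leg_down` (0.5 -> 0) and `leg_up` (0.5 -> 1), both starting at 0.5.
#' @export
make_lambda_schedule <- function(n = 101, steepness = 2.0) {
  if (n < 3L) stop("need at least 3 lambda windows")
  if (n %% 2L == 0L) stop("number of lambda windows must be odd")
  stopifnot(steepness > 0)
  x <- seq(-1, 1, length.out = n)
  lam <- 0.5 * (1 + tanh(steepness * x) / tanh(steepness))
  # enforce exact symmetry and endpoints against fp rounding
  lam <- (lam + rev(1 - lam)) / 2
  lam[1] <- 0; lam[n] <- 1; lam[(n + 1L) / 2L] <- 0.5
  mid <- (n + 1L) / 2L
  structure(list(values = lam, steepness = steepness,
                 leg_down = lam[mid:1], leg_up = lam[mid:n]),
            class = "lambda_schedule")
}

#' @export
print.lambda_schedule <- function(x, ...) {
  cat(sprintf("<lambda_schedule> %d windows (steepness %g), legs of %d sharing lambda = 0.5\n",
              length(x$values), x$steepness, length(x$leg_up)))
  invisible(x)
}

#' Protocol configuration
#'
#' Defaults follow the production protocol: 101 windows, 5000 steps of 2 fs
#' per window (10 ps sampling), 10 replicates per leg, first 100 steps of
#' each window discarded as equilibration, 298.15 K.
#'
#' @param n_windows odd integer.
#' @param steps_per_window integer MD steps per window.
#' @param timestep_fs integration timestep in femtoseconds.
#' @param replicates replicates per leg (protein, water).
#' @param discard equilibration steps discarded per window at analysis.
#' @param temperature temperature in Kelvin.
#' @return object of class `protocol_config`; `window_ps` is derived as
#'   steps x timestep.
#' @export
protocol_config <- function(n_windows = 101, steps_per_window = 5000,
                            timestep_fs = 2, replicates = 10,
                            discard = 100, temperature = 298.15) {
  if (n_windows %% 2L == 0L) stop("n_windows must be odd")
  stopifnot(replicates >= 1, steps_per_window > 0, timestep_fs > 0,
            temperature > 0, discard >= 0)
  structure(list(n_windows = as.integer(n_windows),
                 steps_per_window = as.integer(steps_per_window),
                 timestep_fs = timestep_fs,
                 window_ps = steps_per_window * timestep_fs / 1000,
                 replicates = as.integer(replicates),
                 discard = as.integer(discard),
                 temperature = temperature),
            class = "protocol_config")
}

#' @export
print.protocol_config <- function(x, ...) {
  cat(sprintf("<protocol_config> %d windows x %g ps (%d steps @ %g fs), %d replicates/leg, discard %d, %g K\n",
              x$n_windows, x$window_ps, x$steps_per_window, x$timestep_fs,
              x$replicates, x$discard, x$temperature))
  invisible(x)
}

#' Total production sampling per replicate leg
#' @param config a [protocol_config()].
#' @return picoseconds (defaults give 1010 ps).
#' @export
total_production_time <- function(config) {
  config$n_windows * config$window_ps
}

#' Reproducible distinct replicate seeds
#'
#' Derives `n` distinct positive integer seeds from one master seed without
#' disturbing the caller's RNG state.
#'
#' @param n number of seeds.
#' @param master_seed integer master seed.
#' @return integer vector of `n` distinct seeds.
#' @export
generate_seeds <- function(n, master_seed) {
  stopifnot(n >= 1)
  with_preserved_rng({
    set.seed(as.integer(master_seed))
    sample.int(.Machine$integer.max - 1L, n)
  })
}

# evaluate expr with the global RNG state restored afterwards
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Emit per-window input manifests for an edge
#'
#' Writes one plain-text manifest per (leg, replicate, window):
#' `outdir/<leg>/replicate_XX/window_YYY.txt`, each containing the lambda
#' pair (lambda_A, 1 - lambda_A), the replicate seed, step counts, the
#' restraint table and the boundary-constrained atom table. The manifest
#' format is this package's own versioned plain-text dialect, not any MD
#' engine's input syntax. Re-emission with identical inputs is
#' byte-identical.
#'
#' @param system a solvated [sphere_system()] with the dual topology
#'   attached ([attach_dual_topology()]).
#' @param schedule a [lambda_schedule()].
#' @param config a [protocol_config()].
#' @param outdir output directory.
#' @param master_seed integer master seed for replicate seeds.
#' @return (invisibly) character vector of the 2 x replicates replicate
#'   directories created.
#' @export
emit_inputs <- function(system, schedule, config, outdir, master_seed = 42) {
  stopifnot(inherits(system, "sphere_system"),
            inherits(schedule, "lambda_schedule"),
            inherits(config, "protocol_config"))
  dual <- system$dual
  if (is.null(dual)) stop("attach a dual topology before emitting inputs")
  ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  legs <- c("protein", "water")
  seeds <- generate_seeds(length(legs) * config$replicates, master_seed)
  rest <- dual$restraints_merged
  rest_lines <- if (nrow(rest))
    sprintf("restraint %d %d %.6g %.6g", rest$i - 1L, rest$j - 1L,
            rest$k, rest$activation) else character(0)
  bc <- which(system$solute_class$class == "boundary")
  bc_lines <- sprintf("boundary_atom %d %g", bc - 1L, system$k_boundary)
  dirs <- character(0)
  s <- 0L
  for (leg in legs) {
    for (rep in seq_len(config$replicates)) {
      s <- s + 1L
      rdir <- file.path(outdir, leg, sprintf("replicate_%02d", rep))
      dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
      dirs <- c(dirs, rdir)
      for (w in seq_len(config$n_windows)) {
        lamA <- schedule$values[w]
        lines <- c(
          "# rbfekit window manifest v1",
          sprintf("leg %s", leg),
          sprintf("replicate %d", rep),
          sprintf("window %d", w),
          sprintf("lambda_A %.12f", lamA),
          sprintf("lambda_B %.12f", 1 - lamA),
          sprintf("seed %d", seeds[s]),
          sprintf("steps %d", config$steps_per_window),
          sprintf("timestep_fs %g", config$timestep_fs),
          sprintf("temperature_K %g", config$temperature),
          sprintf("equilibration_steps %d", 0L),
          rest_lines, bc_lines)
        writeLines(lines, file.path(rdir, sprintf("window_%03d.txt", w)))
      }
    }
  }
  invisible(dirs)
}
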