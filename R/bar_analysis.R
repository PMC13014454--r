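# ---------------------------------------------------------------------------
# Bennett acceptance ratio analysis: per-window estimates, leg summation,
# replicate aggregation, thermodynamic-cycle combination.
# ---------------------------------------------------------------------------

KB_KCAL <- 0.0019872041  # Boltzmann constant, kcal/mol/K

#' Work samples for one adjacent lambda-window pair
#'
#' @param forward potential-energy differences (kcal/mol) sampled in window
#'   i and evaluated toward window i+1 (U_{i+1} - U_i).
#' @param reverse the converse series sampled in window i+1 (U_i - U_{i+1}).
#' @param temperature Kelvin.
#' @param window label for error messages (e.g. "3-4").
#' @return object of class `work_samples`.
#' @export
work_samples <- function(forward, reverse, temperature = 298.15,
                         window = NA_character_) {
  forward <- as.numeric(forward); reverse <- as.numeric(reverse)
  if (!length(forward) || !length(reverse))
    stop("forward and reverse series must be non-empty")
  if (!all(is.finite(forward)) || !all(is.finite(reverse)))
    stop("non-finite work values")
  stopifnot(temperature > 0)
  structure(list(forward = forward, reverse = reverse,
                 temperature = temperature, window = window),
            class = "work_samples")
}

#' Discard the equilibration head of a work series
#'
#' Removes the first `n_discard` entries of both directions (default 100,
#' matching the protocol's per-window equilibration discard).
#'
#' @param samples a [work_samples()].
#' @param n_discard number of leading samples to drop from each series.
#' @return trimmed [work_samples()].
#' @export
discard_equilibration <- function(samples, n_discard = 100) {
  stopifnot(inherits(samples, "work_samples"), n_discard >= 0)
  if (length(samples$forward) <= n_discard || length(samples$reverse) <= n_discard)
    stop(sprintf("window %s: %d samples cannot survive a %d-sample discard",
                 samples$window, min(length(samples$forward), length(samples$reverse)),
                 n_discard))
  if (n_discard == 0) return(samples)
  samples$forward <- samples$forward[-seq_len(n_discard)]
  samples$reverse <- samples$reverse[-seq_len(n_discard)]
  samples
}

#' BAR estimate for one window pair
#'
#' Solves Bennett's self-consistency condition: with reduced works
#' w_F = beta * dU_F, w_R = beta * dU_R and M = log(n_F / n_R), the reduced
#' free energy df satisfies
#' sum_F fermi(M + w_F - df) = sum_R fermi(-M + w_R + df),
#' where fermi(x) = 1 / (1 + exp(x)). The left side is increasing and the
#' right decreasing in df, so the root is unique; it is bracketed by the
#' two one-sided exponential-averaging (EXP) estimates and found to 1e-8
#' kcal/mol. The reported uncertainty is the standard BAR asymptotic
#' variance (a per-window diagnostic; replicate SEM is the headline
#' uncertainty downstream).
#'
#' @param samples a [work_samples()].
#' @param tol convergence tolerance in kcal/mol.
#' @return list with `dG` (kcal/mol), `se` (asymptotic), `overlap_warning`
#'   (TRUE when the Fermi weights effectively vanish, i.e. no phase-space
#'   overlap and the estimate is unreliable).
#' @export
bar_pair <- function(samples, tol = 1e-8) {
  stopifnot(inherits(samples, "work_samples"))
  kT <- KB_KCAL * samples$temperature
  wf <- samples$forward / kT
  wr <- samples$reverse / kT
  nf <- length(wf); nr <- length(wr)
  M <- log(nf / nr)
  fermi <- function(x) 1 / (1 + exp(x))
  g <- function(df) sum(fermi(M + wf - df)) - sum(fermi(-M + wr + df))
  # bracket from the two one-sided EXP estimates
  exp_f <- -logmeanexp(-wf)           # forward EXP, reduced units
  exp_r <- logmeanexp(-wr)            # reverse EXP
  lo <- min(exp_f, exp_r) - 1; hi <- max(exp_f, exp_r) + 1
  # g is increasing in df: expand whichever end excludes the root
  for (k in 1:200) {
    if (g(lo) <= 0 && g(hi) >= 0) break
    span <- hi - lo
    if (g(lo) > 0) lo <- lo - span
    if (g(hi) < 0) hi <- hi + span
  }
  if (g(lo) > 0 || g(hi) < 0)
    stop(sprintf("BAR failed to bracket a root (window %s); last bracket [%g, %g]",
                 samples$window, lo * kT, hi * kT))
  df <- uniroot(g, c(lo, hi), tol = tol / kT, maxiter = 2000)$root
  # asymptotic variance (Bennett): per-direction relative variances of the
  # Fermi weights
  ff <- fermi(M + wf - df)
  fr <- fermi(-M + wr + df)
  overlap_warning <- mean(ff) < 1e-12 || mean(fr) < 1e-12
  if (overlap_warning)
    warning(sprintf("window %s: negligible overlap; BAR estimate unreliable",
                    samples$window))
  var_red <- (mean(ff^2) / mean(ff)^2 - 1) / nf +
             (mean(fr^2) / mean(fr)^2 - 1) / nr
  list(dG = df * kT, se = sqrt(max(var_red, 0)) * kT,
       overlap_warning = overlap_warning)
}

# log(mean(exp(x))) without overflow
logmeanexp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Sum per-window BAR estimates over a leg
#'
#' @param dG numeric vector of adjacent-pair estimates, one per window pair,
#'   covering the leg contiguously (names or `pair_ids` identify gaps).
#' @param se optional per-pair uncertainties; combined in quadrature.
#' @param pair_ids optional integer vector of window-pair indices; if given,
#'   must be a permutation of a contiguous range (a missing pair is an
#'   error naming the gap).
#' @return list `dG`, `se`.
#' @export
sum_leg <- function(dG, se = NULL, pair_ids = NULL) {
  if (!is.null(pair_ids)) {
    r <- range(pair_ids)
    missing <- setdiff(seq(r[1], r[2]), pair_ids)
    if (length(missing))
      stop("missing window pair(s): ", paste(missing, collapse = ", "))
  }
  list(dG = sum(dG),
       se = if (is.null(se)) NA_real_ else sqrt(sum(se^2)))
}

#' Aggregate replicate leg estimates
#'
#' Averages per-replicate leg free energies; the uncertainty is the
#' standard error of the mean across replicates (sd / sqrt(n)). A single
#' replicate gives a mean but no SEM (reported missing, with a warning).
#'
#' @param dG_replicates numeric vector, one leg estimate per replicate.
#' @return object of class `leg_result`: `dG` (per-replicate), `mean`,
#'   `sem`, `n`.
#' @export
aggregate_replicates <- function(dG_replicates) {
  dG_replicates <- as.numeric(dG_replicates)
  if (!length(dG_replicates)) stop("no replicate estimates")
  n <- length(dG_replicates)
  sem <- if (n >= 2L) sd(dG_replicates) / sqrt(n) else {
    warning("single replicate: SEM unavailable")
    NA_real_
  }
  structure(list(dG = dG_replicates, mean = mean(dG_replicates),
                 sem = sem, n = n),
            class = "leg_result")
}

#' @export
print.leg_result <- function(x, ...) {
  cat(sprintf("<leg_result> dG = %.3f +/- %s kcal/mol (n = %d)\n",
              x$mean, ifelse(is.na(x$sem), "NA", sprintf("%.3f", x$sem)), x$n))
  invisible(x)
}

#' Combine protein and water legs through the thermodynamic cycle
#'
#' ddG_bind = dG_protein - dG_water; the SEMs combine in quadrature.
#'
#' @param protein,water [aggregate_replicates()] results.
#' @return object of class `edge_result`: `ddG`, `sem`, plus both legs.
#' @export
combine_cycle <- function(protein, water) {
  stopifnot(inherits(protein, "leg_result"), inherits(water, "leg_result"))
  structure(list(ddG = protein$mean - water$mean,
                 sem = sqrt(protein$sem^2 + water$sem^2),
                 protein = protein, water = water),
            class = "edge_result")
}

#' @export
print.edge_result <- function(x, ...) {
  cat(sprintf("<edge_result> ddG_bind = %.3f +/- %.3f kcal/mol (protein %.3f +/- %.3f, water %.3f +/- %.3f)\n",
              x$ddG, x$sem, x$protein$mean, x$protein$sem,
              x$water$mean, x$water$sem))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Energy-file I/O and edge-level driver
# ---------------------------------------------------------------------------

#' Read a two-column work series file
#'
#' Whitespace-delimited `step  dU` (kcal/mol), `#` comments allowed: the
#' documented plain-text energy format of this package.
#'
#' @param path file path.
#' @return numeric vector of dU values in file order.
#' @export
read_work_series <- function(path) {
  tab <- read.table(path, header = FALSE, comment.char = "#")
  if (ncol(tab) < 2L) stop("expected two columns (step, dU) in ", path)
  as.numeric(tab[[2]])
}

#' Analyze one edge directory
#'
#' Expects `edge_dir/<leg>/replicate_XX/pair_YYY.{fwd,rev}` work files (as
#' written by [gen_bar_samples()]); runs discard + BAR per window pair,
#' sums each leg per replicate, aggregates replicates, and combines the
#' cycle.
#'
#' @param edge_dir directory with `protein/` and `water/` leg subdirs.
#' @param temperature Kelvin.
#' @param discard equilibration samples dropped per series (default 100).
#' @return an `edge_result`.
#' @export
analyze_edge <- function(edge_dir, temperature = 298.15, discard = 100) {
  leg <- function(name) {
    ldir <- file.path(edge_dir, name)
    reps <- sort(list.dirs(ldir, recursive = FALSE))
    if (!length(reps)) stop("no replicate directories under ", ldir)
    est <- vapply(reps, function(rdir) {
      fwd <- sort(Sys.glob(file.path(rdir, "pair_*.fwd")))
      if (!length(fwd)) stop("no work files under ", rdir)
      dGs <- vapply(fwd, function(f) {
        r <- sub("\\.fwd$", ".rev", f)
        ws <- work_samples(read_work_series(f), read_work_series(r),
                           temperature, window = basename(f))
        bar_pair(discard_equilibration(ws, discard))$dG
      }, numeric(1))
      sum_leg(dGs)$dG
    }, numeric(1))
    aggregate_replicates(est)
  }
  combine_cycle(leg("protein"), leg("water"))
}
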