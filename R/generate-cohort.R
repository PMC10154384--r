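#' Generate a cohort of synthetic single-cell datasets from a preset
#'
#' Draws per-cell truths from a positive-support distribution matched to the
#' published cohort summary (lognormal with mean = preset mean and
#' SD = SEM * sqrt(n); below-bilayer fractions use a moment-matched beta since
#' they live in `[0, 1]`), then runs the per-assay generator once per cell.
#' The cohort mean of the drawn truths converges to the preset mean.
#'
#' @param preset a [condition_preset()] or preset name.
#' @param assay one of `"pillar"`, `"afm"`, `"tweezers"`, `"invasion"`.
#' @param seed master seed; per-cell sub-seeds are derived from it.
#' @param n override the preset sample size (default: the published n).
#' @param day for the invasion assay: 3 or 5 (which published percentage
#'   parameterizes the cohort).
#' @param ... further arguments passed to the per-cell generator
#'   ([generate_pillar_video()], [generate_indentation_curve()],
#'   [generate_bead_trajectory()] or [generate_invasion_stack()]).
#' @return list with `cells` (list of per-cell generator outputs) and `truth`
#'   (a [ground_truth()] with the per-cell drawn truths and the preset).
#' @export
generate_cohort <- function(preset, assay = c("pillar", "afm", "tweezers",
                                              "invasion"),
                            seed = 1, n = NULL, day = 3, ...) {
  if (is.character(preset)) preset <- condition_preset(preset)
  stopifnot(inherits(preset, "condition_preset"))
  assay <- match.arg(assay)
  need <- switch(assay,
                 pillar   = c("traction_mean", "traction_sem", "n_traction"),
                 afm      = c("stiffness_mean", "stiffness_sem", "n_stiffness"),
                 tweezers = c("relamp12_mean", "relamp12_sem", "n_tweezers"),
                 invasion = if (day == 3)
                   c("invasion_day3_pct", "invasion_day3_sem", "n_invasion_day3")
                 else
                   c("invasion_day5_pct", "invasion_day5_sem", "n_invasion_day5"))
  vals <- unlist(preset[need])
  if (anyNA(vals))
    stop("preset '", preset$name, "' has no published ", assay,
         " summary: cannot simulate this cohort")
  m <- vals[1]; sem <- vals[2]
  n <- n %||% as.integer(vals[3])
  sdv <- preset_sd(sem, as.integer(vals[3]))

  seeds <- derive_seeds(seed, n + 1L)
  draw_seed <- seeds[1]
  cell_seeds <- seeds[-1]

  withr::with_seed(draw_seed, {
    truths <- switch(assay,
      invasion = rbeta_matched(n, m / 100, sdv / 100),
      rlnorm_matched(n, m, sdv))
    amp1 <- if (assay == "tweezers") rlnorm_matched(n, 1, 0.2) else NULL
  })

  cells <- vector("list", n)
  for (i in seq_len(n)) {
    cells[[i]] <- switch(assay,
      pillar = {
        args <- list(...)
        spec <- args$spec %||% pillar_array_spec()
        # 13 um: keeps the mask boundary off the 2-pitch lattice ring, so no
        # node sits exactly on the edge where rounding could flip membership
        mask <- args$cell_mask %||% disk_mask(128, 128, radius_um = 13,
                                              pixel_size = spec$pixel_size)
        extra <- args[setdiff(names(args), c("spec", "cell_mask"))]
        do.call(generate_pillar_video,
                c(list(spec = spec, cell_mask = mask,
                       force_scale = truths[i] * 0.6,
                       target_max_force = truths[i],
                       seed = cell_seeds[i]), extra))
      },
      afm = generate_indentation_curve(E_true = truths[i],
                                       seed = cell_seeds[i], ...),
      tweezers = generate_bead_trajectory(amp1 = amp1[i],
                                          relamp12 = truths[i],
                                          seed = cell_seeds[i], ...),
      invasion = generate_invasion_stack(below_fraction = truths[i],
                                         seed = cell_seeds[i], ...))
  }
  truth <- ground_truth(
    if (assay == "pillar") "pillar" else
      if (assay == "afm") "afm" else
        if (assay == "tweezers") "tweezers" else "invasion",
    list(preset = preset$name, cohort_mean = unname(m), cohort_sem = unname(sem),
         cohort_sd = unname(sdv), n = n, per_cell_truths = truths),
    seed)
  list(cells = cells, truth = truth)
}
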