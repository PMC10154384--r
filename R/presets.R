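#' Published condition presets for the Suit2 mechanophenotyping cohorts
#'
#' Cohort-level summaries (mean, SEM, n) for the five experimental conditions:
#' untreated control, RAR-beta agonist (CD 2314), RAR-beta knockdown
#' (`siRARB`), agonist + knockdown, and the MLC-2 overexpression rescue.
#' Values are the published cohort summaries for mean maximum traction force
#' (nN), cortical Young's modulus (Pa), relative 12th-pulse bead displacement
#' (dimensionless) and percent invasion at days 3 and 5. Entries the study did
#' not report numerically are `NA`; the cohort generator refuses to simulate
#' from them.
#'
#' @format A data frame with one row per condition.
#' @export
condition_presets <- function() {
  data.frame(
    name            = c("control", "agonist", "siRARB", "agonist_siRARB", "agonist_OE_MLC2"),
    traction_mean   = c(1.1, 0.7, NA, NA, 1.0),
    traction_sem    = c(0.1, 0.1, NA, NA, 0.1),
    n_traction      = c(70L, 53L, 97L, 110L, 87L),
    stiffness_mean  = c(292, 202, NA, NA, NA),
    stiffness_sem   = c(20, 12, NA, NA, NA),
    n_stiffness     = c(91L, 58L, 58L, 56L, 64L),
    relamp12_mean   = c(0.63, 0.84, NA, NA, NA),
    relamp12_sem    = c(0.02, 0.06, NA, NA, NA),
    n_tweezers      = c(41L, 22L, 28L, 30L, 21L),
    invasion_day3_pct = c(54, 44, NA, NA, 72),
    invasion_day3_sem = c(4, 3, NA, NA, 2),
    n_invasion_day3   = c(19L, 21L, NA, NA, 22L),
    invasion_day5_pct = c(75, 42, NA, NA, 70),
    invasion_day5_sem = c(3, 2, NA, NA, 2),
    n_invasion_day5   = c(21L, 18L, NA, NA, 22L),
    invasion_rate_per_day = c(12, 8, NA, NA, 10),
    stringsAsFactors = FALSE
  )
}

#' Look up one condition preset
#'
#' @param name one of `"control"`, `"agonist"`, `"siRARB"`,
#'   `"agonist_siRARB"`, `"agonist_OE_MLC2"`.
#' @return a one-row list of class `condition_preset`.
#' @export
condition_preset <- function(name) {
  tab <- condition_presets()
  i <- match(name, tab$name)
  if (is.na(i)) {
    stop("unknown condition preset '", name, "'; available: ",
         paste(tab$name, collapse = ", "))
  }
  out <- as.list(tab[i, ])
  class(out) <- "condition_preset"
  out
}

# Population SD implied by a reported SEM at sample size n.
preset_sd <- function(sem, n) sem * sqrt(n)
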