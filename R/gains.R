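#' Truncation-selection intensity
#'
#' Standardized selection differential for infinite-population truncation
#' selection of the best fraction `p`: `i = phi(z) / p` with `z` the
#' `(1 - p)` quantile of the standard normal. No finite-sample correction is
#' applied.
#'
#' @param p selected fraction, strictly in (0, 1); vectorized.
#' @return selection intensity (same length as `p`).
#' @examples
#' selection_intensity(0.02)   # 2.421
#' selection_intensity(0.10)   # 1.755
#' @export
selection_intensity <- function(p) {
  if (any(p <= 0 | p >= 1)) stop2("`p` must be strictly in (0, 1)")
  stats::dnorm(stats::qnorm(1 - p)) / p
}

#' GS accuracy from predictive ability
#'
#' `r_Ac = r_Ab / H`, where `H` is the square root of the broad-sense
#' heritability of the validation data; values above 1 (possible through
#' estimation noise) are returned with attribute `flagged = TRUE`.
#'
#' @param r_Ab predictive ability.
#' @param H square root of heritability, in (0, 1].
#' @return accuracy.
#' @export
accuracy_from_ability <- function(r_Ab, H) {
  if (H <= 0) stop2("`H` must be > 0")
  if (H > 1) stop2("`H` must be <= 1")
  out <- r_Ab / H
  if (any(abs(out) > 1)) attr(out, "flagged") <- TRUE
  out
}

#' Selection-scenario bundle for the GS vs PS efficiency calculus
#'
#' Collects the quantities entering the expected-gain comparison of genomic
#' selection (GS) and phenotypic selection (PS): predictive ability `r_Ab`
#' and comparator heritability root `H` (accuracy `r_Ac = r_Ab / H` is
#' recomputed, never stored independently), the SD of breeding values `s_A`,
#' the intensity ratio `i_G / i_P` (default 1.46, the midpoint of the
#' cost-derived 1.379-1.539 range for five-fold cheaper GS), cycle lengths
#' `t_G` (default 0.5 years: two GS cycles per year) and `t_P` (1 year for
#' two sites in one year, 2 years for two years at one site), and per-line
#' evaluation costs (defaults 40 and 200 currency units for GS and PS).
#'
#' @param r_Ab predictive ability of the GS model.
#' @param H square root of broad-sense heritability for the PS comparator,
#'   in (0, 1].
#' @param s_A SD of breeding values (trait units).
#' @param i_P standardized selection differential for PS.
#' @param intensity_ratio `i_G / i_P` (default 1.46).
#' @param t_G,t_P cycle lengths in years.
#' @param cost_GS,cost_PS evaluation cost per genotype.
#' @return object of class `gain_scenario` (with derived `r_Ac` and `i_G`).
#' @export
gain_scenario <- function(r_Ab, H, s_A = 1, i_P = selection_intensity(0.10),
                          intensity_ratio = 1.46, t_G = 0.5, t_P = 1,
                          cost_GS = 40, cost_PS = 200) {
  if (H <= 0 || H > 1) stop2("`H` must be in (0, 1]")
  if (t_G <= 0 || t_P <= 0) stop2("cycle lengths must be > 0")
  if (i_P <= 0 || intensity_ratio <= 0) stop2("intensities must be > 0")
  structure(list(r_Ab = r_Ab, H = H, r_Ac = accuracy_from_ability(r_Ab, H),
                 s_A = s_A, i_P = i_P, i_G = intensity_ratio * i_P,
                 intensity_ratio = intensity_ratio, t_G = t_G, t_P = t_P,
                 cost_GS = cost_GS, cost_PS = cost_PS),
            class = "gain_scenario")
}

#' Expected genetic gain per year from genomic selection
#'
#' `dG_G' = i_G * r_Ac * s_A / t_G`.
#'
#' @param scenario a [gain_scenario()].
#' @return gain per year, trait units.
#' @export
gain_per_year_gs <- function(scenario) {
  stopifnot(inherits(scenario, "gain_scenario"))
  scenario$i_G * as.numeric(scenario$r_Ac) * scenario$s_A / scenario$t_G
}

#' Expected genetic gain per year from phenotypic selection
#'
#' `dG_P' = i_P * H * s_A / t_P`.
#'
#' @param scenario a [gain_scenario()].
#' @return gain per year, trait units.
#' @export
gain_per_year_ps <- function(scenario) {
  stopifnot(inherits(scenario, "gain_scenario"))
  scenario$i_P * scenario$H * scenario$s_A / scenario$t_P
}

#' GS vs PS efficiency ratio
#'
#' Ratio of expected genetic gains per year for the same budget:
#' `(intensity_ratio * r_Ac / t_G) / (H / t_P)`. The breeding-value SD `s_A`
#' cancels and is not required.
#'
#' @param r_Ac GS accuracy.
#' @param H square root of the PS comparator heritability.
#' @param t_G,t_P cycle lengths in years (defaults 0.5 and 1).
#' @param intensity_ratio `i_G / i_P` (default 1.46).
#' @return efficiency ratio (> 1 favours GS).
#' @examples
#' efficiency_ratio(0.390, 0.632, t_P = 1)   # about 1.80
#' @export
efficiency_ratio <- function(r_Ac, H, t_G = 0.5, t_P = 1,
                             intensity_ratio = 1.46) {
  if (any(c(r_Ac, H, t_G, t_P, intensity_ratio) <= 0))
    stop2("all inputs must be positive")
  (intensity_ratio * r_Ac / t_G) / (H / t_P)
}

#' Intensity ratio implied by selection costs
#'
#' For a fixed budget, a `cost_ratio`-fold cheaper GS evaluation allows
#' `cost_ratio`-fold more genotypes, hence a `cost_ratio`-fold smaller
#' selected fraction: `i_G / i_P = i(p_PS / cost_ratio) / i(p_PS)`.
#'
#' @param base_selected_fraction_ps PS selected fraction, in (0, 1).
#' @param cost_ratio PS cost / GS cost (default 5).
#' @return the implied `i_G / i_P`.
#' @examples
#' intensity_ratio_from_costs(0.10, 5)   # 1.379
#' intensity_ratio_from_costs(0.20, 5)   # 1.539
#' @export
intensity_ratio_from_costs <- function(base_selected_fraction_ps,
                                       cost_ratio = 5) {
  p_ps <- base_selected_fraction_ps
  assert_proportion(p_ps, "base_selected_fraction_ps", 0, 1,
                    lo_open = TRUE, hi_open = TRUE)
  p_gs <- p_ps / cost_ratio
  if (p_gs <= 0 || p_gs >= 1) stop2("scaled GS fraction out of (0, 1)")
  selection_intensity(p_gs) / selection_intensity(p_ps)
}

#' Build a GS-vs-PS efficiency table
#'
#' Recomputes the efficiency ratios for a set of traits from their
#' `(r_Ac, H)` inputs under both PS cycle-length scenarios, mirroring the
#' audit trail inputs -> ratio.
#'
#' @param inputs data.frame with columns `trait`, `r_Ac`, `H` (optionally
#'   `r_Ac_inter` for an inter-population accuracy column).
#' @param t_G GS cycle length (default 0.5).
#' @param t_P_values PS cycle lengths (default `c(1, 2)`).
#' @param intensity_ratio `i_G / i_P` (default 1.46).
#' @return data.frame with one ratio column per scenario.
#' @export
gains_table <- function(inputs, t_G = 0.5, t_P_values = c(1, 2),
                        intensity_ratio = 1.46) {
  out <- inputs
  for (tp in t_P_values) {
    out[[sprintf("ratio_tP%g", tp)]] <-
      efficiency_ratio(inputs$r_Ac, inputs$H, t_G, tp, intensity_ratio)
    if ("r_Ac_inter" %in% names(inputs))
      out[[sprintf("ratio_inter_tP%g", tp)]] <-
        efficiency_ratio(inputs$r_Ac_inter, inputs$H, t_G, tp, intensity_ratio)
  }
  out
}
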