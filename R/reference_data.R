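#' Reference cohort group summary statistics
#'
#' Published per-segment group means (mean, SD, n) for a surgically
#' reconstructed (HLHS) cohort and age-matched (AM) controls: BSA-indexed
#' diameter, wall thickness and curvature; peak WERP pressure components
#' and viscous energy-loss peak; PWV, elastic modulus and transient timing
#' metrics. These summary values are the inputs to the derived
#' percentage / fold-change statistics layer; they are not computable from
#' phantom data.
#'
#' @return data frame with columns `metric`, `segment`, `units`, `group`,
#'   `mean`, `sd`, `n`
#' @export
cohort_reference_means <- function() {
  path <- system.file("extdata", "cohort_group_means.csv",
                      package = "aortaflow", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Derived cohort statistics from the reference group means
#'
#' Recomputes the headline percentage and fold-change comparisons between
#' the two groups from the per-segment reference means: relative size of
#' diameter and wall thickness, the curvature reduction in the
#' reconstructed ascending aorta, the rise in DA1 advective pressure
#' (both the WERP peak ratio and the peak-systolic advective-profile
#' fold), the DA2 viscous-loss excess, the ascending-aorta stiffness
#' increase and descending-aorta compliance gain, and the across-segment
#' average PWV.
#'
#' @param ref reference table, by default [cohort_reference_means()]
#' @return named list of derived statistics
#' @export
derived_cohort_statistics <- function(ref = cohort_reference_means()) {
  g <- function(metric, segment, group)
    ref$mean[ref$metric == metric & ref$segment == segment &
               ref$group == group]
  pooled <- function(metric, segments, group)
    mean(vapply(segments, function(s) g(metric, s, group), numeric(1)))
  list(
    diameter_aa_ta_pct = percent_difference(
      pooled("diameter", c("AA", "TA"), "AM"),
      pooled("diameter", c("AA", "TA"), "HLHS")),
    wall_thickness_aa_ta_pct = percent_difference(
      g("wall_thickness", "AA-TA", "AM"), g("wall_thickness", "AA-TA", "HLHS")),
    diameter_da1_pct = percent_difference(g("diameter", "DA1", "AM"),
                                          g("diameter", "DA1", "HLHS")),
    diameter_da2_pct = percent_difference(g("diameter", "DA2", "AM"),
                                          g("diameter", "DA2", "HLHS")),
    curvature_aa_pct = percent_difference(g("curvature", "AA", "AM"),
                                          g("curvature", "AA", "HLHS")),
    dp_adv_da1_fold = fold_change(g("peak_dp_adv", "DA1", "AM"),
                                  g("peak_dp_adv", "DA1", "HLHS")),
    dp_tot_da1_pct = percent_difference(g("peak_dp_tot", "DA1", "AM"),
                                        g("peak_dp_tot", "DA1", "HLHS")),
    saw_da1_fold = fold_change(g("saw_delta", "DA1", "AM"),
                               g("saw_delta", "DA1", "HLHS")),
    ve_da2_pct = percent_difference(g("ve_peak", "DA2", "AM"),
                                    g("ve_peak", "DA2", "HLHS")),
    e_aa_pct = percent_difference(g("elastic_modulus", "AA", "AM"),
                                  g("elastic_modulus", "AA", "HLHS")),
    e_da_pooled_pct = percent_difference(
      g("elastic_modulus", "DA-pooled", "AM"),
      g("elastic_modulus", "DA-pooled", "HLHS")),
    pwv_overall_mean = mean(ref$mean[ref$metric == "pwv"]))
}
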