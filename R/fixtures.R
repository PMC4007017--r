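#' Bundled synthetic connectivity ground truths
#'
#' Four synthetic data-generating path models over the ten motor
#' association ROIs, one per age group x coupling mode condition. Each
#' has 26 directed paths (so 36 free parameters and 19 chi-square
#' degrees of freedom over the 10 variables). The sets of strong paths
#' (|coef| around 0.4-0.6) differ across conditions in the qualitative
#' pattern expected of young vs elderly bimanual coordination networks:
#' the young models carry a reciprocal bilateral PMd coupling,
#' left-to-right SMA and premotor-to-contralateral-M1 drive, with a
#' PMd/SPL link that reverses direction between modes; the elderly
#' models shift towards right-to-left interhemispheric drive
#' (SMA, PMd), an intra-left PMd -> M1 -> S1 chain and right-parietal
#' input to premotor cortex. The remaining paths are weak filler
#' (coefficients 0.05-0.25). All coefficients are synthetic choices,
#' not estimates from any real dataset.
#'
#' @param group `"young"` or `"elderly"`.
#' @param mode `"in_phase"` or `"anti_phase"`.
#' @return a [connectivity_truth()] over [default_rois()].
#' @export
connectivity_fixture <- function(group = c("young", "elderly"),
                                 mode = c("in_phase", "anti_phase")) {
  group <- match.arg(group)
  mode <- match.arg(mode)
  P <- function(from, to, coef) data.frame(from = from, to = to, coef = coef)
  young_shared <- rbind(
    P("L.PMd", "R.PMd", 0.45), P("R.PMd", "L.PMd", 0.45),
    P("L.SMA", "R.SMA", 0.60), P("R.M1", "L.M1", 0.60),
    P("L.PMd", "R.M1", 0.50), P("L.PMd", "L.S1", 0.60),
    P("L.M1", "R.PMd", 0.40))
  young_filler <- rbind(
    P("L.SMA", "L.M1", 0.20), P("R.SMA", "R.M1", 0.20),
    P("L.SPL", "L.PMd", 0.20), P("L.SPL", "L.S1", 0.15),
    P("R.SPL", "R.S1", 0.15), P("L.S1", "L.M1", 0.20),
    P("R.S1", "R.M1", 0.20), P("L.SMA", "L.PMd", 0.15),
    P("R.SMA", "R.PMd", 0.15), P("L.SPL", "R.SPL", 0.20),
    P("L.S1", "L.SPL", 0.15), P("R.S1", "R.SPL", 0.15),
    P("L.SPL", "L.SMA", 0.15), P("R.SPL", "R.PMd", 0.10),
    P("L.S1", "R.S1", 0.10), P("R.SMA", "L.SMA", 0.05),
    P("L.M1", "R.M1", 0.05))
  elderly_shared <- rbind(
    P("R.SMA", "L.SMA", 0.60), P("R.PMd", "L.PMd", 0.60),
    P("L.PMd", "L.M1", 0.60), P("L.M1", "L.S1", 0.60),
    P("R.PMd", "R.M1", 0.50), P("R.SPL", "R.SMA", 0.50),
    P("R.S1", "R.PMd", 0.50))
  elderly_filler <- rbind(
    P("L.SMA", "L.M1", 0.20), P("R.SMA", "R.M1", 0.20),
    P("L.SPL", "L.PMd", 0.20), P("L.SPL", "L.S1", 0.15),
    P("R.SPL", "R.S1", 0.15), P("L.S1", "L.SPL", 0.15),
    P("L.SMA", "L.PMd", 0.15), P("R.SMA", "R.PMd", 0.15),
    P("L.SPL", "R.SPL", 0.20), P("L.SPL", "L.SMA", 0.15),
    P("R.SPL", "R.PMd", 0.10), P("L.S1", "R.S1", 0.10),
    P("L.SMA", "R.SMA", 0.05), P("L.PMd", "L.S1", 0.15))
  paths <- switch(paste(group, mode, sep = "."),
    young.in_phase = rbind(
      young_shared,
      P("R.SPL", "L.PMd", 0.50), P("R.SPL", "R.SMA", 0.50),
      young_filler),
    young.anti_phase = rbind(
      young_shared,
      P("L.PMd", "R.SPL", 0.50), P("L.PMd", "L.M1", 0.60),
      young_filler),
    elderly.in_phase = rbind(
      elderly_shared,
      P("R.S1", "L.PMd", 0.40), P("R.M1", "R.S1", 0.50),
      elderly_filler,
      P("R.M1", "L.M1", 0.10), P("L.M1", "R.M1", 0.05),
      P("L.M1", "R.PMd", 0.05)),
    elderly.anti_phase = rbind(
      elderly_shared,
      P("R.M1", "L.M1", 0.50), P("L.M1", "R.M1", 0.40),
      P("L.PMd", "R.M1", 0.50),
      elderly_filler,
      P("R.S1", "L.PMd", 0.15), P("L.M1", "R.PMd", 0.05)))
  connectivity_truth(default_rois(), paths, disturbance_vars = 1)
}
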