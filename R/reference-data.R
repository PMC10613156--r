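# Bundled clinical reference values for the two subjects (one healthy, one
# with severe mitral regurgitation) used by the worked examples: vitals,
# echo-Doppler peak-velocity comparisons, the reported hemodynamic index
# summaries, and the cardiac event times. These numbers are inputs to the
# helper arithmetic, not outputs of the simulations.

#' Reference subject data
#'
#' `lh_reference_vitals()`: heart rate, height, weight and the reported body
#' surface area of the healthy (H) and regurgitant (R) subjects.
#' `lh_reference_ecd()`: echo-Doppler peak velocities at three probe
#' locations (P1: upstream of the aortic valve; P2: downstream of the mitral
#' annulus; P3: above the apex) with the matching simulated peaks and the
#' reported relative discrepancies for subject H.
#' `lh_reference_indices()`: the reported per-subject index summary (E-wave
#' propagation index; percentage of wall area with RRT > 5 1/Pa in the LV,
#' LV apex, LA and appendage; time-averaged GTKE in LV and LA, mJ; total
#' exposure time to tau_max > 800 Pa, ms).
#' `lh_reference_events()`: cardiac event times (s) within the cycle.
#'
#' @return a `data.frame` (see each description).
#' @export
lh_reference_vitals <- function() {
  data.frame(
    subject = c("H", "R"),
    heart_rate_bpm = c(66, 75),
    height_m = c(1.93, 1.84),
    weight_kg = c(84, 105),
    bsa_reported_m2 = c(2.14, 2.28),
    period_s = c(0.9, 0.8)
  )
}

#' @rdname lh_reference_vitals
#' @export
lh_reference_ecd <- function() {
  data.frame(
    point = c("P1", "P2", "P3"),
    ecd_m_s = c(1.25, 0.85, 0.62),
    sim_m_s = c(1.20, 0.80, 0.60),
    delta_reported_pct = c(4.0, 5.9, 3.2)
  )
}

#' @rdname lh_reference_vitals
#' @export
lh_reference_indices <- function() {
  data.frame(
    subject = c("H", "R"),
    epi = c(1, 2),
    area_rrt5_lv_pct = c(68, 40),
    area_rrt5_lv_apex_pct = c(83, 53),
    area_rrt5_la_pct = c(48, 33),
    area_rrt5_laa_pct = c(100, 100),
    gtke_lv_mj = c(0.20, 4.80),
    gtke_la_mj = c(0.12, 7.30),
    exposure_ms = c(0, 220)
  )
}

#' @rdname lh_reference_vitals
#' @export
lh_reference_events <- function() {
  data.frame(
    subject = c("H", "R"),
    period_s = c(0.9, 0.8),
    av_closure_s = c(0.30, 0.32),
    mv_closure_s = c(0.9, 0.8),
    diastasis_reversal_s = c(0.63, 0.60),
    final_mv_reversal_s = c(NA, 0.77),
    gtke_peak_s = c(0.29, 0.25)
  )
}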