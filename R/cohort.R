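#' Validation-cohort tolerance data
#'
#' Per-participant maximum tolerable stimulation current (mA) and Visual
#' Analogue Scale (VAS, 0-10) pain rating for the two transcutaneous
#' spinal-cord stimulation paradigms used to validate the pupillometry
#' system: single monopolar rectangular pulses without kHz modulation (`MN`)
#' and with 5 kHz modulation (`MM`). Nine participants reached a defined
#' tolerance threshold and enter the paired analyses.
#'
#' @return `data.frame` with columns `participant`, `mn_current_ma`,
#'   `mn_vas`, `mm_current_ma`, `mm_vas`.
#' @export
tolerance_cohort <- function() {
  data.frame(
    participant = 1:9,
    mn_current_ma = c(240, 235, 240, 200, 90, 240, 240, 140, 100),
    mn_vas       = c(7, 8, 6, 7, 7, 8, 7, 9, 7),
    mm_current_ma = c(240, 230, 240, 200, 130, 250, 250, 240, 250),
    mm_vas       = c(7, 5, 4, 5, 6, 7, 2, 7, 6)
  )
}
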