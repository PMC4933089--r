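#' Cytotoxic treatment strategy
#'
#' The intervention loosely modelled on maximum-tolerated-dose chemotherapy:
#' while active, every HEALTHY (or DIVIDING) cell whose clock is at or below
#' the cut-off for its type is flagged TO_BE_CLEARED instead of completing
#' its cycle — a cell reaching clock zero under treatment dies rather than
#' divides. Higher cut-offs affect more cells and are therefore more toxic.
#' Differential toxicity uses a lower cut-off for Normal than for Malignant
#' cells; a `NA` Normal cut-off is the "magic bullet": toxicity applies to
#' Malignant cells only.
#'
#' @param trigger `"generation"` (start at a fixed tick) or
#'   `"malignant_count"` (start when the malignant population first reaches
#'   `trigger_value`).
#' @param trigger_value generation number or malignant-cell threshold.
#' @param duration number of consecutive active generations (`Inf` for
#'   open-ended).
#' @param cutoff_normal,cutoff_malignant clock cut-offs (>= 0), or `NA` to
#'   leave that cell type untargeted.
#' @return list of class `"cytotoxic_treatment"` for use as the `treatment`
#'   field of [sim_config()].
#' @examples
#' # the standard toxicity experiment: 25 generations from generation 1500
#' cytotoxic_treatment(trigger_value = 1500, duration = 25,
#'                     cutoff_normal = 20, cutoff_malignant = 20)
#' @export
cytotoxic_treatment <- function(trigger = c("generation", "malignant_count"),
                                trigger_value, duration = Inf,
                                cutoff_normal = NA, cutoff_malignant = NA) {
  trigger <- match.arg(trigger)
  tr <- list(trigger = trigger,
             trigger_value = as.numeric(trigger_value),
             duration = as.numeric(duration),
             cutoff_normal = if (is.na(cutoff_normal)) NA_integer_ else as.integer(cutoff_normal),
             cutoff_malignant = if (is.na(cutoff_malignant)) NA_integer_ else as.integer(cutoff_malignant))
  class(tr) <- "cytotoxic_treatment"
  tr
}

#' Treatment activation window
#'
#' A strategy triggered at generation `g` with duration `d` is active during
#' the half-open window `[g, g + d)`; the default no-treatment behaviour
#' applies before and after. A `malignant_count` trigger opens the window at
#' the first generation the malignant population reaches the threshold.
#'
#' @param treatment a [cytotoxic_treatment()] (or any list with `trigger`,
#'   `trigger_value`, `duration`).
#' @param generation current generation (1-based tick index).
#' @param malignant_count malignant population at the previous census; only
#'   used by the `malignant_count` trigger.
#' @param started_at for a count trigger that has already fired, the
#'   generation it fired at (`NA` if not yet fired).
#' @return `TRUE` while the strategy is active.
#' @export
window_active <- function(treatment, generation, malignant_count = 0,
                          started_at = NA) {
  start <- if (treatment$trigger == "generation") {
    treatment$trigger_value
  } else if (!is.na(started_at)) {
    started_at
  } else if (malignant_count >= treatment$trigger_value) {
    generation
  } else {
    return(FALSE)
  }
  generation >= start && generation < start + treatment$duration
}

#' Flag cells for cytotoxic clearance
#'
#' Vectorised application of the age cut-off over a cell population:
#' HEALTHY or DIVIDING cells with `clock <= cutoff` for their type are
#' flagged. Flagging is idempotent — already-flagged cells stay flagged and
#' no others are affected by a repeated application.
#'
#' @param clock integer vector of cell clocks.
#' @param type `"Normal"`/`"Malignant"` character vector (or 0/1 integers).
#' @param state cell-state names (default all `"HEALTHY"`).
#' @param cutoff_normal,cutoff_malignant cut-offs, `NA` = type untargeted.
#' @return logical vector: which cells are flagged TO_BE_CLEARED.
#' @export
flag_cytotoxic <- function(clock, type, state = rep("HEALTHY", length(clock)),
                           cutoff_normal = NA, cutoff_malignant = NA) {
  type_int <- if (is.numeric(type)) as.integer(type) else
    as.integer(type %in% c("Malignant", "MALIGNANT", "malignant"))
  state_int <- CELL_STATES[match(state, names(CELL_STATES))]
  cpp_flag_cytotoxic(as.integer(clock), type_int, as.integer(state_int),
                     if (is.na(cutoff_normal)) -1L else as.integer(cutoff_normal),
                     if (is.na(cutoff_malignant)) -1L else as.integer(cutoff_malignant))
}
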