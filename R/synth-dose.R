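## Dose-effect scenarios: multiplicative modulation of activity or
## morphology parameters as a function of dose and exposure time, used to
## inject known excitatory (factor > 1) or inhibitory (factor < 1) effects
## into the generators.

#' Multiplicative dose-and-time effect map
#'
#' @param factors `data.frame` with columns `dose`, `timepoint` (hours) and
#'   `factor` (> 0).  The untreated conditions are fixed points: any row
#'   with `dose == 0` or `timepoint == 0` must carry factor 1.
#' @return An object of class `dose_effect_spec` with the factor map and a
#'   per-row `direction` (`excitatory`, `inhibitory`, `none`).
#' @export
dose_effect_spec <- function(factors) {
  need <- c("dose", "timepoint", "factor")
  stop_if(!is.data.frame(factors) || !all(need %in% names(factors)),
          "`factors` needs columns dose, timepoint, factor")
  stop_if(any(factors$factor < 0),
          "factors must be >= 0 (0 = complete suppression)")
  bad <- (factors$dose == 0 | factors$timepoint == 0) & factors$factor != 1
  stop_if(any(bad),
          "factor must be 1 at dose 0 and at timepoint 0 h")
  stop_if(anyDuplicated(factors[, c("dose", "timepoint")]) > 0,
          "duplicate (dose, timepoint) rows")
  factors$direction <- ifelse(factors$factor > 1, "excitatory",
                              ifelse(factors$factor < 1, "inhibitory",
                                     "none"))
  structure(list(factors = factors), class = "dose_effect_spec")
}

effect_factor <- function(effect, dose, timepoint) {
  stop_if(!inherits(effect, "dose_effect_spec"),
          "`effect` must be a dose_effect_spec")
  hit <- effect$factors$dose == dose & effect$factors$timepoint == timepoint
  stop_if(!any(hit), "no factor for dose %g at %g h", dose, timepoint)
  effect$factors$factor[which(hit)[1]]
}

#' Apply a dose effect to a generator specification
#'
#' Scales the activity parameters of a [spike_train_spec()] (background and
#' burst rates) or the outgrowth parameters of a [morphology_spec()]
#' (segment-length range) by the factor registered for `(dose, timepoint)`.
#' The factor applied is recorded in the `dose_effect` attribute of the
#' result.
#'
#' @param base A [spike_train_spec()] or [morphology_spec()].
#' @param effect A [dose_effect_spec()].
#' @param dose,timepoint Condition looked up in the effect map; unknown
#'   combinations are an error.
#' @return A modified copy of `base`.
#' @export
apply_dose_effect <- function(base, effect, dose, timepoint) {
  f <- effect_factor(effect, dose, timepoint)
  out <- base
  if (inherits(base, "spike_train_spec")) {
    out$background_rate <- base$background_rate * f
    out$burst_rate <- base$burst_rate * f
  } else if (inherits(base, "morphology_spec")) {
    scaled <- pmax(base$segment_length * f, 12)
    if (f == 0) scaled <- c(12, 12)   # floor of the drawable length
    out$segment_length <- scaled
  } else {
    stop("`base` must be a spike_train_spec or morphology_spec",
         call. = FALSE)
  }
  attr(out, "dose_effect") <- list(dose = dose, timepoint = timepoint,
                                   factor = f)
  out
}
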