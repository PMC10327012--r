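# Rule-based firing-pattern phenotype classification from interspike
# intervals. The labels follow the field's phenotype vocabulary: NASP
# (non-adapting spiking), ASP. (adapting spiking), TSTUT. (transient
# stuttering), PSTUT (persistent stuttering), SLN (silence), SP (spiking,
# too few spikes to subclassify), and dot-compositions such as TSTUT.SLN
# (silence preceded by transient stuttering).

FIRING_PATTERN_LABELS <- c("NASP", "ASP.", "TSTUT.", "PSTUT", "SLN", "SP",
                           "TSTUT.SLN", "ASP.SLN", "TSTUT.PSTUT")

#' Closed vocabulary of firing-pattern labels
#'
#' @return Character vector of the labels [classify_firing_pattern()] can
#'   draw from.
#' @export
firing_pattern_labels <- function() FIRING_PATTERN_LABELS

#' Classify a spike train's firing-pattern phenotype
#'
#' A deterministic, total rule tree over interspike-interval (ISI)
#' statistics within the stimulus window. The thresholds are package-defined
#' simplifications of the field's quantitative phenotype analysis:
#'
#' * silence (`SLN` component): no spikes in the final 50% of the stimulus;
#' * stuttering: ISI coefficient of variation >= 0.5 with a largest gap at
#'   least 3 times the median ISI; transient (`TSTUT.`) when every gap ends
#'   within the first third of the stimulus, persistent (`PSTUT`) otherwise;
#' * adapting (`ASP.`): last-to-first ISI ratio >= 1.5 (without stuttering);
#' * `NASP` otherwise; trains of one or two spikes that keep firing past the
#'   midpoint are labelled `SP`.
#'
#' Every train receives exactly one label from [firing_pattern_labels()].
#'
#' @param spike_times_ms Spike times (ms).
#' @param protocol The [step_protocol()] that produced the train (defines
#'   the stimulus window).
#' @return A single label string.
#' @examples
#' proto <- step_protocol(0, onset_ms = 0, duration_ms = 900, tail_ms = 0)
#' classify_firing_pattern(seq(50, 850, by = 50), proto)  # "NASP"
#' @export
classify_firing_pattern <- function(spike_times_ms, protocol) {
  stopifnot(inherits(protocol, "step_protocol"))
  t0 <- protocol$onset_ms
  dur <- protocol$duration_ms
  st <- sort(spike_times_ms[spike_times_ms >= t0 & spike_times_ms <= t0 + dur])
  n <- length(st)
  if (n == 0) {
    return("SLN")
  }
  rel <- (st - t0) / dur
  silent_tail <- all(rel <= 0.5)
  if (n <= 2) {
    return(if (silent_tail) "TSTUT.SLN" else "SP")
  }
  isi <- diff(st)
  cv <- sd(isi) / mean(isi)
  adapt_ratio <- isi[length(isi)] / isi[1]
  med <- median(isi)
  stutter <- cv >= 0.5 && max(isi) / med >= 3
  if (silent_tail) {
    if (!stutter && adapt_ratio >= 1.5) {
      return("ASP.SLN")
    }
    return("TSTUT.SLN")
  }
  if (stutter) {
    gap_ends <- st[which(isi >= 3 * med) + 1]
    if (all((gap_ends - t0) / dur <= 1 / 3)) {
      return("TSTUT.")
    }
    return("PSTUT")
  }
  if (adapt_ratio >= 1.5) {
    return("ASP.")
  }
  "NASP"
}
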