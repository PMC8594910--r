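## Three-step phosphene-threshold (PT) staircase protocol and the synthetic
## observer answering its trials.
##
## Step 1 ascends in 50 uA steps from 50 to 500 uA until the first detection
## (the reference). Step 2 presents reference -25/+25/+50 uA twice each and
## keeps the lowest intensity detected on both presentations. Step 3
## presents the step-2 value -25/0/+25 uA three times each at 16 Hz, in
## random order with one 5 Hz catch burst per intensity, and the PT is the
## lowest intensity detected in at least two of three 16 Hz trials.

#' Synthetic observer
#'
#' A psychometric observer with detection probability
#' `p = gate(freq) * ((1 - lapse) * Psi((I - theta)/slope) + fp * (1 - Psi))`
#' where `Psi` is the standard normal CDF. `slope = 0` gives a deterministic
#' step observer (detect iff intensity >= theta at 16 Hz). The 5 Hz control
#' frequency is gated by `gate5` (default 0: catch bursts are never
#' detected).
#'
#' @param threshold_uA true detection threshold theta (uA), > 0.
#' @param slope_uA psychometric spread (uA), >= 0; 0 = deterministic.
#' @param lapse lapse rate in `[0, 1]`.
#' @param fp false-positive rate in `[0, 1]`.
#' @param gate5 detection-probability multiplier at 5 Hz (default 0).
#' @return list of class `observer_model`.
#' @export
observer_model <- function(threshold_uA, slope_uA = 0, lapse = 0, fp = 0,
                           gate5 = 0) {
  if (threshold_uA <= 0) stop("threshold must be positive")
  if (slope_uA < 0) stop("slope must be >= 0")
  if (any(c(lapse, fp, gate5) < 0) || any(c(lapse, fp, gate5) > 1))
    stop("rates must be in [0, 1]")
  structure(list(threshold = threshold_uA, slope = slope_uA,
                 lapse = lapse, fp = fp, gate5 = gate5),
            class = "observer_model")
}

#' Observer response to one stimulation burst
#'
#' Deterministic when the detection probability is 0 or 1 (no random number
#' is consumed); otherwise a Bernoulli draw from the session RNG stream.
#'
#' @param observer an [observer_model()].
#' @param intensity_uA burst intensity (uA).
#' @param freq_hz 16 (stimulation) or 5 (control).
#' @return logical: phosphene reported?
#' @export
respond <- function(observer, intensity_uA, freq_hz = 16) {
  gate <- if (freq_hz == 5) observer$gate5 else 1
  base <- if (observer$slope == 0) {
    as.numeric(intensity_uA >= observer$threshold)
  } else {
    stats::pnorm((intensity_uA - observer$threshold) / observer$slope)
  }
  p <- gate * ((1 - observer$lapse) * base + observer$fp * (1 - base))
  if (p <= 0) return(FALSE)
  if (p >= 1) return(TRUE)
  stats::runif(1) < p
}

new_trial_log <- function() {
  data.frame(step = integer(0), order = integer(0),
             intensity_uA = numeric(0), freq_hz = numeric(0),
             response = logical(0))
}

log_trial <- function(log, step, intensity, freq, response) {
  rbind(log, data.frame(step = step, order = nrow(log) + 1L,
                        intensity_uA = intensity, freq_hz = freq,
                        response = response))
}

#' Step 1: ascending series
#'
#' Intensity rises in 50 uA steps from 50 to 500 uA until the observer
#' reports a phosphene; returns that reference intensity, or `NA` if no
#' burst is detected.
#'
#' @param observer an [observer_model()].
#' @param log optional existing trial log to append to.
#' @return list `reference` (uA or NA) and `log`.
#' @export
step1_ascending <- function(observer, log = new_trial_log()) {
  for (I in seq(50, 500, by = 50)) {
    det <- respond(observer, I, 16)
    log <- log_trial(log, 1L, I, 16, det)
    if (det) return(list(reference = I, log = log))
  }
  list(reference = NA_real_, log = log)
}

#' Step 2: refinement around the reference
#'
#' Presents reference -25, +25 and +50 uA twice each (intensities below
#' 25 uA are clamped to 25 uA) and returns the lowest intensity detected on
#' both presentations. If no intensity is detected twice, the reference is
#' returned, flagged.
#'
#' @param observer an [observer_model()].
#' @param reference step-1 reference intensity (uA).
#' @param log optional trial log.
#' @return list `refined` (uA), `fallback` (logical) and `log`.
#' @export
step2_refine <- function(observer, reference, log = new_trial_log()) {
  if (is.na(reference)) stop("reference is NA; step 1 found no detection")
  cand <- pmax(25, reference + c(-25, 25, 50))
  both <- logical(length(cand))
  for (i in seq_along(cand)) {
    d1 <- respond(observer, cand[i], 16)
    log <- log_trial(log, 2L, cand[i], 16, d1)
    d2 <- respond(observer, cand[i], 16)
    log <- log_trial(log, 2L, cand[i], 16, d2)
    both[i] <- d1 && d2
  }
  if (any(both))
    list(refined = min(cand[both]), fallback = FALSE, log = log)
  else
    list(refined = reference, fallback = TRUE, log = log)
}

#' Step 3: randomized final measurement
#'
#' Presents the step-2 intensity -25/0/+25 uA three times each at 16 Hz
#' plus one 5 Hz catch burst per intensity, all in randomized order. The PT
#' is the lowest intensity (at or above the 50 uA protocol floor) detected
#' in at least two of its three 16 Hz presentations; if none qualifies, the
#' step-2 value +25 uA is returned flagged invalid. Catch-burst responses
#' are logged but excluded from the threshold rule.
#'
#' @param observer an [observer_model()].
#' @param refined step-2 intensity (uA).
#' @param log optional trial log.
#' @return list `pt` (uA), `valid`, and `log`.
#' @export
step3_final <- function(observer, refined, log = new_trial_log()) {
  cand <- unique(pmax(25, refined + c(-25, 0, 25)))
  bursts <- data.frame(
    intensity = c(rep(cand, each = 3L), cand),
    freq = c(rep(16, 3L * length(cand)), rep(5, length(cand))))
  bursts <- bursts[sample.int(nrow(bursts)), ]
  hits <- setNames(integer(length(cand)), cand)
  for (i in seq_len(nrow(bursts))) {
    I <- bursts$intensity[i]; fr <- bursts$freq[i]
    det <- respond(observer, I, fr)
    log <- log_trial(log, 3L, I, fr, det)
    if (fr == 16 && det) hits[as.character(I)] <- hits[as.character(I)] + 1L
  }
  eligible <- cand[cand >= 50 & hits[as.character(cand)] >= 2L]
  if (length(eligible))
    list(pt = min(eligible), valid = TRUE, log = log)
  else
    list(pt = refined + 25, valid = FALSE, log = log)
}

#' Run the full three-step protocol
#'
#' Chains [step1_ascending()], [step2_refine()] and [step3_final()] with a
#' complete trial log. For a deterministic observer (`slope = 0`, no lapses
#' or false positives) with threshold `theta` in `[26, 500]` uA the result
#' is the protocol's quantization law `PT = 25 * ceiling(theta / 25)`.
#'
#' @param observer an [observer_model()].
#' @param subject,montage optional identifiers stored in the record.
#' @return object of class `threshold_record`: `pt` (uA or NA), `valid`,
#'   `reason`, `reference`, `refined`, `trials` (log data.frame).
#' @export
run_protocol <- function(observer, subject = NA, montage = NA_character_) {
  s1 <- step1_ascending(observer)
  if (is.na(s1$reference)) {
    return(structure(list(subject = subject, montage = montage,
                          pt = NA_real_, valid = FALSE,
                          reason = "no detection in ascending series",
                          reference = NA_real_, refined = NA_real_,
                          trials = s1$log),
                     class = "threshold_record"))
  }
  s2 <- step2_refine(observer, s1$reference, s1$log)
  s3 <- step3_final(observer, s2$refined, s2$log)
  structure(list(subject = subject, montage = montage,
                 pt = s3$pt,
                 valid = s3$valid && !s2$fallback,
                 reason = if (s3$valid && !s2$fallback) NA_character_
                          else "no intensity reached the detection criterion",
                 reference = s1$reference, refined = s2$refined,
                 trials = s3$log),
            class = "threshold_record")
}

#' @export
print.threshold_record <- function(x, ...) {
  cat("threshold_record:",
      if (is.na(x$pt)) "PT = NA" else sprintf("PT = %g uA", x$pt),
      if (x$valid) "(valid)" else sprintf("(invalid: %s)", x$reason), "\n")
  invisible(x)
}
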