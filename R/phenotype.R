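#' Allergen-induced shift in methacholine PC20
#'
#' The ratio of the provocative methacholine concentration (PC20, mg/mL)
#' measured one day before allergen challenge to the PC20 measured one day
#' after. Values >= 2 indicate an allergen-induced increase in airway
#' hyperresponsiveness of at least one doubling dose.
#'
#' @param pc20_pre,pc20_post PC20 in mg/mL, both > 0.
#' @return `pc20_pre / pc20_post`.
#' @export
allergen_induced_shift <- function(pc20_pre, pc20_post) {
  if (any(pc20_pre <= 0) || any(pc20_post <= 0))
    stop("PC20 values must be positive")
  pc20_pre / pc20_post
}

#' Maximum late-phase FEV1 drop
#'
#' The most negative percent change from baseline FEV1 within the closed
#' late-phase window [3, 7] hours post-challenge.
#'
#' @param times Measurement times in hours.
#' @param fev1_pct_change Percent change from baseline at each time
#'   (negative = fall).
#' @return The most negative (minimum) percent change in the window.
#' @export
max_late_drop <- function(times, fev1_pct_change) {
  stopifnot(length(times) == length(fev1_pct_change))
  in_window <- times >= 3 & times <= 7
  if (!any(in_window)) stop("no FEV1 measurements in the 3-7 h window")
  min(fev1_pct_change[in_window])
}

#' Classify a subject as isolated early responder or dual responder
#'
#' A subject is a dual responder (DR) if the maximum late-phase (3-7 h) FEV1
#' drop is >= 15% (`max_late_drop <= -15`, rule `late_drop`), or failing that
#' if the fall at 7 h exceeds 10% (`drop_at_7h < -10`) and the
#' allergen-induced shift is >= 2 (rule `ais_rescue`, capturing a late
#' response that develops after the last spirometric measurement). Otherwise
#' the subject is an isolated early responder (ER).
#'
#' @param max_late_drop Most negative percent FEV1 change in 3-7 h.
#' @param drop_at_7h Percent FEV1 change at (nearest to) 7 h.
#' @param ais Allergen-induced shift; may be `NA` only if the rescue rule is
#'   never reached.
#' @return A list with `label` (`"ER"` or `"DR"`) and `rule_fired`
#'   (`"late_drop"`, `"ais_rescue"` or `"none"`).
#' @export
classify_responder <- function(max_late_drop, drop_at_7h, ais = NA_real_) {
  if (max_late_drop <= -15)
    return(list(label = "DR", rule_fired = "late_drop"))
  if (drop_at_7h < -10) {
    if (is.na(ais)) stop("AIS required to evaluate the rescue rule")
    if (ais >= 2) return(list(label = "DR", rule_fired = "ais_rescue"))
  }
  list(label = "ER", rule_fired = "none")
}

#' Classify responders for a table of subjects
#'
#' Applies [max_late_drop()] and [classify_responder()] to a spirometry table.
#' The 7 h drop is taken as the measurement nearest 7 h within +/- 15 min.
#'
#' @param spirometry A data.frame with columns `subject_id`, `time_h`,
#'   `fev1_pct_change`, and per-subject `pc20_pre`, `pc20_post`.
#' @return A data.frame: `subject_id`, `max_late_drop`, `drop_at_7h`, `ais`,
#'   `label`, `rule_fired`.
#' @export
classify_responders <- function(spirometry) {
  need <- c("subject_id", "time_h", "fev1_pct_change", "pc20_pre", "pc20_post")
  missing <- setdiff(need, names(spirometry))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  out <- lapply(split(spirometry, spirometry$subject_id), function(d) {
    mld <- max_late_drop(d$time_h, d$fev1_pct_change)
    near7 <- which(abs(d$time_h - 7) <= 0.25)
    if (!length(near7)) stop("subject ", d$subject_id[1], ": no measurement near 7 h")
    d7 <- d$fev1_pct_change[near7[which.min(abs(d$time_h[near7] - 7))]]
    ais <- allergen_induced_shift(d$pc20_pre[1], d$pc20_post[1])
    call <- classify_responder(mld, d7, ais)
    data.frame(subject_id = d$subject_id[1], max_late_drop = mld,
               drop_at_7h = d7, ais = ais, label = call$label,
               rule_fired = call$rule_fired, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[match(unique(spirometry$subject_id), res$subject_id), , drop = FALSE]
}
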