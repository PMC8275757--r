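# Behavioural outcome scores: reappraisal success, affective distance,
# dietary health-challenge success, and the assembled score table.

#' Per-stimulus reappraisal success
#'
#' Rating shift toward neutral: \code{reappraise - view} for negative
#' stimuli, \code{view - reappraise} for positive stimuli (SAM scale,
#' 1 = most negative ... 9 = most positive). Positive scores mean the
#' feeling moved toward neutral.
#'
#' @param view_rating,reappraise_rating integer ratings in 1..9 (vectors
#'   recycled to common length).
#' @param valence character, \code{"positive"} or \code{"negative"} per
#'   stimulus; neutral stimuli have no defined success and raise an error.
#' @return numeric signed success scores, SAM points.
#' @export
reappraisal_success <- function(view_rating, reappraise_rating, valence) {
  if (any(valence == "neutral"))
    pc_stop_data("reappraisal success is undefined for neutral stimuli")
  if (!all(valence %in% c("positive", "negative")))
    pc_stop_data("valence must be 'positive' or 'negative'")
  ok <- function(r) all(r >= 1 & r <= 9 & r == round(r))
  if (!ok(view_rating) || !ok(reappraise_rating))
    pc_stop_data("ratings must be integers in 1..9")
  ifelse(valence == "negative",
         reappraise_rating - view_rating,
         view_rating - reappraise_rating)
}

#' Overall reappraisal success (RS)
#'
#' Per-stimulus scores are averaged within valence first, then the two
#' valence means are averaged, so unequal numbers of missing ratings cannot
#' bias the score.
#'
#' @param scores numeric per-stimulus success scores.
#' @param valence character vector parallel to \code{scores}.
#' @return single RS value, SAM points (range -8..8).
#' @export
overall_success <- function(scores, valence) {
  keep <- !is.na(scores)
  scores <- scores[keep]; valence <- valence[keep]
  if (!any(valence == "positive") || !any(valence == "negative"))
    pc_stop_data("both valences are required to compute RS")
  mean(c(mean(scores[valence == "negative"]),
         mean(scores[valence == "positive"])))
}

#' Affective distance
#'
#' Mean absolute distance of the view ratings of the regulated stimuli from
#' the scale midpoint (5 on the 9-point SAM scale); a proxy for average
#' regulation difficulty.
#'
#' @param view_ratings integer ratings in 1..9.
#' @return mean |rating - 5|, SAM points (range 0..4).
#' @export
affective_distance <- function(view_ratings) {
  view_ratings <- view_ratings[!is.na(view_ratings)]
  if (!length(view_ratings)) pc_stop_data("no view ratings supplied")
  if (!all(view_ratings >= 1 & view_ratings <= 9))
    pc_stop_data("ratings must lie in 1..9")
  mean(abs(view_ratings - 5))
}

#' Dietary health-challenge success (HCS)
#'
#' Percentage of answered challenge trials in which the participant refused
#' a tasty-unhealthy food or accepted a healthy-untasty food. Trials without
#' a logged response are excluded from the denominator (count attached as
#' attribute \code{"n_missed"}).
#'
#' @param choices data.frame with columns \code{challenge_flag} (logical),
#'   \code{food_type} and \code{choice} (\code{"yes"}/\code{"no"}/NA).
#' @return HCS in percent (0..100).
#' @export
health_challenge_success <- function(choices) {
  need <- c("challenge_flag", "food_type", "choice")
  miss <- setdiff(need, names(choices))
  if (length(miss)) pc_stop_data("choice table lacks column(s): ",
                                 paste(miss, collapse = ", "))
  ch <- choices[choices$challenge_flag, ]
  answered <- ch[!is.na(ch$choice), ]
  if (!nrow(answered)) pc_stop_data("no answered challenge trials")
  controlled <- (answered$food_type == "tasty-unhealthy" & answered$choice == "no") |
    (answered$food_type == "healthy-untasty" & answered$choice == "yes")
  out <- 100 * mean(controlled)
  attr(out, "n_missed") <- sum(is.na(ch$choice))
  out
}

#' Assemble the per-participant score table
#'
#' Joins the behavioural scores of a synthetic cohort (RS, affective
#' distance, HCS, age, task order) with a PDI table.
#'
#' @param cohort a [generate_cohort()] result.
#' @param pdi a \code{pdi_table} from [compute_pdi()] (optional; PDI column
#'   is NA when absent).
#' @return data.frame of class \code{score_table} with columns
#'   \code{participant_id}, \code{PDI}, \code{RS}, \code{AffectiveDistance},
#'   \code{HCS}, \code{Age}, \code{TaskOrder}.
#' @export
build_score_table <- function(cohort, pdi = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  rows <- lapply(cohort$participants, function(p) {
    s <- reappraisal_success(p$ratings$view_rating, p$ratings$reappraise_rating,
                             p$ratings$valence)
    data.frame(participant_id = p$participant_id,
               RS = overall_success(s, p$ratings$valence),
               AffectiveDistance = affective_distance(p$ratings$view_rating),
               HCS = as.numeric(health_challenge_success(p$choices)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- merge(out, cohort$truth[, c("participant_id", "age", "task_order")],
               by = "participant_id", sort = FALSE)
  names(out)[names(out) == "age"] <- "Age"
  names(out)[names(out) == "task_order"] <- "TaskOrder"
  out$PDI <- if (is.null(pdi)) NA_real_ else
    pdi$pdi[match(out$participant_id, pdi$participant_id)]
  out <- out[, c("participant_id", "PDI", "RS", "AffectiveDistance",
                 "HCS", "Age", "TaskOrder")]
  class(out) <- c("score_table", "data.frame")
  out
}
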