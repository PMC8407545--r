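#' Build a participant's serial timeline
#'
#' @param participant_id Identifier.
#' @param tf_series `data.frame` with `day`, `tf`, `detected` (days strictly
#'   increasing).
#' @param sld_series `data.frame` with `day`, `sld`, `recist` (days strictly
#'   increasing), or NULL.
#' @param therapy_change_days Sorted integer days of therapy changes.
#' @return Object of class `serial_timeline`.
#' @export
serial_timeline <- function(participant_id, tf_series, sld_series = NULL,
                            therapy_change_days = integer(0)) {
  stopifnot(all(c("day", "tf", "detected") %in% names(tf_series)))
  if (any(diff(tf_series$day) <= 0))
    stop("tf_series days must be strictly increasing", call. = FALSE)
  if (!is.null(sld_series) && nrow(sld_series) &&
      any(diff(sld_series$day) <= 0))
    stop("sld_series days must be strictly increasing", call. = FALSE)
  structure(list(participant_id = participant_id,
                 tf_series = tf_series, sld_series = sld_series,
                 therapy_change_days = sort(therapy_change_days)),
            class = "serial_timeline")
}

#' Match plasma tumor fractions to nearest eligible SLD
#'
#' Each plasma sample is paired with its nearest SLD observation within
#' `max_gap_days` (inclusive) and without any therapy change strictly
#' between the plasma and imaging days. Gap ties are broken toward the
#' earlier SLD. Plasma samples with no eligible SLD are dropped.
#'
#' @param timeline A `serial_timeline`.
#' @param max_gap_days Maximum |plasma day - SLD day| (default 30).
#' @return `data.frame` with `participant_id`, `plasma_day`, `sld_day`,
#'   `tf`, `sld`, `gap_days` (possibly 0 rows).
#' @export
match_sld_tf <- function(timeline, max_gap_days = 30) {
  empty <- data.frame(participant_id = character(), plasma_day = numeric(),
                      sld_day = numeric(), tf = numeric(), sld = numeric(),
                      gap_days = numeric(), stringsAsFactors = FALSE)
  sld <- timeline$sld_series
  if (is.null(sld) || nrow(sld) == 0L) return(empty)
  tcd <- timeline$therapy_change_days
  rows <- lapply(seq_len(nrow(timeline$tf_series)), function(i) {
    pd <- timeline$tf_series$day[i]
    gap <- abs(sld$day - pd)
    eligible <- gap <= max_gap_days &
      !vapply(sld$day, function(sd)
        any(tcd > min(pd, sd) & tcd < max(pd, sd)), logical(1))
    if (!any(eligible)) return(NULL)
    cand <- which(eligible)
    best <- cand[order(gap[cand], sld$day[cand])][1]
    data.frame(participant_id = timeline$participant_id, plasma_day = pd,
               sld_day = sld$day[best], tf = timeline$tf_series$tf[i],
               sld = sld$sld[best], gap_days = gap[best],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Pearson correlation of matched SLD and tumor fraction
#'
#' @param pairs `data.frame` from [match_sld_tf()] (or any with `sld`,
#'   `tf`), n >= 3.
#' @return List: `r`, `p_value` (two-sided, t distribution), `n`.
#' @export
correlate <- function(pairs) {
  n <- nrow(pairs)
  if (n < 3L) stop("need >= 3 pairs", call. = FALSE)
  if (stats::sd(pairs$sld) == 0 || stats::sd(pairs$tf) == 0)
    stop("zero variance in sld or tf", call. = FALSE)
  ct <- stats::cor.test(pairs$sld, pairs$tf)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Normalize a serial tumor-fraction series
#'
#' Each detected value is divided by the participant's lowest detected
#' value and log2-transformed, so the minimum detected timepoint maps to 0.
#' Undetected timepoints are rendered as a sentinel one log2 unit below the
#' series minimum (rather than -Inf).
#'
#' @param tf_series `data.frame` with `tf` and `detected`.
#' @return Numeric per-timepoint values.
#' @export
normalize_serial <- function(tf_series) {
  det <- tf_series$detected
  if (!any(det)) stop("no detected values in series", call. = FALSE)
  ref <- min(tf_series$tf[det])
  out <- log2(tf_series$tf / ref)
  sentinel <- min(out[det]) - 1
  out[!det] <- sentinel
  out
}

#' Fold change between two tumor fractions
#'
#' @param tf_a Earlier tumor fraction; must be detected and > 0.
#' @param tf_b Later tumor fraction.
#' @param detected_a Whether `tf_a` was detected (default TRUE).
#' @return `tf_b / tf_a`.
#' @export
fold_change <- function(tf_a, tf_b, detected_a = TRUE) {
  if (!detected_a || is.na(tf_a) || tf_a <= 0)
    stop("baseline tumor fraction undetected", call. = FALSE)
  tf_b / tf_a
}

#' Lead time of molecular relapse over radiographic progression
#'
#' Days between the first detected tumor fraction after an undetected nadir
#' and the first radiographic progression (by default the first RECIST PD
#' label; optionally the first nonzero SLD after a zero-SLD interval, the
#' post-resection surveillance situation). `NULL` if tumor fraction is
#' never re-detected or no progression is observed.
#'
#' @param timeline A `serial_timeline`.
#' @param progression One of `"pd"` (first PD label) or `"sld_rebound"`
#'   (first SLD > 0 after an observed SLD of 0).
#' @return Integer days (progression day minus molecular detection day), or
#'   `NULL`.
#' @export
lead_time <- function(timeline, progression = c("pd", "sld_rebound")) {
  progression <- match.arg(progression)
  ts <- timeline$tf_series
  nadir <- which(!ts$detected)[1]
  if (is.na(nadir)) return(NULL)
  redet <- which(ts$detected & seq_len(nrow(ts)) > nadir)[1]
  if (is.na(redet)) return(NULL)
  sld <- timeline$sld_series
  if (is.null(sld) || nrow(sld) == 0L) return(NULL)
  prog_day <- if (progression == "pd") {
    pd <- which(sld$recist == "PD")[1]
    if (is.na(pd)) return(NULL) else sld$day[pd]
  } else {
    zero <- which(sld$sld == 0)[1]
    if (is.na(zero)) return(NULL)
    reb <- which(sld$sld > 0 & seq_len(nrow(sld)) > zero)[1]
    if (is.na(reb)) return(NULL) else sld$day[reb]
  }
  prog_day - ts$day[redet]
}
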