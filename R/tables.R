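# Event and behavior tables (delimited text), subsequent-memory labeling,
# and the behavioral summary.

#' Read an event table
#'
#' Tab-separated with header columns `onset_ms`, `block`, `trial_id`,
#' `pair_id`.  `block` is `"encoding"` or `"recognition"`; `onset_ms` is the
#' stimulus onset in milliseconds from recording start.
#'
#' @param path path to the TSV file.
#' @return A validated `data.frame`.
#' @export
read_events <- function(path) {
  validate_events(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_events
#' @param events event table to validate.
#' @export
validate_events <- function(events) {
  need <- c("onset_ms", "block", "trial_id", "pair_id")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop_itfx("event table missing columns: ", paste(miss, collapse = ", "),
              class = "itfx_data_error")
  if (!all(events$block %in% c("encoding", "recognition")))
    stop_itfx("event block must be 'encoding' or 'recognition'",
              class = "itfx_data_error")
  for (b in unique(events$block)) {
    on <- events$onset_ms[events$block == b]
    if (any(diff(on) <= 0))
      stop_itfx("onsets must be strictly increasing within the ", b, " block",
                class = "itfx_data_error")
  }
  events
}

#' Read a behavior table
#'
#' Tab-separated with header columns `trial_id` (recognition trial), `truth`
#' (`"old"` for intact pairs, `"recombined"` for rearranged ones) and
#' `response` (the participant's judgement; empty/NA for omissions).
#'
#' @param path path to the TSV file.
#' @return A validated `data.frame`.
#' @export
read_behavior <- function(path) {
  validate_behavior(utils::read.delim(path, stringsAsFactors = FALSE,
                                      na.strings = c("NA", "")))
}

#' @rdname read_behavior
#' @param behavior behavior table to validate.
#' @export
validate_behavior <- function(behavior) {
  need <- c("trial_id", "truth", "response")
  miss <- setdiff(need, names(behavior))
  if (length(miss))
    stop_itfx("behavior table missing columns: ", paste(miss, collapse = ", "),
              class = "itfx_data_error")
  if (anyDuplicated(behavior$trial_id))
    stop_itfx("behavior table must have one row per recognition trial",
              class = "itfx_data_error")
  ok <- behavior$response %in% c("old", "recombined") | is.na(behavior$response)
  if (!all(ok))
    stop_itfx("responses must be 'old', 'recombined', or missing",
              class = "itfx_data_error")
  if (!all(behavior$truth %in% c("old", "recombined")))
    stop_itfx("truth must be 'old' or 'recombined'", class = "itfx_data_error")
  behavior
}

#' Label encoding trials by subsequent recognition accuracy
#'
#' An encoding trial is `successful` when its intact pair was later judged
#' "old" in the recognition block, `unsuccessful` when it was incorrectly
#' judged "recombined", and `unlabeled` when no intact-pair recognition trial
#' or no response exists for it.  Recombined recognition trials contribute no
#' label: only intact ("old") pairs map one-to-one onto encoding trials.
#'
#' @param events event table ([read_events()]).
#' @param behavior behavior table ([read_behavior()]).
#' @return A `data.frame` with one row per encoding trial: `trial_id`,
#'   `pair_id`, `label`.
#' @export
#' @examples
#' ev <- data.frame(onset_ms = c(0, 3000, 10000, 13000),
#'                  block = c("encoding", "encoding", "recognition", "recognition"),
#'                  trial_id = c("E1", "E2", "R1", "R2"),
#'                  pair_id = c("P1", "P2", "P1", "P2"))
#' bh <- data.frame(trial_id = c("R1", "R2"), truth = "old",
#'                  response = c("old", "recombined"))
#' label_epochs(ev, bh)
label_epochs <- function(events, behavior) {
  events <- validate_events(events)
  behavior <- validate_behavior(behavior)
  enc <- events[events$block == "encoding", , drop = FALSE]
  rec <- events[events$block == "recognition", , drop = FALSE]

  old <- behavior[behavior$truth == "old", , drop = FALSE]
  old <- merge(old, rec[, c("trial_id", "pair_id")], by = "trial_id")
  if (anyDuplicated(old$pair_id))
    stop_itfx("duplicate pair_id among intact recognition trials: ",
              paste(unique(old$pair_id[duplicated(old$pair_id)]), collapse = ", "),
              class = "itfx_data_error")

  idx <- match(enc$pair_id, old$pair_id)
  resp <- old$response[idx]
  label <- ifelse(is.na(idx) | is.na(resp), "unlabeled",
                  ifelse(resp == "old", "successful", "unsuccessful"))
  data.frame(trial_id = enc$trial_id, pair_id = enc$pair_id,
             label = label, stringsAsFactors = FALSE)
}

#' Summarize recognition performance
#'
#' @param behavior behavior table ([read_behavior()]).
#' @return A list with `overall_pct`, `hits_pct` (intact pairs judged "old"),
#'   `correct_rejections_pct` (recombined pairs judged "recombined"), and the
#'   underlying counts.  Percentages are on the 0-100 scale; missing responses
#'   count as incorrect.
#' @export
summarize_behavior <- function(behavior) {
  behavior <- validate_behavior(behavior)
  if (nrow(behavior) == 0L)
    stop_itfx("empty behavior table", class = "itfx_data_error")
  correct <- !is.na(behavior$response) & behavior$response == behavior$truth
  is_old <- behavior$truth == "old"
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  list(overall_pct = pct(sum(correct), nrow(behavior)),
       hits_pct = pct(sum(correct & is_old), sum(is_old)),
       correct_rejections_pct = pct(sum(correct & !is_old), sum(!is_old)),
       n_trials = nrow(behavior),
       n_old = sum(is_old),
       n_hits = sum(correct & is_old),
       n_correct_rejections = sum(correct & !is_old))
}
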