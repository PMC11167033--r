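#' Score recovered contact episodes against simulator ground truth
#'
#' A recovered episode matches a true episode when (i) their frame
#' intervals overlap by at least `min_overlap` of the shorter episode,
#' and (ii) during the overlap the recovered track lies within
#' `match_dist_px` of that true cell's positions for at least half of its
#' observed frames. Each recovered and each true episode is used at most
#' once (greedy by descending overlap). Matching intervals directly —
#' rather than assigning whole tracks to cells first — keeps the score
#' meaningful when tracks swap identity between neighboring cells outside
#' the episode under test; matching on the shorter length forgives
#' boundary jitter of a frame while merges, splits and misses still score
#' as unmatched. Precision, recall and F1 are computed over episodes.
#'
#' @param tracks Recovered tracks tibble (`track_id`, `frame`, `x_px`,
#'   `y_px`).
#' @param episodes Recovered episodes tibble (`track_id`, `start_frame`,
#'   `end_frame`).
#' @param truth_tracks Truth tracks tibble (`cell_id`, `frame`, `x_px`,
#'   `y_px`).
#' @param truth_episodes Truth episodes tibble (`cell_id`, `start_frame`,
#'   `end_frame`); filter to the minimal episode length under study before
#'   calling.
#' @param match_dist_px Maximal position error for a frame to count as
#'   lying on the true cell.
#' @param min_overlap Minimal temporal overlap as a fraction of the
#'   shorter episode.
#' @return A list: `precision`, `recall`, `f1`, `n_matched`, and a
#'   `matched` tibble pairing recovered and true episode durations.
#' @export
episode_recovery <- function(tracks, episodes, truth_tracks, truth_episodes,
                             match_dist_px = 4, min_overlap = 0.5) {
  n_rec <- nrow(episodes)
  n_true <- nrow(truth_episodes)
  empty_matched <- tibble(track_id = integer(0), cell_id = integer(0),
                          rec_n_frames = integer(0), true_n_frames = integer(0))
  finish <- function(tp, matched) {
    precision <- if (n_rec == 0L) 1 else tp / n_rec
    recall <- if (n_true == 0L) 1 else tp / n_true
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    list(precision = precision, recall = recall, f1 = f1,
         n_matched = tp, matched = matched)
  }
  if (n_rec == 0L || n_true == 0L) return(finish(0L, empty_matched))

  # position lookups keyed by (id, frame)
  tr_key <- paste(tracks$track_id, tracks$frame)
  tr_x <- setNames(tracks$x_px, tr_key)
  tr_y <- setNames(tracks$y_px, tr_key)
  tt_key <- paste(truth_tracks$cell_id, truth_tracks$frame)
  tt_x <- setNames(truth_tracks$x_px, tt_key)
  tt_y <- setNames(truth_tracks$y_px, tt_key)

  cand <- tidyr::expand_grid(.rec = seq_len(n_rec), .true = seq_len(n_true))
  rs <- episodes$start_frame[cand$.rec]
  re <- episodes$end_frame[cand$.rec]
  ts <- truth_episodes$start_frame[cand$.true]
  te <- truth_episodes$end_frame[cand$.true]
  inter <- pmin(re, te) - pmax(rs, ts) + 1L
  shorter <- pmin(re - rs, te - ts) + 1L
  cand$overlap <- pmax(inter, 0L) / shorter
  cand <- cand[cand$overlap >= min_overlap, , drop = FALSE]
  if (nrow(cand) == 0L) return(finish(0L, empty_matched))

  prox <- vapply(seq_len(nrow(cand)), function(r) {
    i <- cand$.rec[r]; j <- cand$.true[r]
    frames <- seq.int(max(episodes$start_frame[i],
                          truth_episodes$start_frame[j]),
                      min(episodes$end_frame[i], truth_episodes$end_frame[j]))
    kt <- paste(episodes$track_id[i], frames)
    kc <- paste(truth_episodes$cell_id[j], frames)
    rx <- tr_x[kt]; ry <- tr_y[kt]
    cx <- tt_x[kc]; cy <- tt_y[kc]
    seen <- !is.na(rx) & !is.na(cx)
    if (!any(seen)) return(0)
    mean((rx[seen] - cx[seen])^2 + (ry[seen] - cy[seen])^2 <= match_dist_px^2)
  }, numeric(1))
  cand <- cand[prox >= 0.5, , drop = FALSE]
  if (nrow(cand) == 0L) return(finish(0L, empty_matched))
  cand <- cand[order(-cand$overlap, cand$.rec, cand$.true), , drop = FALSE]

  used_rec <- logical(n_rec)
  used_true <- logical(n_true)
  matched <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand$.rec[r]; j <- cand$.true[r]
    if (used_rec[i] || used_true[j]) next
    used_rec[i] <- TRUE
    used_true[j] <- TRUE
    matched[[length(matched) + 1L]] <- tibble(
      track_id = episodes$track_id[i],
      cell_id = truth_episodes$cell_id[j],
      rec_n_frames = episodes$end_frame[i] - episodes$start_frame[i] + 1L,
      true_n_frames = truth_episodes$end_frame[j] -
        truth_episodes$start_frame[j] + 1L)
  }
  finish(sum(used_rec), bind_rows(matched))
}
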