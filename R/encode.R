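# ---------------------------------------------------------------------------
# Missing-response encoding: feed-forward fill plus a cumulative counting
# channel.
# ---------------------------------------------------------------------------

#' Encode missing responses as a cumulative counting channel
#'
#' Each sentinel entry is replaced by the most recent prior valid value in the
#' same channel (feed-forward fill); a leading run of sentinels, for which no
#' past value exists, is back-filled with the first subsequent valid value so
#' that the fill contributes no spurious increment.  Alongside, a counting
#' channel records the cumulative number of missing responses (summed over
#' channels by default) up to and including each week.  The fill does not
#' assert that the missing responses took those values — it makes the
#' increments of both the scores and the missing count well defined, which is
#' what the log-signature consumes.
#'
#' @param stream a [mood_stream()].
#' @param per_channel if `TRUE`, keep one cumulative count per channel instead
#'   of a single total (default `FALSE`, one extra channel).
#' @return An object of class `encoded_stream`: list with `filled` (W x 4, no
#'   sentinels), `miss_count` (length-W non-decreasing integer vector, or W x 4
#'   matrix when `per_channel`), `participant_id`, `diagnosis`, `weeks`.
#' @examples
#' s <- mood_stream("p1", cbind(c(3, -1, 2, 4), c(-1, 5, -1, 4),
#'                              c(50, 50, -1, 50), c(0, 0, 0, 0)))
#' encode_missing(s)$miss_count  # 2 3 5 5
#' @export
encode_missing <- function(stream, per_channel = FALSE) {
  stopifnot(inherits(stream, "mood_stream"))
  sc <- stream$scores
  sentinel <- stream$sentinel
  miss <- sc == sentinel
  filled <- sc
  for (ch in seq_len(ncol(sc))) {
    v <- sc[, ch]
    ok <- which(!miss[, ch])
    if (!length(ok))
      stop(sprintf("participant %s: channel %s is entirely missing",
                   stream$participant_id, colnames(sc)[ch]))
    if (any(miss[, ch])) {
      # feed-forward: index of nearest past valid entry
      idx <- findInterval(seq_len(nrow(sc)), ok)
      idx[idx == 0L] <- 1L  # leading gap: back-fill from first valid value
      filled[, ch] <- v[ok[idx]]
    }
  }
  miss_count <- if (per_channel) {
    apply(miss, 2L, cumsum)
  } else {
    cumsum(rowSums(miss))
  }
  structure(list(filled = filled,
                 miss_count = miss_count,
                 participant_id = stream$participant_id,
                 diagnosis = stream$diagnosis,
                 weeks = stream$weeks),
            class = "encoded_stream")
}
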