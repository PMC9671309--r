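# ---------------------------------------------------------------------------
# Missing-response-incorporated log-signature features (MRLSF).
# ---------------------------------------------------------------------------

#' Extract log-signature features from prepared windows
#'
#' One feature row per window: the level-`p` log-signature coordinates of the
#' window's five-channel path on the Lyndon basis.  For the study geometry
#' (five channels, level 3) this yields 55 features per window.
#'
#' @param windows list of `prepared_window` objects (see [cut_windows()]).
#' @param p truncation level (default 3).
#' @return An object of class `window_set`: list with `features` (N x F
#'   matrix, columns named `L<word>`), `window_participant` (length-N ids),
#'   `labels` (length-N diagnoses), `words` (list of integer word vectors)
#'   and `p`.
#' @export
extract_mrlsf <- function(windows, p = 3L) {
  if (!length(windows)) stop("no windows to extract features from")
  d <- ncol(windows[[1L]]$path)
  if (!all(vapply(windows, function(w) ncol(w$path) == d, logical(1))))
    stop("windows disagree on channel count")
  bp <- .logsig_basis(d, p)
  feats <- t(vapply(windows, function(w) logsig(w$path, p)$coords,
                    numeric(length(bp$basis$words))))
  colnames(feats) <- paste0("L", bp$basis$strings)
  structure(list(features = feats,
                 window_participant = vapply(windows, `[[`, character(1),
                                             "participant_id"),
                 labels = vapply(windows, `[[`, character(1), "diagnosis"),
                 words = bp$basis$words,
                 p = as.integer(p)),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("Window set: %d windows x %d features, %d participants\n",
              nrow(x$features), ncol(x$features),
              length(unique(x$window_participant))))
  invisible(x)
}
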