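#' Y-maze spontaneous alternation percentage
#'
#' An arm-entry sequence over the three maze arms is scanned with a sliding
#' window of three consecutive entries; a window visiting three distinct
#' arms is a spontaneous alternation. The score is
#' `alternations / (entries - 2) * 100`, the number of overlapping triplets
#' being exactly `entries - 2`.
#'
#' @param entries character (or factor) vector of arm labels; at most three
#'   distinct arms, no two consecutive entries identical (a re-entry into
#'   the current arm is not an entry), length >= 3.
#' @return the alternation percentage in \[0, 100\].
#' @export
spontaneous_alternation <- function(entries) {
  entries <- as.character(entries)
  n <- length(entries)
  if (n < 3) stop("need at least 3 arm entries")
  if (length(unique(entries)) > 3) stop("more than 3 distinct arm labels")
  if (any(entries[-1] == entries[-n])) {
    stop("consecutive duplicate entries are not valid arm entries")
  }
  wins <- vapply(seq_len(n - 2), function(i) {
    length(unique(entries[i:(i + 2)])) == 3
  }, logical(1))
  sum(wins) / (n - 2) * 100
}
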