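# A-priori operational definitions of the qualitative profile shapes used by
# the trend-signature checks. `x` are bin values / centers, `y` masses or
# means, ordered by x.

spearman <- function(x, y) suppressWarnings(cor(x, y, method = "spearman"))

# rises from the lowest bins to an interior mode, then falls
is_peaked <- function(x, y) {
  mode_idx <- which.max(y)
  mode_idx > 1 && mode_idx < length(y) &&
    y[mode_idx] > 1.2 * y[1] &&
    y[mode_idx] > 1.2 * y[length(y)]
}

# overall downward trend with no interior rise above the start
# (complement of is_peaked's 1.2x criterion, so the two are exclusive)
is_decaying <- function(x, y) {
  max(y) < 1.2 * y[1] && spearman(x, y) < -0.5
}

# initial decay followed by a later local maximum clearly above the valley
has_secondary_peak <- function(x, y) {
  valley <- which.min(y[seq_len(max(2, length(y) - 1))])
  if (valley >= length(y)) return(FALSE)
  tail_max <- max(y[(valley + 1):length(y)])
  valley > 1 && tail_max > 1.5 * y[valley]
}
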