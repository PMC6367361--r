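# Shared fixtures: small geometric masks and a truth-vs-segmentation label
# matcher used across the imaging tests.

disk_mask <- function(radius_px, pad = 5L) {
  n <- 2L * (radius_px + pad) + 1L
  c0 <- radius_px + pad + 1L
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - c0)^2 + (j - c0)^2 <= radius_px^2)
}

ellipse_mask <- function(a_px, b_px, pad = 5L) {
  n <- 2L * (max(a_px, b_px) + pad) + 1L
  c0 <- max(a_px, b_px) + pad + 1L
  outer(seq_len(n), seq_len(n),
        function(i, j) ((j - c0) / a_px)^2 + ((i - c0) / b_px)^2 <= 1)
}

# For each segmentation label, the truth label it overlaps most.
match_labels <- function(seg, truth) {
  seg <- unclass(seg)
  vapply(sort(unique(seg[seg > 0])), function(l) {
    tl <- truth[seg == l]
    tl <- tl[tl > 0]
    if (!length(tl)) return(NA_integer_)
    as.integer(names(sort(table(tl), decreasing = TRUE))[1L])
  }, integer(1))
}

# Brute-force per-label mean via an explicit pixel loop (oracle for the
# vectorised extraction).
brute_label_mean <- function(img, lab, label, valid = NULL) {
  tot <- 0; n <- 0L
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    if (lab[r, c] == label && (is.null(valid) || valid[r, c])) {
      tot <- tot + img[r, c]; n <- n + 1L
    }
  }
  tot / n
}
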