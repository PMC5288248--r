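# Brute-force oracles kept deliberately independent of the package internals:
# plain loops and sums, no calls into tss_curve()/max_tss().

oracle_tss_at_cutoff <- function(labels, probs, cutoff) {
  pred <- ifelse(probs > cutoff, 1, 0)
  tp <- sum(labels == 1 & pred == 1)
  fn <- sum(labels == 1 & pred == 0)
  fp <- sum(labels == 0 & pred == 1)
  tn <- sum(labels == 0 & pred == 0)
  tp / (tp + fn) + tn / (tn + fp) - 1
}

oracle_tss_curve <- function(labels, probs, cutoffs) {
  out <- numeric(length(cutoffs))
  for (i in seq_along(cutoffs)) {
    out[i] <- oracle_tss_at_cutoff(labels, probs, cutoffs[i])
  }
  out
}

oracle_max_tss <- function(labels, probs, cutoffs) {
  vals <- oracle_tss_curve(labels, probs, cutoffs)
  best <- which(vals == max(vals))[1]  # smallest cutoff on ties
  c(max = vals[best], cutoff = cutoffs[best])
}

# a random integer-valued confusion matrix with both classes present
random_confusion <- function() {
  repeat {
    cells <- sample(0:30, 4, replace = TRUE)
    if (cells[1] + cells[3] > 0 && cells[2] + cells[4] > 0) {
      return(confusion_matrix(tp = cells[1], fp = cells[2],
                              fn = cells[3], tn = cells[4]))
    }
  }
}
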