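# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: plain loops and direct formula evaluation only.

oracle_least_confident <- function(p) 1 - max(p)

oracle_margin <- function(p) {
  s <- sort(p, decreasing = TRUE)
  s[1] - s[2]
}

oracle_entropy <- function(p) {
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log(pi)
  h
}

oracle_vote_entropy <- function(votes) {
  C <- length(votes)
  h <- 0
  for (v in unique(votes)) {
    share <- sum(votes == v) / C
    h <- h - share * log(share)
  }
  h
}

# threshold-crossing peak counter for barcode traces
count_peaks <- function(x, threshold = 0.5) {
  above <- x > threshold
  sum(above[-1] & !above[-length(above)]) + as.integer(above[1])
}

# decode a barcode trace: first/last peaks are delimiters; inner peaks are
# assigned to the nearest of three evenly spaced slot centers between them
decode_barcode <- function(x, threshold = 0.5) {
  r <- rle(x > threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  centers <- (starts[r$values] + ends[r$values]) / 2
  if (length(centers) < 2) return(NA_character_)
  p0 <- centers[1]; p1 <- centers[length(centers)]
  slots <- p0 + (1:3) * (p1 - p0) / 4
  bits <- c("0", "0", "0")
  for (ctr in centers[-c(1, length(centers))]) {
    bits[which.min(abs(slots - ctr))] <- "1"
  }
  paste(bits, collapse = "")
}

# pairwise (Mann-Whitney) AUC: P(score_pos > score_neg) + 0.5 P(tie)
oracle_pairwise_auc <- function(scores, is_pos) {
  pos <- scores[is_pos]
  neg <- scores[!is_pos]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# central 99% binomial interval
binom99 <- function(n, p) {
  c(lo = qbinom(0.005, n, p), hi = qbinom(0.995, n, p))
}

# the full-data accuracy ceiling of a dataset
full_data_accuracy <- function(ds, seed = 1L) {
  clf <- rf_classifier()
  x <- rbind(ds$labeled$x, ds$pool$x)
  y <- factor(c(as.character(ds$labeled$y), as.character(ds$pool$y)),
              levels = levels(ds$labeled$y))
  m <- clf$fit(x, y, seed = seed)
  evaluate_model(clf, m, ds$test)$accuracy
}
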