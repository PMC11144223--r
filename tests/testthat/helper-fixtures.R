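# Shared fixtures: small, fast synthetic studies built in code.

# Short night with only the channels a test needs; low rates keep the
# suite fast while exercising every code path.
quick_params <- function(duration_h = 1, sleep_fraction = 0.8,
                         target_ahi = 15, seed = 1L,
                         channel_rates = c(abdominal = 10, thoracic = 10,
                                           airflow = 10, spo2 = 1, ecg = 125),
                         ...) {
  sim_params(duration_h = duration_h, sleep_fraction = sleep_fraction,
             target_ahi = target_ahi, seed = seed,
             channel_rates = channel_rates, ...)
}

# Brute-force threshold scan used as the independent oracle for
# select_threshold: evaluates |precision - recall| at every candidate.
brute_force_threshold <- function(probs, labels) {
  candidates <- sort(unique(c(0, 1, probs)))
  best <- NA_real_; best_gap <- Inf; best_prec <- -Inf
  for (th in candidates) {
    tp <- sum(probs >= th & labels == 1)
    fp <- sum(probs >= th & labels == 0)
    if (tp == 0) next
    prec <- tp / (tp + fp)
    rec <- tp / sum(labels == 1)
    gap <- abs(prec - rec)
    better <- gap < best_gap - 1e-12 ||
      (abs(gap - best_gap) <= 1e-12 &&
         (prec > best_prec + 1e-12 ||
            (abs(prec - best_prec) <= 1e-12 && th > best)))
    if (better) {
      best <- th; best_gap <- gap; best_prec <- prec
    }
  }
  best
}

# O(n^2) pairwise AUROC oracle: P(score+ > score-) + 0.5 P(equal).
pairwise_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
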