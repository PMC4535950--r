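# Independent brute-force oracles, kept deliberately naive so they share no
# code path with the implementation they check.

# Pairwise agreement by explicit enumeration of all unordered expert pairs.
oracle_pwa_item <- function(scores) {
  r <- length(scores)
  agree <- 0L
  for (k in seq_len(r - 1L))
    for (kk in (k + 1L):r)
      if (scores[k] == scores[kk]) agree <- agree + 1L
  agree / (r * (r - 1L) / 2L)
}

# Cluster identification by literal enumeration of every candidate interval
# and step-by-step greedy selection.
oracle_clusters <- function(scores, v = 3L, p = 0.5, q = 10L) {
  cand <- data.frame(low = integer(0), high = integer(0), count = integer(0))
  for (a in 1:q)
    for (b in a:min(q, a + v - 1L))
      cand <- rbind(cand, data.frame(
        low = a, high = b, count = sum(scores >= a & scores <= b)))
  cand <- cand[order(-cand$count, -(cand$high - cand$low), cand$low), ]
  r_mode <- cand$count[1L]
  chosen <- cand[0L, ]
  for (i in seq_len(nrow(cand))) {
    row <- cand[i, ]
    if (row$count + 1e-9 < p * r_mode || row$count == 0L) break
    overlaps <- any(row$low <= chosen$high & row$high >= chosen$low)
    if (!overlaps) chosen <- rbind(chosen, row)
  }
  chosen <- chosen[order(chosen$low), ]
  chosen$mean <- vapply(seq_len(nrow(chosen)), function(i)
    mean(scores[scores >= chosen$low[i] & scores <= chosen$high[i]]),
    numeric(1))
  rownames(chosen) <- NULL
  list(table = chosen, r_mode = r_mode)
}

random_matrix <- function(r, n, q = 10L) {
  rating_matrix(matrix(sample.int(q, r * n, replace = TRUE), nrow = r),
                scale_max = q)
}
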