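# Brute-force reference implementations used as independent oracles,
# plus small fixture builders. Deliberately simple, loop-based code.

# cluster pooled per-lead peaks by chaining within `tol` (one peak per
# lead per cluster) and return per-cluster member indices and supports
oracle_clusters <- function(per_lead_idx, tol) {
  pool <- data.frame(idx = integer(0), lead = integer(0))
  for (l in seq_along(per_lead_idx)) {
    if (length(per_lead_idx[[l]]))
      pool <- rbind(pool, data.frame(idx = per_lead_idx[[l]], lead = l))
  }
  if (!nrow(pool)) return(list())
  pool <- pool[order(pool$idx, pool$lead), ]
  clusters <- list()
  cur_idx <- pool$idx[1]; cur_leads <- pool$lead[1]
  members <- pool$idx[1]
  if (nrow(pool) > 1) for (k in 2:nrow(pool)) {
    if (pool$idx[k] - cur_idx <= tol && !(pool$lead[k] %in% cur_leads)) {
      members <- c(members, pool$idx[k])
      cur_leads <- c(cur_leads, pool$lead[k])
    } else {
      clusters[[length(clusters) + 1]] <- list(members = members,
                                               support = length(cur_leads))
      members <- pool$idx[k]; cur_leads <- pool$lead[k]
    }
    cur_idx <- pool$idx[k]
  }
  clusters[[length(clusters) + 1]] <- list(members = members,
                                           support = length(cur_leads))
  clusters
}

oracle_fused_indices <- function(per_lead_idx, tol, need) {
  cl <- oracle_clusters(per_lead_idx, tol)
  out <- integer(0)
  for (c_ in cl) {
    if (c_$support >= need)
      out <- c(out, as.integer(floor(stats::median(c_$members))))
  }
  unique(out)
}

# refractory pruning: accept peaks in decreasing amplitude (earliest
# first on ties) if far enough from every accepted peak
oracle_refractory <- function(idx, amp, rf) {
  remaining <- order(-amp, idx)
  kept <- integer(0)
  for (k in remaining) {
    ok <- TRUE
    for (j in kept) if (abs(idx[k] - idx[j]) < rf) ok <- FALSE
    if (ok) kept <- c(kept, k)
  }
  sort(idx[kept])
}

# maximum-cardinality one-to-one matching between detections and
# references within tol, by exhaustive recursion (small inputs only)
oracle_max_matching <- function(d, r, tol) {
  rec <- function(i, used) {
    if (i > length(d)) return(0L)
    best <- rec(i + 1L, used)           # leave detection i unmatched
    for (j in seq_along(r)) {
      if (!used[j] && abs(d[i] - r[j]) <= tol) {
        used[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  rec(1L, logical(length(r)))
}

oracle_true_negatives <- function(refs, fps) {
  if (length(refs) < 2) return(0L)
  tn <- 0L
  for (g in seq_len(length(refs) - 1L)) {
    inside <- any(fps > refs[g] & fps < refs[g + 1L])
    if (!inside) tn <- tn + 1L
  }
  tn
}

# random per-lead peak configurations with physiologic-ish spacing
random_peak_config <- function(n_leads = 3, n_beats = 8, fs = 200,
                               drop_p = 0.3, jitter = 1) {
  beats <- sort(sample(seq(100, 20000, by = 120), n_beats))
  lapply(seq_len(n_leads), function(l) {
    keep <- stats::runif(n_beats) > drop_p
    idx <- beats[keep] + sample(-jitter:jitter, sum(keep), replace = TRUE)
    sort(unique(idx[idx >= 0]))
  })
}

clean_rec <- function(duration_s = 60, seed = 5, ...) {
  synth_ecg(synth_config(duration_s = duration_s, seed = seed, ...))
}
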