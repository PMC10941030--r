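# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: plain loops and textbook definitions only.

# Textbook step-down Holm adjustment.
brute_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running_max <- 0
  for (k in seq_len(m)) {
    val <- min(1, (m - k + 1) * p[ord[k]])
    running_max <- max(running_max, val)
    adj[ord[k]] <- running_max
  }
  adj
}

# Pairwise AUC by explicit pair enumeration.
brute_auc <- function(scores, labels) {
  y <- as.logical(labels)
  pos <- scores[y]
  neg <- scores[!y]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Exhaustive cardinality matching over all subset pairs (bitmask search).
# Returns the maximum feasible per-group size and one witness.
brute_cardinality <- function(X, y, tolerance) {
  idx_a <- which(y == 1)
  idx_b <- which(y == 0)
  check <- function(sa, sb) {
    for (j in seq_len(ncol(X))) {
      va <- X[sa, j]; vb <- X[sb, j]
      s <- soleplay::smd(c(va, vb), rep(c("A", "B"), c(length(va), length(vb))))
      if (s > tolerance) return(FALSE)
    }
    TRUE
  }
  best_k <- 0
  for (ma in seq_len(2^length(idx_a) - 1)) {
    sa <- idx_a[bitwAnd(ma, 2^(seq_along(idx_a) - 1)) > 0]
    for (mb in seq_len(2^length(idx_b) - 1)) {
      sb <- idx_b[bitwAnd(mb, 2^(seq_along(idx_b) - 1)) > 0]
      if (length(sa) != length(sb) || length(sa) <= best_k) next
      if (check(sa, sb)) best_k <- length(sa)
    }
  }
  best_k
}

# Brute-force greedy correlation pruning re-applied from the rule text.
brute_prune <- function(X, threshold) {
  keep <- seq_len(ncol(X))
  cm <- abs(stats::cor(X))
  diag(cm) <- 0
  repeat {
    sub <- cm[keep, keep, drop = FALSE]
    if (all(sub <= threshold)) break
    w <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    i <- keep[w[1]]; j <- keep[w[2]]
    mi <- mean(cm[i, keep]); mj <- mean(cm[j, keep])
    drop <- if (mi > mj) i else if (mj > mi) j else max(i, j)
    keep <- setdiff(keep, drop)
  }
  keep
}

# Manually constructed task trace for feature-extraction tests.
manual_trace <- function(game = "AC", task_index = 1, t, value,
                         sensor = "L4", outcome = "success",
                         response_time = NA_real_, aux = list()) {
  list(game = game, task_index = task_index, controlling_foot = "left",
       outcome = outcome, response_time = response_time, restarts = 0L,
       samples = data.frame(t = t, sensor_id = sensor, value = value),
       aux = aux)
}

zero_impairment_traits <- function() {
  list(reaction_latency_mean = 0, reaction_latency_sd = 0,
       pressure_noise_sd = 0, sensation_threshold = 0,
       decision_error_prob = 0, fatigue_slope = 0)
}

fast_config <- function(...) game_config(sampling_rate = 50, ...)

# Tiny toy cohort for matching tests: two groups with one skewed covariate.
toy_match_cohort <- function(ages_a, ages_b) {
  tibble::tibble(
    id = sprintf("T%02d", seq_len(length(ages_a) + length(ages_b))),
    grp = rep(c(1, 0), c(length(ages_a), length(ages_b))),
    age = c(ages_a, ages_b)
  )
}
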