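# Exhaustive oracles for larger point sets: the loop over processing
# objects stays explicit, the per-target distance scan is vectorized.
# Independent of the package's outer()-matrix implementation.
oracle_counts_big <- function(proc, targ, radius) {
  same <- paste(targ$kind, targ$object_id)
  out <- integer(nrow(proc))
  for (i in seq_len(nrow(proc))) {
    d <- sqrt((targ$x - proc$x[i])^2 + (targ$y - proc$y[i])^2)
    d[same == paste(proc$kind[i], proc$object_id[i])] <- Inf
    out[i] <- sum(d <= radius)
  }
  out
}

oracle_nearest_big <- function(proc, targ) {
  same <- paste(targ$kind, targ$object_id)
  ord <- order(targ$object_id)
  targ <- targ[ord, , drop = FALSE]
  same <- same[ord]
  dist <- rep(NA_real_, nrow(proc))
  id <- rep(NA_integer_, nrow(proc))
  for (i in seq_len(nrow(proc))) {
    d <- sqrt((targ$x - proc$x[i])^2 + (targ$y - proc$y[i])^2)
    d[same == paste(proc$kind[i], proc$object_id[i])] <- Inf
    j <- which.min(d)
    if (is.finite(d[j])) {
      dist[i] <- d[j]
      id[i] <- targ$object_id[j]
    }
  }
  data.frame(distance = dist, target_id = id)
}
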