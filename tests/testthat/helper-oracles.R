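## Independent oracles and small utilities shared across the test files.
## Every oracle is a deliberately naive implementation (brute force or
## closed form) kept separate from the package's code paths.

## Brute-force maximal-run burst enumerator: for every candidate start
## index, extend while the ISI condition holds, keep runs that are maximal
## on both sides and long enough.
brute_force_bursts <- function(times, min_spikes = 5, max_isi = 0.1) {
  n <- length(times)
  out <- data.frame(start = numeric(), end = numeric(),
                    n_spikes = integer())
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && times[j + 1] - times[j] <= max_isi) j <- j + 1L
    if (j - i + 1L >= min_spikes) {
      out <- rbind(out, data.frame(start = times[i], end = times[j],
                                   n_spikes = j - i + 1L))
    }
    i <- j + 1L
  }
  out
}

## Random spike train mixing a Poisson background with clustered events.
random_mixed_train <- function(seed, duration = 60) {
  set.seed(seed)
  n_bg <- rpois(1, runif(1, 0, 3) * duration)
  tt <- runif(n_bg, 0, duration)
  n_cl <- rpois(1, duration / 20)
  for (k in seq_len(n_cl)) {
    m <- sample(2:12, 1)
    tt <- c(tt, runif(1, 0, duration) + cumsum(runif(m, 0.01, 0.15)))
  }
  sort(tt[tt <= duration])
}

## Event matching between detected and true spike times with a +/- tol
## window (each truth spike may be claimed once).
match_events <- function(det, truth, tol = 0.002) {
  if (length(truth) == 0) {
    return(list(recall = NA_real_, precision = if (length(det)) 0 else
      NA_real_, tp = 0))
  }
  if (length(det) == 0) return(list(recall = 0, precision = NA_real_,
                                    tp = 0))
  hit_truth <- vapply(truth, function(t) any(abs(det - t) <= tol),
                      logical(1))
  hit_det <- vapply(det, function(t) any(abs(truth - t) <= tol), logical(1))
  list(recall = mean(hit_truth), precision = mean(hit_det),
       tp = sum(hit_truth))
}

## Independent per-soma phenotype computation from a stored ground-truth
## graph: recursive traversal over the segment table (the generator's own
## bookkeeping is incremental, so this is a genuinely different route).
traverse_truth_phenotypes <- function(truth) {
  v <- truth$vertices; sg <- truth$segments
  out <- data.frame(soma = truth$somas$soma, max_neurite_length = 0,
                    total_neurite_length = 0, n_extremities = 0L,
                    n_roots = 0L, n_segments = 0L, n_nodes = 0L)
  deepest <- function(vid) {
    kids <- sg[sg$from == vid, , drop = FALSE]
    if (nrow(kids) == 0) return(0)
    max(vapply(seq_len(nrow(kids)), function(i) {
      kids$length[i] + deepest(kids$to[i])
    }, numeric(1)))
  }
  for (i in seq_len(nrow(out))) {
    s <- out$soma[i]
    vs <- v[v$soma == s, , drop = FALSE]
    ss <- sg[sg$soma == s, , drop = FALSE]
    roots <- vs$id[vs$type == "root"]
    out$n_roots[i] <- length(roots)
    out$n_nodes[i] <- sum(vs$type == "node")
    out$n_extremities[i] <- sum(vs$type == "extremity")
    out$n_segments[i] <- nrow(ss)
    out$total_neurite_length[i] <- sum(ss$length)
    if (length(roots) > 0) {
      out$max_neurite_length[i] <- max(vapply(roots, deepest, numeric(1)))
    }
  }
  out
}

## Map ground-truth somas to segmentation labels by nearest centre.
map_gt_to_cells <- function(truth, cells) {
  vapply(seq_len(nrow(truth$somas)), function(i) {
    d <- sqrt((cells$x - truth$somas$x[i])^2 +
                (cells$y - truth$somas$y[i])^2)
    cells$cell[which.min(d)]
  }, numeric(1))
}

count_cols <- c("n_extremities", "n_roots", "n_segments", "n_nodes")
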