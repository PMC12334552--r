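# Independent brute-force oracles used to pin down the fast implementations.

# AUC by explicit pair counting over all (positive, negative) pairs
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# max TSS by scanning every candidate threshold explicitly
brute_max_tss <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- -Inf
  best_th <- NA
  for (th in cand) {
    pred <- scores >= th
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    t <- sens + spec - 1
    if (t > best + 1e-12) {
      best <- t
      best_th <- th
    }
  }
  list(threshold = best_th, tss = best)
}

# optimal 1-D partition by exhaustive enumeration of all contiguous splits;
# ties resolved toward the lexicographically smallest split positions
brute_jenks_classes <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  if (k == 1) return(rep(1L, n))
  splits <- utils::combn(seq_len(n - 1), k - 1)
  best_cost <- Inf
  best <- NULL
  for (ci in seq_len(ncol(splits))) {
    b <- c(0, splits[, ci], n)
    cost <- sum(vapply(seq_len(k), function(m) {
      seg <- v[(b[m] + 1):b[m + 1]]
      sum((seg - mean(seg))^2)
    }, numeric(1)))
    if (cost < best_cost - 1e-12) {
      best_cost <- cost
      best <- splits[, ci]
    }
  }
  rep(seq_len(k), times = diff(c(0, best, n)))
}

# a small landscape + virtual species + training set, shared by sdm tests
make_tiny_study <- function(seed = 42, n = 40, breadth = 0.35,
                            n_presences = 120, n_pa = 300) {
  grid <- grid_spec(n, n, 2.5 / 60, lat_top = -15, lon_left = 44)
  land <- make_landscape(grid, 2, autocorrelation_range_cells = 3,
                         seed = seed, layer_names = c("bio12", "bio15"))
  vs <- virtual_species_spec("tiny", c(bio12 = 0, bio15 = 0),
                             c(bio12 = breadth, bio15 = breadth))
  truth <- true_suitability(vs, land)
  occ <- sample_presences(truth, n_presences, seed = seed + 1)
  pa <- build_pa_set(occ, land, n_pa = n_pa, seed = seed + 2)
  list(grid = grid, land = land, truth = truth, occ = occ, pa = pa)
}

# linearly separable 1-feature training set
make_separable <- function(n_per_class = 30) {
  x <- matrix(c(stats::runif(n_per_class, 1, 2),
                stats::runif(n_per_class, -2, -1)), ncol = 1,
              dimnames = list(NULL, "bio12"))
  list(x = x, y = c(rep(1L, n_per_class), rep(0L, n_per_class)))
}

random_mask_pair <- function(grid) {
  n <- grid$n_rows * grid$n_cols
  list(cur = binary_habitat_map("s", "current", stats::runif(n) < 0.4, grid),
       fut = binary_habitat_map("s", "future", stats::runif(n) < 0.4, grid))
}
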