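# Independent oracles and small constructors used across the suite.

# all permutations of 1..n (recursive; n <= 7 in practice)
perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# minimum-total-distance one-to-one assignment by exhaustive enumeration;
# pairs farther than max_disp are forbidden
brute_force_assignment <- function(det_a, det_b, max_disp) {
  na <- nrow(det_a); nb <- nrow(det_b)
  stopifnot(na == nb)
  dmat <- outer(seq_len(na), seq_len(nb), function(i, j)
    sqrt((det_a$x_um[i] - det_b$x_um[j])^2 + (det_a$y_um[i] - det_b$y_um[j])^2))
  best <- NULL; best_cost <- Inf
  for (r in seq_len(nrow(perms(na)))) {
    p <- perms(na)[r, ]
    d <- dmat[cbind(seq_len(na), p)]
    if (any(d > max_disp)) next
    cost <- sum(d)
    if (cost < best_cost) { best_cost <- cost; best <- p }
  }
  unname(best)
}

# exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# choose(n_a + n_b, n_a) labelings (no ties assumed); mirrors the standard
# two-sided convention p = min(1, 2 * min(P(W <= w), P(W >= w)))
wilcox_enum_p <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  pooled <- rank(c(a, b))
  w_obs <- sum(pooled[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  labelings <- utils::combn(n_a + n_b, n_a)
  ranks <- seq_len(n_a + n_b)
  w_all <- apply(labelings, 2, function(idx)
    sum(ranks[idx]) - n_a * (n_a + 1) / 2)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# detection data frame from coordinate vectors
make_dets <- function(x, y, frame = 0L) {
  data.frame(det = seq_along(x), x_um = x, y_um = y,
             area_um2 = 3, orientation_deg = 0, length_um = 5,
             pa_x = x - 2.5, pa_y = y, pb_x = x + 2.5, pb_y = y,
             degenerate = FALSE, frame = frame,
             pa_int = NA_real_, pb_int = NA_real_)
}

# single-track data frame from centroid series
make_track <- function(x, y, frame_interval = 15, track_id = 1L) {
  n <- length(x)
  data.frame(track_id = track_id, frame = seq_len(n) - 1L,
             time_s = (seq_len(n) - 1L) * frame_interval,
             x_um = x, y_um = y)
}

# capsule area in um^2: rectangle plus end caps (tip-to-tip length L, width w)
capsule_area <- function(L, w) (L - w) * w + pi * (w / 2)^2
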