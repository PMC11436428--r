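# Independent brute-force oracles and small fixture builders. These stay
# deliberately loop-based and naive: they re-derive every quantity from its
# definition rather than reusing package internals.

rand_volume <- function(dim = c(16, 16, 16), spacing = c(2, 2, 2),
                        lo = 0, hi = 8) {
  pet_volume(array(runif(prod(dim), lo, hi), dim), spacing, unit = "SUV")
}

rand_voi <- function(dim = c(16, 16, 16), frac = 0.2,
                     component = "pump") {
  n <- max(1L, round(frac * prod(dim)))
  voi_mask(sample.int(prod(dim), n), component, dim)
}

# definition-level segmentation: loop over the VOI, collect suprathreshold
# voxels, then apply the MTV/TLG definitions
brute_segment <- function(vol, voi, thr) {
  vv <- prod(vol$spacing) / 1000
  kept <- numeric(0)
  for (idx in voi$indices) {
    v <- vol$values[idx]
    if (v >= thr) kept <- c(kept, v)
  }
  n <- length(kept)
  mtv <- n * vv
  m <- if (n > 0) mean(kept) else 0
  list(n_voxels = n, mtv = mtv, suv_mean_seg = m, tlg = mtv * m)
}

brute_suv_stats <- function(vol, voi) {
  mx <- -Inf; s <- 0
  for (idx in voi$indices) {
    v <- vol$values[idx]
    if (v > mx) mx <- v
    s <- s + v
  }
  list(suv_max = mx, suv_mean = s / length(voi$indices))
}

# pairwise rank form of the AUC
brute_auc <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  s <- 0
  for (a in x) for (b in y) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(x) * length(y))
}

brute_confusion <- function(scores, labels, cutoff) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(scores)) {
    pos <- scores[i] >= cutoff
    if (labels[i] == 1) { if (pos) tp <- tp + 1 else fn <- fn + 1 }
    else { if (pos) fp <- fp + 1 else tn <- tn + 1 }
  }
  list(sens = tp / (tp + fn), spec = tn / (tn + fp))
}

# sens/spec at a cutoff by direct counting (for ROC operating points)
brute_operating_point <- function(scores, labels, cutoff) {
  brute_confusion(scores, labels, cutoff)
}

# a small phantom spec whose default geometry fits a 64^3 grid at 3 mm
small_phantom_spec <- function(...) {
  phantom_spec(shape = c(64, 64, 64), spacing = c(3, 3, 3), ...)
}

# tiny uniform-cube fixture: a box VOI of known size in a uniform background
uniform_cube_volume <- function(dim = c(12, 12, 12), spacing = c(2, 2, 2),
                                cube = 5:9, inside = 4, outside = 1) {
  vals <- array(outside, dim)
  vals[cube, cube, cube] <- inside
  vol <- pet_volume(vals, spacing, unit = "SUV")
  mask <- array(FALSE, dim)
  mask[cube, cube, cube] <- TRUE
  list(vol = vol, voi = voi_mask(which(mask), "pump", dim))
}
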