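# Shared fixtures: tiny phantoms, desk-scale configs, and pure-R reference
# implementations used as independent oracles.

tiny_phantom_spec <- function(...) {
  phantom_spec(shape = c(8L, 16L, 16L), spacing = c(5, 0.741, 0.741),
               semi_axes_range = list(z = c(1.2, 1.8), y = c(2.5, 4.5),
                                      x = c(2.5, 4.5)), ...)
}

tiny_train_config <- function(...) {
  desk_train_config(preprocess = preprocess_config(
    patch_shape = c(8L, 16L, 16L), target_spacing = c(5, 0.741, 0.741)), ...)
}

# Random blob mask: thresholded distance to a few random seed points.
random_mask <- function(dm, n_seeds = 2, radius = 2.5) {
  m <- array(0L, dm)
  for (s in seq_len(n_seeds)) {
    ctr <- sapply(dm, function(n) runif(1, 1, n))
    zz <- slice.index(m, 1); yy <- slice.index(m, 2); xx <- slice.index(m, 3)
    d2 <- (zz - ctr[1])^2 + (yy - ctr[2])^2 + (xx - ctr[3])^2
    m[d2 <= radius^2] <- 1L
  }
  m
}

# Pure-R brute-force surface extraction (face adjacency, outside counts as
# background) independent of the compiled implementation.
r_surface_points <- function(m) {
  dm <- dim(m)
  idx <- which(m == 1, arr.ind = TRUE)
  keep <- apply(idx, 1, function(v) {
    for (d in 1:3) for (s in c(-1L, 1L)) {
      nb <- v; nb[d] <- nb[d] + s
      if (nb[d] < 1 || nb[d] > dm[d]) return(TRUE)
      if (m[nb[1], nb[2], nb[3]] == 0) return(TRUE)
    }
    FALSE
  })
  idx[keep, , drop = FALSE]
}

# All-pairs directed distances between physical point sets.
r_directed_dists <- function(A, B) {
  apply(A, 1, function(a)
    sqrt(min(colSums((t(B) - a)^2))))
}

r_surface_metrics <- function(pred, gt, spacing) {
  A <- sweep(matrix(as.numeric(r_surface_points(pred) - 1), ncol = 3), 2,
             spacing, "*")
  B <- sweep(matrix(as.numeric(r_surface_points(gt) - 1), ncol = 3), 2,
             spacing, "*")
  dab <- r_directed_dists(A, B)
  dba <- r_directed_dists(B, A)
  list(asd = 0.5 * (mean(dab) + mean(dba)),
       hd95 = max(quantile(dab, 0.95, type = 7, names = FALSE),
                  quantile(dba, 0.95, type = 7, names = FALSE)),
       hd = max(max(dab), max(dba)))
}
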