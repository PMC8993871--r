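# Fixture builders and independent brute-force oracles. Everything is
# generated in code; oracles deliberately use scalar loops / enumeration so
# they share no code path with the implementation they check.

# circle/annulus masks by lattice-point inclusion (pixel centers)
annulus_mask <- function(nr, nc, cy, cx, r_in, r_out, ps = 0.1) {
  lab <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    d2 <- (i - cy)^2 + (j - cx)^2
    if (d2 <= r_in^2) lab[i, j] <- MASK_AXON
    else if (d2 <= r_out^2) lab[i, j] <- MASK_MYELIN
  }
  semantic_mask(lab, ps)
}

disk_pixels <- function(r) {
  # lattice points with x^2 + y^2 <= r^2, centered at the origin
  n <- 0L
  for (x in -r:r) for (y in -r:r) if (x * x + y * y <= r * r) n <- n + 1L
  n
}

random_mask <- function(nr, nc, ps = 0.1,
                        probs = c(0.6, 0.25, 0.15)) {
  semantic_mask(matrix(sample(0:2, nr * nc, replace = TRUE, prob = probs),
                       nr, nc), ps)
}

# scalar-loop bilinear sampler, same pixel-center alignment convention
oracle_bilinear <- function(m, out_nrow, out_ncol) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, out_nrow, out_ncol)
  for (i in seq_len(out_nrow)) for (j in seq_len(out_ncol)) {
    r <- min(max((i - 0.5) * nr / out_nrow - 0.5, 0), nr - 1)
    c_ <- min(max((j - 0.5) * nc / out_ncol - 0.5, 0), nc - 1)
    r0 <- floor(r); c0 <- floor(c_)
    r1 <- min(r0 + 1, nr - 1); c1 <- min(c0 + 1, nc - 1)
    fr <- r - r0; fc <- c_ - c0
    out[i, j] <- m[r0 + 1, c0 + 1] * (1 - fr) * (1 - fc) +
      m[r1 + 1, c0 + 1] * fr * (1 - fc) +
      m[r0 + 1, c1 + 1] * (1 - fr) * fc +
      m[r1 + 1, c1 + 1] * fr * fc
  }
  out
}

# exhaustive per-pixel set enumeration of the five pixelwise metrics
oracle_pixel_metrics <- function(S, T_, cls) {
  s_set <- character(); t_set <- character()
  for (i in seq_len(nrow(S$labels))) for (j in seq_len(ncol(S$labels))) {
    key <- paste(i, j)
    if (S$labels[i, j] == cls) s_set <- c(s_set, key)
    if (T_$labels[i, j] == cls) t_set <- c(t_set, key)
  }
  ni <- length(intersect(s_set, t_set))
  nu <- length(union(s_set, t_set))
  ns <- length(s_set); nt <- length(t_set)
  list(overlap = if (nt > 0) ni / nt else NA_real_,
       jaccard = if (nu > 0) ni / nu else 1,
       dice = if (ns + nt > 0) 2 * ni / (ns + nt) else 1,
       fne = if (nt > 0) length(setdiff(t_set, s_set)) / nt else NA_real_,
       fpe = if (ns > 0) length(setdiff(s_set, t_set)) / ns else NA_real_)
}

# exhaustive nearest-axon-component search for every myelin pixel
oracle_nearest_axon <- function(mask, axon_labels) {
  k <- max(axon_labels)
  comp_px <- lapply(seq_len(k), function(id)
    which(axon_labels == id, arr.ind = TRUE))
  out <- matrix(0L, nrow(mask$labels), ncol(mask$labels))
  my <- which(mask$labels == MASK_MYELIN, arr.ind = TRUE)
  for (m in seq_len(nrow(my))) {
    best <- Inf; bid <- 0L
    for (id in seq_len(k)) {
      d <- min(sqrt((comp_px[[id]][, 1] - my[m, 1])^2 +
                    (comp_px[[id]][, 2] - my[m, 2])^2))
      if (d < best) { best <- d; bid <- id }   # ties keep lower id
    }
    out[my[m, 1], my[m, 2]] <- bid
  }
  out
}

# brute-force maximum-cardinality one-to-one assignment over candidate pairs
oracle_max_matching <- function(pairs) {
  if (nrow(pairs) == 0L) return(0L)
  recurse <- function(pred_ids, used_t) {
    if (length(pred_ids) == 0L) return(0L)
    p <- pred_ids[1]
    best <- recurse(pred_ids[-1], used_t)  # leave p unmatched
    for (t in pairs$truth_id[pairs$pred_id == p]) {
      if (t %in% used_t) next
      best <- max(best, 1L + recurse(pred_ids[-1], c(used_t, t)))
    }
    best
  }
  recurse(unique(pairs$pred_id), integer())
}

# random small fiber sets (axon rectangles, possibly merging) for matching
random_instance_set <- function(n_blobs, nr = 24, nc = 24, ps = 0.1) {
  lab <- matrix(0L, nr, nc)
  for (i in seq_len(n_blobs)) {
    h <- sample(2:5, 1); w <- sample(2:5, 1)
    r <- sample(seq_len(nr - h), 1); c_ <- sample(seq_len(nc - w), 1)
    lab[r:(r + h - 1), c_:(c_ + w - 1)] <- MASK_AXON
  }
  build_fiber_set(semantic_mask(lab, ps), min_axon_px = 1L)
}

# display rounding, half away from zero
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

mask_as_image <- function(mask) intensity_image(mask$labels + 0, mask$pixel_size)
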