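# Brute-force oracles, independent of the package implementation.

# Exhaustive HSV threshold + breadth-first connected-component labelling,
# returning the intensity-weighted centroid of the largest red component.
oracle_centroid <- function(frame, hue_lo = 0.92, hue_hi = 0.08,
                            s_min = 0.4, v_min = 0.2, min_area = 5) {
  h <- dim(frame)[1]; w <- dim(frame)[2]
  mask <- matrix(FALSE, h, w)
  val <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (cc in seq_len(w)) {
      hsv <- grDevices::rgb2hsv(matrix(frame[r, cc, 1:3], ncol = 1),
                                maxColorValue = 1)
      val[r, cc] <- hsv[3, 1]
      in_hue <- if (hue_lo > hue_hi) hsv[1, 1] >= hue_lo || hsv[1, 1] <= hue_hi
                else hsv[1, 1] >= hue_lo && hsv[1, 1] <= hue_hi
      mask[r, cc] <- in_hue && hsv[2, 1] >= s_min && hsv[3, 1] >= v_min
    }
  }
  if (!any(mask)) return(NULL)
  lab <- matrix(0L, h, w)
  nextlab <- 0L
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    if (mask[r, cc] && lab[r, cc] == 0L) {
      nextlab <- nextlab + 1L
      queue <- list(c(r, cc)); lab[r, cc] <- nextlab
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (dr in -1:1) for (dc in -1:1) {
          rr <- p[1] + dr; c2 <- p[2] + dc
          if (rr >= 1 && rr <= h && c2 >= 1 && c2 <= w &&
              mask[rr, c2] && lab[rr, c2] == 0L) {
            lab[rr, c2] <- nextlab
            queue[[length(queue) + 1]] <- c(rr, c2)
          }
        }
      }
    }
  }
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  if (sizes[big] < min_area) return(NULL)
  idx <- which(lab == big, arr.ind = TRUE)
  wt <- val[lab == big]
  list(x = sum(idx[, 2] * wt) / sum(wt), y = sum(idx[, 1] * wt) / sum(wt),
       area = sizes[big])
}

# Render a soft-edged disc directly into an RGB array (red channel only).
disc_frame <- function(cx, cy, radius = 6, width = 64, height = 48) {
  img <- array(0, dim = c(height, width, 3))
  for (r in seq_len(height)) for (cc in seq_len(width)) {
    dist <- sqrt((cc - cx)^2 + (r - cy)^2)
    img[r, cc, 1] <- min(max(radius + 0.5 - dist, 0), 1)
  }
  img
}

# Closed-form logarithmic decrement of the generator's waveform.
true_decrement <- function(zeta) 2 * pi * zeta / sqrt(1 - zeta^2)

# Shared short synthetic video for tracking/batch tests.
make_test_video <- function(dir, f_d = 20, zeta = 0.05, duration = 1.5,
                            noise_sigma = 0, seed = 1, amplitude0 = 30) {
  tr <- generate_trace(f_d = f_d, zeta = zeta, duration = duration,
                       noise_sigma = noise_sigma, seed = seed,
                       amplitude0 = amplitude0,
                       source_id = basename(dir))
  render_frames(tr, dir)
  tr
}
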