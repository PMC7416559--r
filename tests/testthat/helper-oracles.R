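# Independent brute-force oracles. These deliberately share no code with the
# package internals they check.

# Exact Euclidean distance to the nearest non-fiber pixel, by exhaustive
# search over all background pixels.
bf_distance_transform <- function(mask) {
  out <- matrix(0, nrow(mask), ncol(mask))
  bg <- which(!mask, arr.ind = TRUE)
  fg <- which(mask, arr.ind = TRUE)
  if (nrow(bg) == 0L) { out[mask] <- Inf; return(out) }
  for (i in seq_len(nrow(fg))) {
    out[fg[i, 1], fg[i, 2]] <-
      sqrt(min((fg[i, 1] - bg[, 1])^2 + (fg[i, 2] - bg[, 2])^2))
  }
  out
}

# Flood-fill connected components by explicit queue traversal.
bf_components <- function(mask, connectivity = 4L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbs <- if (connectivity == 4L) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
         else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                   c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  k <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    k <- k + 1L
    queue <- list(c(r0, c0)); lab[r0, c0] <- k
    while (length(queue) > 0L) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in nbs) {
        r <- p[1] + d[1]; c <- p[2] + d[2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- k
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Benjamini-Hochberg step-up, written directly from the definition:
# adj p_(i) = min_{j >= i} ( n / j * p_(j) ), capped at 1.
bf_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(1, min(n / seq(i, n) * ps[seq(i, n)]))
  }
  out <- numeric(n)
  out[ord] <- adj
  out
}

# Welch's t-test from the textbook formulas.
bf_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Synthetic grating with constant intensity along axis `angle_deg`
# (math convention: x = col, y = -row, CCW positive).
make_grating <- function(n = 128L, angle_deg = 0, wavelength = 8) {
  rr <- matrix(rep(seq_len(n), n), n, n)
  cc <- matrix(rep(seq_len(n), each = n), n, n)
  th <- angle_deg * pi / 180
  phase <- -cc * sin(th) + (-rr) * cos(th)
  (sin(2 * pi * phase / wavelength) + 1) / 2
}

# Interior high-energy angle sample from an orientation field.
grating_angles <- function(field, margin = 30L) {
  n <- nrow(field$energy)
  i <- margin:(n - margin)
  a <- field$angle[i, i]; e <- field$energy[i, i]
  a[e > median(field$energy)]
}
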