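# Shared fixtures and independent reference implementations used as oracles.

# A branch small enough for closed-form and finite-difference work:
# 24 -> 11 -> 9 -> 7 -> 5 -> 3 (no pooling), so pre-GAP maps are 3x3.
small_spec <- function(widths = c(3L, 3L, 4L, 4L, 4L)) {
  branch_spec(N = 4L, widths = widths, pool_after = integer(0),
              input_px = 24L)
}

random_pair <- function(S = 24L, seed = 1L, geom = NULL) {
  set.seed(seed)
  structure(list(lateral = matrix(stats::rnorm(S * S), S, S),
                 medial = matrix(stats::rnorm(S * S), S, S),
                 geometry = geom, source_id = "fixture"),
            class = "patch_pair")
}

# Direct (quadruple-loop) valid 3x3 convolution over an (h, w, B, C) array;
# independent reference for the compiled kernel.
conv3_reference <- function(X, Wmat, stride) {
  d <- dim(X)
  oh <- (d[1] - 3L) %/% stride + 1L
  ow <- (d[2] - 3L) %/% stride + 1L
  cout <- ncol(Wmat)
  Y <- array(0, c(oh, ow, d[3], cout))
  for (co in seq_len(cout)) {
    for (b in seq_len(d[3])) {
      for (oy in seq_len(oh)) {
        for (ox in seq_len(ow)) {
          acc <- 0
          for (ci in seq_len(d[4])) {
            for (ky in 0:2) {
              for (kx in 0:2) {
                wrow <- (ci - 1L) * 9L + ky + 3L * kx + 1L
                acc <- acc + X[(oy - 1L) * stride + 1L + ky,
                               (ox - 1L) * stride + 1L + kx, b, ci] *
                  Wmat[wrow, co]
              }
            }
          }
          Y[oy, ox, b, co] <- acc
        }
      }
    }
  }
  Y
}

# Brute-force quadratic weighted kappa via the explicit 5x5 double loop.
kappa_reference <- function(truth, pred, K = 5L) {
  n <- length(truth)
  O <- matrix(0, K, K)
  for (i in seq_len(n)) O[truth[i] + 1L, pred[i] + 1L] <-
    O[truth[i] + 1L, pred[i] + 1L] + 1
  O <- O / n
  rm_ <- rowSums(O)
  cm_ <- colSums(O)
  num <- 0
  den <- 0
  for (i in 1:K) {
    for (j in 1:K) {
      w <- (i - j)^2 / (K - 1)^2
      num <- num + w * O[i, j]
      den <- den + w * rm_[i] * cm_[j]
    }
  }
  1 - num / den
}

# All-pairs Mann-Whitney AUC (ties count one half).
auc_reference <- function(pos_scores, neg_scores) {
  tot <- 0
  for (p in pos_scores) {
    for (q in neg_scores) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos_scores) * length(neg_scores))
}

# Finite-difference oracle for the class-discriminating maps: per-pixel
# gradients of the class score with respect to the pre-GAP activation maps,
# obtained by central differences through the GAP + linear head, then
# spatially averaged (the explicit form of the Grad-CAM weights).
cam_fd_reference <- function(net, pair, cls, branch, eps = 1e-4) {
  v <- c(pair$lateral, pair$medial)
  mu <- mean(v)
  sdv <- stats::sd(v)
  if (sdv < 1e-8) sdv <- 1
  lat <- (pair$lateral - mu) / sdv
  med <- (pair$medial - mu) / sdv
  maps_l <- branch_features(net, lat)$maps
  maps_m <- branch_features(net, med)$maps
  y_of <- function(ml, mm) {
    feat <- c(apply(ml, 3, mean), apply(mm, 3, mean))
    (net$params$head_W %*% feat + net$params$head_b)[cls + 1L]
  }
  maps <- if (branch == 1L) maps_l else maps_m
  d <- dim(maps)
  w_fd <- numeric(d[3])
  for (k in seq_len(d[3])) {
    g <- 0
    for (x in seq_len(d[1])) {
      for (y in seq_len(d[2])) {
        mp <- maps
        mp[x, y, k] <- mp[x, y, k] + eps
        up <- if (branch == 1L) y_of(mp, maps_m) else y_of(maps_l, mp)
        mp[x, y, k] <- mp[x, y, k] - 2 * eps
        dn <- if (branch == 1L) y_of(mp, maps_m) else y_of(maps_l, mp)
        g <- g + (up - dn) / (2 * eps)
      }
    }
    w_fd[k] <- g / (d[1] * d[2])
  }
  m <- matrix(matrix(maps, d[1] * d[2], d[3]) %*% w_fd, d[1], d[2])
  m[m < 0] <- 0
  m
}

# Minimal explicit-VR little-endian DICOM writer for reader round trips.
write_test_dicom <- function(path, pixels, spacing_mm, laterality = "R") {
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  el_str <- function(group, elem, vr, s) {
    if (nchar(s) %% 2 == 1) s <- paste0(s, " ")
    u16(group); u16(elem); writeChar(vr, con, eos = NULL); u16(nchar(s))
    writeChar(s, con, eos = NULL)
  }
  el_us <- function(group, elem, value) {
    u16(group); u16(elem); writeChar("US", con, eos = NULL); u16(2)
    u16(value)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  # file meta group (explicit VR): transfer syntax only
  ts <- "1.2.840.10008.1.2.1"
  ts_len <- nchar(ts) + nchar(ts) %% 2          # NUL-padded to even length
  u16(2); u16(0); writeChar("UL", con, eos = NULL); u16(4)
  u32(8 + ts_len)
  u16(2); u16(16); writeChar("UI", con, eos = NULL); u16(ts_len)
  writeChar(ts, con, eos = NULL)
  if (ts_len > nchar(ts)) writeBin(raw(1), con)
  # main dataset
  el_str(0x0018, 0x1164, "DS", sprintf("%g\\%g", spacing_mm, spacing_mm))
  el_str(0x0020, 0x0062, "CS", laterality)
  el_us(0x0028, 0x0010, nrow(pixels))
  el_us(0x0028, 0x0011, ncol(pixels))
  el_us(0x0028, 0x0100, 16)
  npx <- length(pixels)
  u16(0x7fe0); u16(0x0010); writeChar("OW", con, eos = NULL); u16(0)
  u32(2 * npx)
  # row-major pixel order
  writeBin(as.integer(t(pixels)), con, size = 2, endian = "little")
  invisible(path)
}

# Quiet phantom configuration: no noise, tilt, shift, offset or gap jitter,
# so geometry is exactly the per-grade means.
quiet_phantom_config <- function(...) {
  phantom_config(gap_sd_mm = 0, noise_sd = 0, tilt_deg = 0, shift_px = 0,
                 offset_range = 0, ...)
}

# Phantom sets with distinct source ids, for disjoint train/val fixtures.
relabel_rois <- function(rois, prefix) {
  lapply(seq_along(rois), function(i) {
    r <- rois[[i]]
    r$source_id <- paste0(prefix, i)
    r
  })
}
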