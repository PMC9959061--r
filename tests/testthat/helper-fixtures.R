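# Shared fixture builders and independent brute-force oracles.

const_image <- function(value, role, nr = 16, nc = 16) {
  channel_image(matrix(value, nr, nc), role)
}

rand_image <- function(role, nr = 16, nc = 16, max = 100) {
  channel_image(matrix(runif(nr * nc, 0, max), nr, nc), role)
}

square_mask <- function(nr = 16, nc = 16, r1 = 3, r2 = 12, c1 = 3, c2 = 12) {
  m <- matrix(FALSE, nr, nc)
  m[r1:r2, c1:c2] <- TRUE
  liver_mask(m)
}

# brute-force in-mask sum ratio, double loop (oracle for raw_ratio)
oracle_ratio <- function(green, blue, mask) {
  sg <- sb <- 0
  for (r in seq_len(nrow(mask$mask))) for (c in seq_len(ncol(mask$mask))) {
    if (mask$mask[r, c]) {
      sg <- sg + green$pixels[r, c]
      sb <- sb + blue$pixels[r, c]
    }
  }
  sg / sb
}

# brute-force elementwise GP evaluation (oracle for gp_map)
oracle_gp <- function(ordered, disordered, mask, floor) {
  out <- matrix(NA_real_, nrow(mask$mask), ncol(mask$mask))
  for (r in seq_len(nrow(out))) for (c in seq_len(ncol(out))) {
    io <- ordered$pixels[r, c]; id <- disordered$pixels[r, c]
    tot <- io + id
    if (mask$mask[r, c] && tot >= floor && tot > 0)
      out[r, c] <- (io - id) / tot
  }
  out
}

# Minimal ImageJ .roi writers (64-byte header, big-endian), used to
# exercise the reader against files of known geometry.
write_roi_header <- function(type, top, left, bottom, right, n = 0L) {
  con <- rawConnection(raw(0), "w")
  writeChar("Iout", con, 4, eos = NULL)
  writeBin(c(225L, 0L), con, size = 1)            # version hi/lo
  writeBin(as.integer(type), con, size = 1)
  writeBin(0L, con, size = 1)
  writeBin(as.integer(c(top, left, bottom, right, n)), con, size = 2,
           endian = "big")
  writeBin(raw(64 - 18), con)
  hdr <- rawConnectionValue(con)
  close(con)
  hdr
}

write_roi_rect <- function(path, top, left, bottom, right) {
  writeBin(write_roi_header(1L, top, left, bottom, right), path)
}

write_roi_oval <- function(path, top, left, bottom, right) {
  writeBin(write_roi_header(2L, top, left, bottom, right), path)
}

write_roi_polygon <- function(path, x, y) {
  top <- min(y); left <- min(x)
  hdr <- write_roi_header(0L, top, left, max(y), max(x), length(x))
  con <- rawConnection(raw(0), "w")
  writeBin(hdr, con)
  writeBin(as.integer(x - left), con, size = 2, endian = "big")
  writeBin(as.integer(y - top), con, size = 2, endian = "big")
  out <- rawConnectionValue(con)
  close(con)
  writeBin(out, path)
}

# a small noiseless slice with disks painted at known positions
disk_slice <- function(centers, radius, nr = 64, nc = 64,
                       bg = 10, amp = 200, blue = 50) {
  g <- matrix(bg, nr, nc)
  for (k in seq_len(nrow(centers))) {
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if ((r - 0.5 - centers[k, 1])^2 + (c - 0.5 - centers[k, 2])^2 <=
          radius^2)
        g[r, c] <- bg + amp
    }
  }
  list(green = channel_image(g, "lipid_green"),
       blue = channel_image(matrix(blue, nr, nc), "norm_blue"),
       mask = liver_mask(matrix(TRUE, nr, nc)))
}

# match detected droplet centroids to true centres within tol pixels;
# returns c(true_positives, n_detected, n_true)
match_droplets <- function(detected, true_centers, tol = 3) {
  nd <- length(detected)
  nt <- nrow(true_centers)
  if (nd == 0L || nt == 0L) return(c(tp = 0L, nd = nd, nt = nt))
  used <- rep(FALSE, nt)
  tp <- 0L
  for (d in detected) {
    # detected centroids are 1-based pixel indices; truth is 0-based centres
    dc <- d$centroid - 0.5
    dist <- sqrt((true_centers[, 1] - dc[1])^2 +
                   (true_centers[, 2] - dc[2])^2)
    j <- which.min(ifelse(used, Inf, dist))
    if (length(j) && dist[j] <= tol && !used[j]) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  c(tp = tp, nd = nd, nt = nt)
}
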