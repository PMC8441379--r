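# Fixture builders shared across test files. Everything is generated in
# code; no data files ship with the package.

# a dense flat rectangular "leaf" along +x, width in y, at height z0
rect_leaf_cloud <- function(n = 20000, len = 0.5, wid = 0.1, z0 = 0,
                            seed = 2) {
  withr_seed(seed)
  point_cloud(cbind(runif(n, 0, len), runif(n, -wid / 2, wid / 2),
                    rep(z0, n)))
}

# minimal seed helper (tests run in their own RNG scope anyway)
withr_seed <- function(seed) set.seed(seed)

# unit tetrahedron corners
tetra_cloud <- function() {
  point_cloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
}

# random leaf specification drawn from the generator's stated world
random_leaf_spec <- function() {
  leaf_spec(length = runif(1, 0.35, 0.55),
            max_width = runif(1, 0.05, 0.09),
            attach_height = runif(1, 0.5, 1.5),
            inclination_deg = runif(1, 20, 60),
            azimuth_deg = runif(1, 0, 360),
            droop = runif(1, 0.05, 0.25))
}

# rotate a cloud about the z axis by `deg` (clockwise-from-north positive,
# i.e. the same sense as an azimuth increase)
rotate_z <- function(cloud, deg) {
  a <- deg * pi / 180
  R <- matrix(c(cos(a), -sin(a), 0,
                sin(a), cos(a), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  # azimuth is clockwise from +y; adding `deg` maps (x, y) accordingly
  xy <- cloud$coords[, 1:2] %*% t(matrix(c(cos(a), sin(a),
                                           -sin(a), cos(a)), 2, 2,
                                         byrow = TRUE))
  out <- cloud
  out$coords <- cbind(xy, cloud$coords[, 3])
  colnames(out$coords) <- c("x", "y", "z")
  out
}

# build a minimal LAS 1.2 file (point format 0) from a coordinate matrix
write_tiny_las <- function(coords, path, scale = c(0.001, 0.001, 0.001),
                           offset = c(10, 20, 0)) {
  n <- nrow(coords)
  header_size <- 227L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- raw(header_size)
  hdr[1:4] <- charToRaw("LASF")
  hdr[25] <- as.raw(1); hdr[26] <- as.raw(2)        # version 1.2
  hdr[95:96] <- writeBin(header_size, raw(), size = 2, endian = "little")  # header size @94
  hdr[97:100] <- writeBin(header_size, raw(), size = 4, endian = "little") # offset to points @96
  hdr[105] <- as.raw(0)                              # point format 0
  hdr[106:107] <- writeBin(20L, raw(), size = 2, endian = "little")
  hdr[108:111] <- writeBin(n, raw(), size = 4, endian = "little")
  hdr[132:139] <- writeBin(scale[1], raw(), size = 8, endian = "little")
  hdr[140:147] <- writeBin(scale[2], raw(), size = 8, endian = "little")
  hdr[148:155] <- writeBin(scale[3], raw(), size = 8, endian = "little")
  hdr[156:163] <- writeBin(offset[1], raw(), size = 8, endian = "little")
  hdr[164:171] <- writeBin(offset[2], raw(), size = 8, endian = "little")
  hdr[172:179] <- writeBin(offset[3], raw(), size = 8, endian = "little")
  writeBin(hdr, con)
  ints <- round(sweep(coords, 2, offset) %*% diag(1 / scale))
  for (i in seq_len(n)) {
    writeBin(as.integer(ints[i, ]), con, size = 4, endian = "little")
    writeBin(raw(8), con)                            # rest of format 0
  }
  invisible(path)
}
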