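# Shared fixtures built in code.

# reference thermodynamic inputs for the 30-min walk at 1.25 m/s
# (literature-derived cohort means with their bound intervals)
ref_thermo <- function() {
  thermo_params(W_stride = -0.0034, m_foot = 1.17, c_foot = 1.96,
                total_strides = 1674, duration_min = 30,
                W_bounds = c(-0.0071, 0.00023), c_bounds = c(1.31, 3.62))
}

# a 20x20 frame with a 5-region striped mask, seeded
random_frame_and_mask <- function(seed = 1) {
  set.seed(seed)
  px <- matrix(runif(400, 25, 38), 20, 20)
  labels <- matrix(0L, 20, 20)
  for (i in 1:5) labels[, (4 * i - 3):(4 * i - 1)] <- i  # col 4i stays background
  list(frame = thermal_frame(px, time_min = 0),
       mask = region_mask(labels, c(hallux = 1, MTP = 2, midfoot = 3,
                                    arch = 4, heel = 5)))
}

# minimal single-strip little-endian float32 TIFF writer (test fixture only:
# the tiff package cannot store out-of-[0,1] floats, while real thermal
# exports carry degrees C)
write_float_tiff <- function(m, path) {
  w <- ncol(m); h <- nrow(m)
  data <- as.vector(t(m))  # row-major strip
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(as.integer(42), con, size = 2, endian = "little")
  writeBin(as.integer(8), con, size = 4, endian = "little")  # IFD offset
  tags <- list(
    c(256, 3, 1, w),          # ImageWidth
    c(257, 3, 1, h),          # ImageLength
    c(258, 3, 1, 32),         # BitsPerSample
    c(259, 3, 1, 1),          # Compression: none
    c(262, 3, 1, 1),          # Photometric: BlackIsZero
    c(273, 4, 1, 0),          # StripOffsets (patched below)
    c(277, 3, 1, 1),          # SamplesPerPixel
    c(278, 3, 1, h),          # RowsPerStrip
    c(279, 4, 1, length(data) * 4),  # StripByteCounts
    c(339, 3, 1, 3))          # SampleFormat: IEEE float
  strip_offset <- 8 + 2 + length(tags) * 12 + 4
  tags[[6]][4] <- strip_offset
  writeBin(as.integer(length(tags)), con, size = 2, endian = "little")
  for (tg in tags) {
    writeBin(as.integer(tg[1]), con, size = 2, endian = "little")
    writeBin(as.integer(tg[2]), con, size = 2, endian = "little")
    writeBin(as.integer(tg[3]), con, size = 4, endian = "little")
    writeBin(as.integer(tg[4]), con, size = 4, endian = "little")
  }
  writeBin(as.integer(0), con, size = 4, endian = "little")  # next IFD
  writeBin(data, con, size = 4, endian = "little")
  invisible(path)
}
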