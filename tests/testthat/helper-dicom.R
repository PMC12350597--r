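# Synthesize a minimal single-frame explicit-VR little-endian DICOM file so
# the reader can be tested without any binary fixture in the repository.

writeTestDicom <- function(path, stored, spacing = c(0.7, 0.7),
                           slope = 1, intercept = -1024,
                           omit = character(0)) {
  con <- file(path, "wb")
  on.exit(close(con))

  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  element <- function(group, elem, vr, payload) {
    u16(group); u16(elem)
    writeBin(charToRaw(vr), con)
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      writeBin(as.raw(c(0, 0)), con)
      writeBin(length(payload), con, size = 4, endian = "little")
    } else {
      u16(length(payload))
    }
    writeBin(payload, con)
  }
  strPayload <- function(s, padNul = FALSE) {
    b <- charToRaw(s)
    if (length(b) %% 2 == 1)
      b <- c(b, if (padNul) as.raw(0) else charToRaw(" "))
    b
  }
  u16Payload <- function(x) {
    tmp <- writeBin(as.integer(x), raw(), size = 2, endian = "little")
    tmp
  }

  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  element(0x0002, 0x0010, "UI", strPayload("1.2.840.10008.1.2.1", padNul = TRUE))
  element(0x0028, 0x0010, "US", u16Payload(nrow(stored)))
  element(0x0028, 0x0011, "US", u16Payload(ncol(stored)))
  element(0x0028, 0x0030, "DS",
          strPayload(paste(spacing, collapse = "\\")))
  element(0x0028, 0x0100, "US", u16Payload(16))
  element(0x0028, 0x0103, "US", u16Payload(0))
  if (!"intercept" %in% omit)
    element(0x0028, 0x1052, "DS", strPayload(as.character(intercept)))
  if (!"slope" %in% omit)
    element(0x0028, 0x1053, "DS", strPayload(as.character(slope)))
  # DICOM pixel order: row by row, top-left first
  pix <- writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little")
  element(0x7fe0, 0x0010, "OW", pix)
  invisible(path)
}
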