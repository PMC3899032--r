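# Assembling rendered frames into movies. GIF is the reference format and
# is encoded natively (a valid LZW stream built from literal codes with
# periodic clear codes, so no dictionary is ever grown — lossless and
# byte-reproducible). AVI is written as an uncompressed RIFF/DIB container.
# MP4 is delegated to an ffmpeg binary when one is on the PATH.

u16le <- function(x) writeBin(as.integer(x), raw(), size = 2L,
                              endian = "little")
u32le <- function(x) writeBin(as.integer(x), raw(), size = 4L,
                              endian = "little")

read_frame_rgb <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  a <- a[, , 1:3, drop = FALSE]
  storage.mode(a) <- "double"
  round(a * 255)
}

# Map frames onto one shared palette. Exact when the frames use <= 256
# distinct colours (the renderer's discrete colour tables keep them well
# under); otherwise colours are quantised onto a fixed 6x7x6 RGB cube.
quantize_frames <- function(rgb_frames) {
  keys <- lapply(rgb_frames, function(a) {
    a[, , 1L] * 65536 + a[, , 2L] * 256 + a[, , 3L]
  })
  uniq <- sort(unique(unlist(lapply(keys, as.vector))))
  if (length(uniq) <= 256L) {
    idx <- lapply(keys, function(k) {
      matrix(match(as.vector(k), uniq) - 1L, nrow(k), ncol(k))
    })
    pal <- cbind(uniq %/% 65536, (uniq %/% 256) %% 256, uniq %% 256)
  } else {
    rl <- 5L; gl <- 6L; bl <- 5L  # 6 x 7 x 6 = 252 levels
    cube <- expand.grid(b = 0:bl, g = 0:gl, r = 0:rl)
    pal <- cbind(round(255 * cube$r / rl), round(255 * cube$g / gl),
                 round(255 * cube$b / bl))
    idx <- lapply(rgb_frames, function(a) {
      r <- round(a[, , 1L] / 255 * rl)
      g <- round(a[, , 2L] / 255 * gl)
      b <- round(a[, , 3L] / 255 * bl)
      matrix(as.integer(r * (gl + 1L) * (bl + 1L) + g * (bl + 1L) + b),
             dim(a)[1L], dim(a)[2L])
    })
  }
  list(palette = pal, indices = idx)
}

# Pack an LZW code stream (fixed code size) into bytes, LSB first.
pack_bits_lsb <- function(codes, code_size) {
  bits <- matrix(0L, nrow = code_size, ncol = length(codes))
  for (k in seq_len(code_size)) {
    bits[k, ] <- bitwAnd(bitwShiftR(codes, k - 1L), 1L)
  }
  stream <- as.integer(bits)
  pad <- (8L - length(stream) %% 8L) %% 8L
  if (pad > 0L) stream <- c(stream, integer(pad))
  bytes <- colSums(matrix(stream, nrow = 8L) * 2L^(0:7))
  as.raw(bytes)
}

# GIF LZW stream of pure literal codes: a clear code is emitted before the
# decoder's dictionary would force a code-size increase, so every code is
# exactly (min_code_size + 1) bits.
gif_lzw_literal <- function(pixel_indices, min_code_size) {
  b <- min_code_size
  clear <- 2L^b
  eoi <- clear + 1L
  # After a clear the decoder's next free slot is 2^b + 2 and its code size
  # grows once that slot reaches 2^(b+1); the first literal after a clear
  # adds no entry, so at most 1 + (2^b - 3) literals may be emitted before
  # the next clear to keep every code at b + 1 bits.
  group <- 2L^b - 2L
  n <- length(pixel_indices)
  n_groups <- ceiling(n / group)
  codes <- integer(n + n_groups + 1L)
  pos <- 1L
  for (g in seq_len(n_groups)) {
    codes[pos] <- clear
    take <- pixel_indices[((g - 1L) * group + 1L):min(g * group, n)]
    codes[(pos + 1L):(pos + length(take))] <- take
    pos <- pos + length(take) + 1L
  }
  codes[pos] <- eoi
  pack_bits_lsb(codes[seq_len(pos)], b + 1L)
}

sub_blocks <- function(bytes) {
  n <- length(bytes)
  starts <- seq.int(1L, n, by = 255L)
  out <- vector("list", length(starts) + 1L)
  for (i in seq_along(starts)) {
    chunk <- bytes[starts[i]:min(starts[i] + 254L, n)]
    out[[i]] <- c(as.raw(length(chunk)), chunk)
  }
  out[[length(out)]] <- as.raw(0L)  # block terminator
  do.call(c, out)
}

write_gif <- function(frames, fps, path) {
  rgb <- lapply(frames, read_frame_rgb)
  q <- quantize_frames(rgb)
  h <- nrow(q$indices[[1L]]); w <- ncol(q$indices[[1L]])
  ncol_pal <- nrow(q$palette)
  bits <- max(2L, ceiling(log2(ncol_pal)))
  table_size <- 2L^bits
  pal <- rbind(q$palette,
               matrix(0L, table_size - ncol_pal, 3L))
  delay_cs <- max(1L, round(100 / fps))  # hundredths of a second
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("GIF89a"), con)
  # logical screen descriptor with a global colour table
  writeBin(c(u16le(w), u16le(h),
             as.raw(bitwOr(0xF0L, bits - 1L)), as.raw(0L), as.raw(0L)), con)
  writeBin(as.raw(t(pal)), con)
  # NETSCAPE looping extension (loop forever)
  writeBin(c(as.raw(c(0x21, 0xFF, 0x0B)), charToRaw("NETSCAPE2.0"),
             as.raw(c(0x03, 0x01)), u16le(0L), as.raw(0L)), con)
  for (ind in q$indices) {
    writeBin(c(as.raw(c(0x21, 0xF9, 0x04, 0x00)), u16le(delay_cs),
               as.raw(c(0x00, 0x00))), con)
    writeBin(c(as.raw(0x2C), u16le(0L), u16le(0L), u16le(w), u16le(h),
               as.raw(0L)), con)
    writeBin(as.raw(bits), con)
    stream <- gif_lzw_literal(as.integer(t(ind)), bits)
    writeBin(sub_blocks(stream), con)
  }
  writeBin(as.raw(0x3B), con)
  invisible(path)
}

#' Structural metadata of a GIF file
#'
#' Walks the block structure of a GIF (without LZW-decoding pixel data) and
#' reports frame count, per-frame delays and canvas size.
#'
#' @param path Path to a GIF file.
#' @return A list: `width`, `height`, `n_frames`, `delays_sec`,
#'   `duration_sec`.
#' @export
gif_info <- function(path) {
  b <- readBin(path, "raw", file.info(path)$size)
  stopifnot(rawToChar(b[1:6]) %in% c("GIF89a", "GIF87a"))
  w <- as.integer(b[7L]) + 256L * as.integer(b[8L])
  h <- as.integer(b[9L]) + 256L * as.integer(b[10L])
  packed <- as.integer(b[11L])
  pos <- 14L
  if (bitwAnd(packed, 0x80L) > 0L) {
    pos <- pos + 3L * 2L^(bitwAnd(packed, 0x07L) + 1L)
  }
  skip_subblocks <- function(pos) {
    repeat {
      len <- as.integer(b[pos]); pos <- pos + 1L
      if (len == 0L) return(pos)
      pos <- pos + len
    }
  }
  delays <- numeric(0)
  pending_delay <- NA_real_
  n_frames <- 0L
  repeat {
    tag <- as.integer(b[pos])
    if (tag == 0x3BL || pos > length(b)) break
    if (tag == 0x21L) {            # extension
      label <- as.integer(b[pos + 1L])
      if (label == 0xF9L) {
        pending_delay <- (as.integer(b[pos + 4L]) +
                          256L * as.integer(b[pos + 5L])) / 100
      }
      pos <- skip_subblocks(pos + 2L)
    } else if (tag == 0x2CL) {     # image descriptor
      ipacked <- as.integer(b[pos + 9L])
      pos <- pos + 10L
      if (bitwAnd(ipacked, 0x80L) > 0L) {
        pos <- pos + 3L * 2L^(bitwAnd(ipacked, 0x07L) + 1L)
      }
      pos <- skip_subblocks(pos + 1L)  # skip LZW min code size + data
      n_frames <- n_frames + 1L
      delays <- c(delays, if (is.na(pending_delay)) 0 else pending_delay)
      pending_delay <- NA_real_
    } else {
      stop(sprintf("gif_info: unexpected block 0x%02X at offset %d",
                   tag, pos), call. = FALSE)
    }
  }
  list(width = w, height = h, n_frames = n_frames, delays_sec = delays,
       duration_sec = sum(delays))
}

avi_frame_bytes <- function(rgb) {
  h <- dim(rgb)[1L]; w <- dim(rgb)[2L]
  row_bytes <- w * 3L
  pad <- (4L - row_bytes %% 4L) %% 4L
  rows <- lapply(seq.int(h, 1L), function(r) {  # bottom-up
    px <- rbind(rgb[r, , 3L], rgb[r, , 2L], rgb[r, , 1L])  # BGR
    c(as.raw(as.integer(px)), raw(pad))
  })
  do.call(c, rows)
}

write_avi <- function(frames, fps, path) {
  rgb <- lapply(frames, read_frame_rgb)
  h <- dim(rgb[[1L]])[1L]; w <- dim(rgb[[1L]])[2L]
  payloads <- lapply(rgb, avi_frame_bytes)
  fsize <- length(payloads[[1L]])
  nf <- length(payloads)
  fourcc <- function(s) charToRaw(s)
  chunk <- function(id, data) c(fourcc(id), u32le(length(data)), data,
                                if (length(data) %% 2L) raw(1L))
  list_chunk <- function(type, data) chunk("LIST", c(fourcc(type), data))
  strf <- c(u32le(40L), u32le(w), u32le(h), u16le(1L), u16le(24L),
            u32le(0L), u32le(fsize), u32le(0L), u32le(0L), u32le(0L),
            u32le(0L))
  strh <- c(fourcc("vids"), fourcc("DIB "), u32le(0L), u16le(0L), u16le(0L),
            u32le(0L), u32le(1L), u32le(round(fps)), u32le(0L), u32le(nf),
            u32le(fsize), u32le(0L), u32le(0L),
            u16le(0L), u16le(0L), u16le(w), u16le(h))
  strl <- list_chunk("strl", c(chunk("strh", strh), chunk("strf", strf)))
  avih <- c(u32le(round(1e6 / fps)), u32le(fsize * round(fps)), u32le(0L),
            u32le(0x10L), u32le(nf), u32le(0L), u32le(1L), u32le(fsize),
            u32le(w), u32le(h), u32le(0L), u32le(0L), u32le(0L), u32le(0L))
  hdrl <- list_chunk("hdrl", c(chunk("avih", avih), strl))
  movi_frames <- lapply(payloads, function(p) chunk("00db", p))
  movi <- list_chunk("movi", do.call(c, movi_frames))
  offsets <- cumsum(c(4L, utils::head(vapply(movi_frames, length, 0L),
                                      -1L)))
  idx1 <- do.call(c, lapply(seq_len(nf), function(i) {
    c(fourcc("00db"), u32le(0x10L), u32le(offsets[i]),
      u32le(length(payloads[[i]])))
  }))
  body <- c(fourcc("AVI "), hdrl, movi, chunk("idx1", idx1))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(fourcc("RIFF"), u32le(length(body)), body), con)
  invisible(path)
}

#' Structural metadata of an AVI file written by this package
#'
#' @param path Path to an AVI file.
#' @return A list: `width`, `height`, `n_frames`, `fps`.
#' @export
avi_info <- function(path) {
  b <- readBin(path, "raw", file.info(path)$size)
  stopifnot(rawToChar(b[1:4]) == "RIFF", rawToChar(b[9:12]) == "AVI ")
  u32 <- function(off) sum(as.integer(b[off + 0:3]) * 256^(0:3))
  # avih payload starts after RIFF(12) + LIST hdr(12) + 'avih'+size(8)
  avih_at <- 33L
  list(width = u32(avih_at + 32L), height = u32(avih_at + 36L),
       n_frames = u32(avih_at + 16L),
       fps = 1e6 / u32(avih_at))
}

#' Decode the frames of an AVI file written by this package
#'
#' Reads the uncompressed DIB payloads back into RGB arrays; used to verify
#' that encoding is lossless and order-preserving.
#'
#' @param path Path to an AVI produced by [write_animation()].
#' @return A list of `height x width x 3` arrays with values in 0..255.
#' @export
avi_frames <- function(path) {
  b <- readBin(path, "raw", file.info(path)$size)
  info <- avi_info(path)
  w <- info$width; h <- info$height
  row_bytes <- w * 3L
  pad <- (4L - row_bytes %% 4L) %% 4L
  marker <- charToRaw("00db")
  hits <- which(b == marker[1L])
  hits <- hits[b[hits + 1L] == marker[2L] & b[hits + 2L] == marker[3L] &
               b[hits + 3L] == marker[4L]]
  # frame chunks all have the full payload size; idx1 entries do not
  fsize <- (row_bytes + pad) * h
  u32 <- function(off) sum(as.integer(b[off + 0:3]) * 256^(0:3))
  hits <- hits[vapply(hits, function(p) u32(p + 4L) == fsize, TRUE)]
  lapply(hits[seq_len(info$n_frames)], function(p) {
    data <- as.integer(b[(p + 8L):(p + 7L + fsize)])
    m <- matrix(data, nrow = row_bytes + pad)[seq_len(row_bytes), ,
                                              drop = FALSE]
    arr <- array(0L, c(h, w, 3L))
    for (ch in 1:3) {
      plane <- m[seq.int(4L - ch, row_bytes, by = 3L), , drop = FALSE]
      arr[, , ch] <- t(plane)[seq.int(h, 1L), , drop = FALSE]
    }
    arr
  })
}

#' Assemble rendered frames into an animation
#'
#' Encodes an ordered list of PNG frame files into an animated GIF
#' (natively, losslessly when frames use at most 256 colours), an
#' uncompressed AVI (natively, always lossless), or an MP4 (requires an
#' `ffmpeg` binary on the PATH).
#'
#' @param frames Character vector of PNG paths in display order (>= 1);
#'   all frames must share the same pixel dimensions.
#' @param fps Frames per second (default 10).
#' @param path Output file path.
#' @param format `"gif"`, `"avi"` or `"mp4"`; defaults to the extension of
#'   `path`.
#' @return The output path, invisibly.
#' @export
write_animation <- function(frames, fps = 10, path,
                            format = c("gif", "avi", "mp4")) {
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("gif", "avi", "mp4")) {
      stop(sprintf("write_animation: unknown format '%s'", ext),
           call. = FALSE)
    }
    format <- ext
  } else {
    format <- match.arg(format)
  }
  if (length(frames) < 1L) {
    stop("write_animation: need at least one frame", call. = FALSE)
  }
  missing_f <- !file.exists(frames)
  if (any(missing_f)) {
    stop(sprintf("write_animation: missing frame file(s): %s",
                 paste(which(missing_f), collapse = ", ")), call. = FALSE)
  }
  dims <- vapply(frames, function(f) dim(png::readPNG(f))[1:2],
                 integer(2L))
  bad <- which(dims[1L, ] != dims[1L, 1L] | dims[2L, ] != dims[2L, 1L])
  if (length(bad) > 0L) {
    stop(sprintf("write_animation: frames %s differ in size from frame 1",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  switch(format,
         gif = write_gif(frames, fps, path),
         avi = write_avi(frames, fps, path),
         mp4 = write_mp4(frames, fps, path))
  invisible(path)
}

write_mp4 <- function(frames, fps, path) {
  ffmpeg <- Sys.which("ffmpeg")
  if (!nzchar(ffmpeg)) {
    stop("write_animation: mp4 output requires an 'ffmpeg' binary on the PATH; use gif or avi",
         call. = FALSE)
  }
  staging <- tempfile("frames_")
  dir.create(staging)
  on.exit(unlink(staging, recursive = TRUE))
  for (i in seq_along(frames)) {
    file.copy(frames[i], file.path(staging, sprintf("frame_%05d.png", i)))
  }
  status <- system2(ffmpeg,
                    c("-y", "-loglevel", "error", "-framerate", fps,
                      "-i", shQuote(file.path(staging, "frame_%05d.png")),
                      "-pix_fmt", "yuv420p", shQuote(path)))
  if (status != 0L) {
    stop("write_animation: ffmpeg failed", call. = FALSE)
  }
  invisible(path)
}
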