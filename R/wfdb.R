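# Minimal WFDB codec: header (.hea), signal data (.dat, formats 16 and
# 212), and MIT-format annotation files. Indices are 0-based sample
# positions throughout, matching the WFDB convention.

# MIT annotation type codes that denote beats (QRS complexes), and their
# conventional mnemonics. Non-beat events (rhythm changes, noise marks,
# comments) are excluded when `beat_only` filtering is requested.
.wfdb_beat_codes <- c(1:13, 25L, 34L, 35L, 38L)
.wfdb_mnemonics <- c(
  "1" = "N", "2" = "L", "3" = "R", "4" = "a", "5" = "V", "6" = "F",
  "7" = "J", "8" = "A", "9" = "S", "10" = "E", "11" = "j", "12" = "/",
  "13" = "Q", "14" = "~", "16" = "|", "22" = "\"", "25" = "B",
  "28" = "+", "34" = "e", "35" = "n", "38" = "f")

.wfdb_code_for <- function(mnemonic) {
  hit <- names(.wfdb_mnemonics)[match(mnemonic, .wfdb_mnemonics)]
  out <- as.integer(hit)
  out[is.na(out)] <- 13L  # unknown beat type
  out
}

wfdb_read_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("empty WFDB header: ", hea_path)
  rec <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(rec) < 2L) stop("unreadable WFDB record line in ", hea_path)
  n_sig <- as.integer(rec[2L])
  fs <- if (length(rec) >= 3L) as.numeric(sub("/.*$", "", rec[3L])) else 250
  n_samp <- if (length(rec) >= 4L) as.integer(rec[4L]) else NA_integer_
  if (length(lines) < 1L + n_sig)
    stop("WFDB header declares ", n_sig, " signals but lists fewer")
  sig <- lapply(lines[1L + seq_len(n_sig)], function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1L]]
    fmt <- as.integer(sub("[x:+].*$", "", f[2L]))
    gain_spec <- if (length(f) >= 3L) f[3L] else "200"
    gain <- as.numeric(sub("^([-0-9.eE]+).*$", "\\1", gain_spec))
    if (is.na(gain) || gain == 0) gain <- 200
    baseline <- 0L
    bl <- regmatches(gain_spec, regexec("\\(([-0-9]+)\\)", gain_spec))[[1L]]
    if (length(bl) == 2L) baseline <- as.integer(bl[2L])
    adc_zero <- if (length(f) >= 5L) suppressWarnings(as.integer(f[5L])) else 0L
    if (is.na(adc_zero)) adc_zero <- 0L
    if (length(bl) != 2L) baseline <- adc_zero
    desc <- if (length(f) >= 9L) paste(f[9:length(f)], collapse = " ") else NA
    list(file = f[1L], fmt = fmt, gain = gain, baseline = baseline,
         description = desc)
  })
  list(record = rec[1L], n_sig = n_sig, fs = fs, n_samp = n_samp,
       signals = sig)
}

.wfdb_decode_212 <- function(raw, n_values) {
  b <- as.integer(raw)
  n_tri <- length(b) %/% 3L
  b0 <- b[seq(1L, by = 3L, length.out = n_tri)]
  b1 <- b[seq(2L, by = 3L, length.out = n_tri)]
  b2 <- b[seq(3L, by = 3L, length.out = n_tri)]
  s1 <- bitwOr(bitwShiftL(bitwAnd(b1, 0x0FL), 8L), b0)
  s2 <- bitwOr(bitwShiftL(bitwAnd(b1, 0xF0L), 4L), b2)
  v <- as.vector(rbind(s1, s2))
  v <- ifelse(v > 2047L, v - 4096L, v)
  v[seq_len(min(n_values, length(v)))]
}

.wfdb_encode_212 <- function(values) {
  if (length(values) %% 2L == 1L) values <- c(values, 0L)
  v <- as.integer(values)
  if (any(v < -2048L | v > 2047L))
    stop("sample out of range for WFDB format 212")
  v <- ifelse(v < 0L, v + 4096L, v)
  s1 <- v[seq(1L, length(v), by = 2L)]
  s2 <- v[seq(2L, length(v), by = 2L)]
  b0 <- bitwAnd(s1, 0xFFL)
  b1 <- bitwOr(bitwShiftR(s1, 8L), bitwAnd(bitwShiftR(s2, 4L), 0xF0L))
  b2 <- bitwAnd(s2, 0xFFL)
  as.raw(as.vector(rbind(b0, b1, b2)))
}

wfdb_read_record <- function(path) {
  hea_path <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea_path)) stop("WFDB header not found: ", hea_path)
  hdr <- wfdb_read_header(hea_path)
  dir <- dirname(hea_path)
  dat_files <- unique(vapply(hdr$signals, `[[`, "", "file"))
  if (length(dat_files) != 1L)
    stop("multi-file WFDB records are not supported")
  dat_path <- file.path(dir, dat_files)
  if (!file.exists(dat_path)) stop("WFDB signal file not found: ", dat_path)
  raw <- readBin(dat_path, "raw", n = file.size(dat_path))
  fmt <- hdr$signals[[1L]]$fmt
  n_sig <- hdr$n_sig
  if (fmt == 16L) {
    v <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                 signed = TRUE, endian = "little")
  } else if (fmt == 212L) {
    v <- .wfdb_decode_212(raw, (length(raw) %/% 3L) * 2L)
  } else stop("unsupported WFDB format: ", fmt)
  n <- length(v) %/% n_sig
  if (!is.na(hdr$n_samp) && hdr$n_samp > 0L) n <- min(n, hdr$n_samp)
  m <- matrix(v[seq_len(n * n_sig)], ncol = n_sig, byrow = TRUE)
  for (i in seq_len(n_sig)) {
    s <- hdr$signals[[i]]
    m[, i] <- (m[, i] - s$baseline) / s$gain
  }
  nm <- vapply(seq_len(n_sig), function(i) {
    d <- hdr$signals[[i]]$description
    if (is.na(d) || !nzchar(d)) paste0("lead", i) else d
  }, "")
  multilead_signal(m, hdr$fs, nm)
}

wfdb_write_record <- function(signal, path, fmt = 16L, gain = 200) {
  base <- sub("\\.hea$", "", path)
  rec <- basename(base)
  n <- n_samples(signal); L <- n_leads(signal)
  adc <- round(signal$samples * gain)
  rng <- if (fmt == 212L) c(-2048, 2047) else c(-32768, 32767)
  adc[adc < rng[1L]] <- rng[1L]; adc[adc > rng[2L]] <- rng[2L]
  storage.mode(adc) <- "integer"
  hdr <- c(sprintf("%s %d %g %d", rec, L, signal$fs, n),
           sprintf("%s.dat %d %g(0)/mV 16 0 %d 0 0 %s",
                   rec, fmt, gain, adc[1L, ], signal$lead_names))
  writeLines(hdr, paste0(base, ".hea"))
  inter <- as.integer(t(adc))  # sample-interleaved across signals
  con <- file(paste0(base, ".dat"), "wb")
  on.exit(close(con))
  if (fmt == 16L) {
    writeBin(inter, con, size = 2L, endian = "little")
  } else if (fmt == 212L) {
    writeBin(.wfdb_encode_212(inter), con)
  } else stop("unsupported WFDB format: ", fmt)
  invisible(paste0(base, ".hea"))
}

wfdb_read_annotations <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  b <- as.integer(raw)
  n <- length(b) %/% 2L
  lo <- b[seq(1L, by = 2L, length.out = n)]
  hi <- b[seq(2L, by = 2L, length.out = n)]
  word <- bitwOr(bitwShiftL(hi, 8L), lo)
  codes <- integer(0); times <- numeric(0)
  t_cur <- 0; skip_add <- 0
  i <- 1L
  while (i <= n) {
    w <- word[i]
    code <- bitwShiftR(w, 10L)
    delta <- bitwAnd(w, 0x3FFL)
    if (w == 0L) break                       # EOF
    if (code == 59L) {                       # SKIP: 4-byte interval follows
      if (i + 2L > n) break
      high <- word[i + 1L]; low <- word[i + 2L]
      iv <- high * 65536 + low
      if (iv >= 2147483648) iv <- iv - 4294967296
      skip_add <- skip_add + iv
      i <- i + 3L
      next
    }
    if (code %in% c(60L, 61L, 62L)) { i <- i + 1L; next }  # NUM/SUB/CHN
    if (code == 63L) {                       # AUX: skip string payload
      i <- i + 1L + ceiling(delta / 2)
      next
    }
    t_cur <- t_cur + delta + skip_add
    skip_add <- 0
    codes <- c(codes, code)
    times <- c(times, t_cur)
    i <- i + 1L
  }
  data.frame(time = times, code = codes,
             label = unname(.wfdb_mnemonics[as.character(codes)]),
             stringsAsFactors = FALSE)
}

wfdb_write_annotations <- function(indices, labels, path) {
  stopifnot(length(indices) == length(labels))
  codes <- .wfdb_code_for(labels)
  words <- integer(0)
  t_prev <- 0
  for (k in seq_along(indices)) {
    delta <- indices[k] - t_prev
    if (delta >= 1024 || delta < 0) {
      iv <- delta
      if (iv < 0) iv <- iv + 4294967296
      high <- iv %/% 65536; low <- iv %% 65536
      words <- c(words, bitwShiftL(59L, 10L), as.integer(high),
                 as.integer(low))
      delta <- 0
    }
    words <- c(words, bitwOr(bitwShiftL(codes[k], 10L), as.integer(delta)))
    t_prev <- indices[k]
  }
  words <- c(words, 0L)  # EOF
  lo <- as.raw(words %% 256L)
  hi <- as.raw(words %/% 256L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(rbind(lo, hi)), con)
  invisible(path)
}
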