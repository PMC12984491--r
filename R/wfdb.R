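# Minimal WFDB support: single-segment records, signal format 16
# (little-endian 16-bit two's complement), all signals interleaved in one
# .dat file, gain/baseline applied at read time so amplitudes are mV
# everywhere downstream.  This is the subset the synthetic cohort writes
# and covers standard 12-lead exports such as MIMIC-IV-ECG.

#' Read a WFDB record
#'
#' @param path record base name, or path to the `.hea` file.
#' @return list with `record_id`, `fs`, `leads` (named list of mV series).
#' @export
read_wfdb <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("unreadable file: ", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  top <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  record_id <- sub("/.*$", "", top[1L])
  nsig <- as.integer(top[2L])
  fs <- if (length(top) >= 3L) as.numeric(sub("/.*$", "", top[3L])) else 250
  nsamp <- if (length(top) >= 4L) as.integer(top[4L]) else NA_integer_
  if (length(lines) < 1L + nsig) stop("truncated WFDB header")
  sig <- lapply(lines[1L + seq_len(nsig)], parse_wfdb_signal_line)
  fmts <- vapply(sig, `[[`, character(1), "format")
  if (!all(fmts == "16")) {
    stop("unsupported WFDB signal format(s): ",
         paste(unique(setdiff(fmts, "16")), collapse = ", "))
  }
  datfiles <- unique(vapply(sig, `[[`, character(1), "file"))
  if (length(datfiles) != 1L) stop("multi-file WFDB records not supported")
  datpath <- file.path(dirname(hea), datfiles)
  if (!file.exists(datpath)) stop("unreadable file: ", datpath)
  raw <- readBin(datpath, "integer", n = file.size(datpath) / 2L,
                 size = 2L, signed = TRUE, endian = "little")
  if (is.na(nsamp)) nsamp <- length(raw) %/% nsig
  mat <- matrix(raw[seq_len(nsig * nsamp)], nrow = nsig)
  leads <- vector("list", nsig)
  names(leads) <- vapply(sig, `[[`, character(1), "name")
  for (i in seq_len(nsig)) {
    g <- sig[[i]]$gain
    if (is.na(g) || g == 0) {
      stop("signal ", names(leads)[i],
           " has no gain: raw ADC units are ambiguous")
    }
    leads[[i]] <- (mat[i, ] - sig[[i]]$baseline) / g
  }
  list(record_id = record_id, fs = fs, leads = leads)
}

parse_wfdb_signal_line <- function(line) {
  tok <- strsplit(trimws(line), "\\s+")[[1L]]
  file <- tok[1L]
  format <- sub("x.*$", "", tok[2L])
  gain <- NA_real_; baseline <- 0; units <- "mV"
  if (length(tok) >= 3L) {
    gs <- tok[3L]
    m <- regmatches(gs, regexec(
      "^(-?[0-9.]+)(\\((-?[0-9]+)\\))?(/(\\S+))?$", gs))[[1L]]
    if (length(m)) {
      gain <- as.numeric(m[2L])
      if (nzchar(m[4L])) baseline <- as.numeric(m[4L])
      if (nzchar(m[6L])) units <- m[6L]
    }
  }
  if (!is.na(gain) && !units %in% c("mV", "mv")) {
    if (units %in% c("uV", "uv")) gain <- gain * 1000
    else stop("unsupported WFDB units: ", units)
  }
  # description is the last field when present; fall back to signal index
  name <- if (length(tok) >= 9L) tok[length(tok)] else paste0("sig", file)
  list(file = file, format = format, gain = gain, baseline = baseline,
       name = name)
}

#' Write a record in WFDB format
#'
#' Writes a `.hea`/`.dat` pair in format 16 with a fixed gain (default
#' 200 ADC units per mV, i.e. 5 uV quantization).
#'
#' @param record an [ecg_record()].
#' @param dir output directory.
#' @param gain ADC units per mV.
#' @return the record base path, invisibly.
#' @export
write_wfdb <- function(record, dir, gain = 200) {
  stopifnot(inherits(record, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  id <- record$record_id
  leads <- record$leads
  nsig <- length(leads)
  nsamp <- length(leads[[1L]])
  adc <- vapply(leads, function(x) {
    v <- as.integer(round(x * gain))
    pmin(pmax(v, -32768L), 32767L)
  }, integer(nsamp))
  inter <- as.integer(t(adc))          # sample-major interleaving
  dat <- paste0(id, ".dat")
  writeBin(inter, file.path(dir, dat), size = 2L, endian = "little")
  hdr <- c(
    sprintf("%s %d %g %d", id, nsig, record$sampling_rate, nsamp),
    vapply(seq_len(nsig), function(i) {
      sprintf("%s 16 %g(0)/mV 16 0 %d 0 0 %s",
              dat, gain, adc[1L, i], names(leads)[i])
    }, character(1)),
    sprintf("# label %s", record$label)
  )
  writeLines(hdr, file.path(dir, paste0(id, ".hea")))
  invisible(file.path(dir, id))
}
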