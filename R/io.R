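#' Read an FHR record from a two-column CSV file
#'
#' Expects a comma-delimited file with header `time_s,fhr_bpm`. The time
#' column must be uniformly sampled; the sampling rate is inferred from the
#' median time step and the file is rejected if any step deviates from it by
#' more than `tolerance` (relative).
#'
#' @param path File path.
#' @param record_id Identifier; defaults to the file name without extension.
#' @param ph,label Optional metadata to attach.
#' @param tolerance Maximum allowed relative deviation of any time step from
#'   the median step (default 0.01).
#' @return An [fhr_record].
#' @export
read_csv_record <- function(path, record_id = NULL, ph = NA_real_,
                            label = NA_character_, tolerance = 0.01) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("time_s", "fhr_bpm") %in% names(df)))
    abort("expected columns `time_s` and `fhr_bpm`")
  if (nrow(df) == 0) abort("empty record")
  # parse with base R (correctly rounded) so the write/read pair is exact
  df$time_s <- suppressWarnings(as.numeric(df$time_s))
  df$fhr_bpm <- suppressWarnings(as.numeric(df$fhr_bpm))
  if (anyNA(df$time_s) || anyNA(df$fhr_bpm))
    abort("non-numeric cells in record file")
  fs <- NA_real_
  if (nrow(df) > 1) {
    dt <- diff(df$time_s)
    dt0 <- median(dt)
    if (dt0 <= 0 || any(abs(dt - dt0) > tolerance * dt0))
      abort("non-uniform sampling: time steps deviate beyond tolerance")
    fs <- 1 / dt0
  }
  fhr_record(df$fhr_bpm, fs = if (is.na(fs)) 4 else fs,
             record_id = record_id %||% sub("\\.[^.]*$", "", basename(path)),
             ph = ph, label = label)
}

#' Write an FHR record to CSV
#'
#' Writes the `time_s,fhr_bpm` dialect read by [read_csv_record()]; values are
#' written with shortest-round-trip precision so write-then-read reproduces
#' the samples exactly.
#'
#' @param record An [fhr_record].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_csv_record <- function(record, path) {
  stopifnot(is_fhr_record(record))
  if (length(record$samples) == 0) abort("empty record")
  df <- as_tibble(record)
  # 17 significant digits guarantee an exact double round trip
  out <- tibble(time_s = sprintf("%.17g", df$time_s),
                fhr_bpm = sprintf("%.17g", df$fhr_bpm))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# Parse one WFDB signal-specification line (format 16 only).
parse_wfdb_sigline <- function(line) {
  f <- strsplit(trimws(line), "[ \t]+")[[1]]
  fmt <- sub("[x:+].*$", "", f[2])
  gain <- 200; baseline <- NA_real_
  if (length(f) >= 3) {
    g <- sub("/.*$", "", f[3])
    if (grepl("\\(", g)) {
      baseline <- as.numeric(sub("^.*\\(([-0-9.]+)\\).*$", "\\1", g))
      g <- sub("\\(.*$", "", g)
    }
    gain <- as.numeric(g)
    if (!is.finite(gain) || gain == 0) gain <- 200
  }
  adc_zero <- if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else 0
  desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else ""
  list(file = f[1], fmt = fmt, gain = gain,
       baseline = if (is.na(baseline)) adc_zero %||% 0 else baseline,
       desc = desc)
}

#' Read an FHR record from local WFDB files
#'
#' Reads a PhysioNet WFDB header (`.hea`) plus its 16-bit signal file, as
#' distributed by the CTU-UHB intrapartum cardiotocography database. The FHR
#' channel is selected by description (first channel whose description
#' contains `"FHR"`, case-insensitively; otherwise the first channel). The
#' umbilical-artery pH is parsed from `#`-comment lines of the form
#' `#<key> <value>`; the key name is configurable because header conventions
#' vary. No network access is performed.
#'
#' @param path Path to the `.hea` header file (with or without extension).
#' @param ph_key Clinical-note key holding the pH (default `"pH"`).
#' @return An [fhr_record]; `ph` is `NA` when the header has no pH note.
#' @export
read_physionet_record <- function(path, ph_key = "pH") {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) abort(sprintf("unreadable header: %s", hea))
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  comments <- grep("^\\s*#", lines, value = TRUE)
  lines <- grep("^\\s*#", lines, value = TRUE, invert = TRUE)
  if (length(lines) < 2) abort("unreadable header: no signal lines")
  hd <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  n_sig <- as.integer(hd[2])
  fs <- if (length(hd) >= 3) as.numeric(sub("/.*$", "", hd[3])) else 250
  n_samp <- if (length(hd) >= 4) as.integer(hd[4]) else NA_integer_
  if (!is.finite(fs) || fs <= 0) abort("unreadable header: bad sampling rate")
  if (fs != 4)
    warn(sprintf("header declares fs = %g Hz (CTU-UHB records are 4 Hz); using the header value", fs))
  sigs <- lapply(lines[2:(1 + n_sig)], parse_wfdb_sigline)
  descs <- vapply(sigs, `[[`, "", "desc")
  ch <- grep("FHR", descs, ignore.case = TRUE)[1]
  if (is.na(ch)) {
    if (any(nzchar(descs))) abort("missing FHR channel")
    ch <- 1L
  }
  if (sigs[[ch]]$fmt != "16")
    abort(sprintf("unsupported WFDB format %s (only 16 is supported)",
                  sigs[[ch]]$fmt))
  dat <- file.path(dirname(hea), sigs[[ch]]$file)
  if (!file.exists(dat)) abort(sprintf("missing signal file: %s", dat))
  raw <- readBin(dat, "integer", n = file.info(dat)$size / 2, size = 2,
                 endian = "little", signed = TRUE)
  # format 16 interleaves channels sample by sample
  same_file <- vapply(sigs, function(s) identical(s$file, sigs[[ch]]$file),
                      logical(1))
  stride <- sum(same_file)
  offset <- cumsum(same_file)[ch]
  adc <- raw[seq.int(offset, length(raw), by = stride)]
  if (!is.na(n_samp)) adc <- adc[seq_len(min(n_samp, length(adc)))]
  bpm <- (adc - sigs[[ch]]$baseline) / sigs[[ch]]$gain
  bpm[!is.finite(bpm) | bpm < 0] <- 0
  ph <- NA_real_
  pat <- sprintf("^\\s*#\\s*%s\\b", ph_key)
  hit <- grep(pat, comments, value = TRUE)
  if (length(hit))
    ph <- suppressWarnings(as.numeric(trimws(sub(pat, "", hit[1]))))
  fhr_record(bpm, fs = fs,
             record_id = sub("\\.hea$", "", basename(hea)), ph = ph)
}

#' Save a recurrence-plot image dataset
#'
#' Writes each image as an 8-bit grayscale PNG plus a `manifest.csv` whose row
#' order defines the dataset order on reload. Intensities are quantised to
#' 8 bits at save time so the save/load round trip is pixel-identical.
#'
#' @param images List of `rp_image` objects (or numeric matrices in \[0,1\]).
#' @param meta Tibble with one row per image; must contain `record_id`, `m`,
#'   `tau`, `k` and `label` columns.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble (with a `file` column), invisibly.
#' @export
save_image_dataset <- function(images, meta, dir) {
  if (!is.list(images)) abort("`images` must be a list of images")
  need <- c("record_id", "m", "tau", "k", "label")
  if (!all(need %in% names(meta)))
    abort(sprintf("`meta` must contain columns: %s", paste(need, collapse = ", ")))
  if (length(images) != nrow(meta))
    abort("`images` and `meta` lengths differ")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s_m%d_t%d_k%d.png", meta$record_id, meta$m, meta$tau,
                   meta$k)
  for (i in seq_along(images)) {
    img <- round(unclass(images[[i]]) * 255) / 255
    png::writePNG(img, file.path(dir, files[i]))
  }
  manifest <- dplyr::mutate(meta, file = files)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"), progress = FALSE)
  invisible(manifest)
}

#' Load a recurrence-plot image dataset
#'
#' Reads `manifest.csv` and the PNGs it lists, in manifest order (loading
#' never reorders).
#'
#' @param dir Dataset directory written by [save_image_dataset()].
#' @return A list with `images` (list of `rp_image`), `meta` (the manifest
#'   tibble) and `params` (unique (m, tau, k) combinations present).
#' @export
load_image_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) abort(sprintf("no manifest at %s", mf))
  manifest <- readr::read_csv(mf, show_col_types = FALSE, progress = FALSE)
  images <- lapply(manifest$file, function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) abort(sprintf("manifest references missing file: %s", f))
    img <- png::readPNG(p)
    if (length(dim(img)) == 3) img <- img[, , 1]
    structure(img, class = c("rp_image", "matrix"))
  })
  list(images = images, meta = manifest,
       params = dplyr::distinct(manifest, .data$m, .data$tau, .data$k))
}

#' Write a synthetic cohort to disk
#'
#' One CSV per record (via [write_csv_record()]) plus a `cohort.csv` manifest
#' with columns `record_id`, `file`, `class`, `ph`, `seed`.
#'
#' @param cohort A [generate_cohort()] tibble.
#' @param dir Output directory.
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- paste0(cohort$record_id, ".csv")
  for (i in seq_len(nrow(cohort)))
    write_csv_record(cohort$record[[i]], file.path(dir, files[i]))
  manifest <- tibble(record_id = cohort$record_id, file = files,
                     class = cohort$label, ph = cohort$ph,
                     seed = cohort$seed)
  readr::write_csv(manifest, file.path(dir, "cohort.csv"), progress = FALSE)
  invisible(manifest)
}
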