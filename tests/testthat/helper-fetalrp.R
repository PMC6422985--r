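# Shared fixtures and independent oracles for the test suite.

# A clean (artifact-free) synthetic record.
clean_record <- function(duration_s = 120, seed = 1,
                         class_label = "normal", ...) {
  generate_fhr(synth_config(class_label, duration_s = duration_s, seed = seed,
                            dropout_rate = 0, spike_rate = 0, ...))
}

# Brute-force k-th nearest-neighbour thresholds: full pairwise distances,
# full sort per row, self excluded.
oracle_knn_eps <- function(traj, k) {
  traj <- as.matrix(traj)
  N <- nrow(traj)
  vapply(seq_len(N), function(i) {
    d <- sqrt(colSums((t(traj[-i, , drop = FALSE]) - traj[i, ])^2))
    sort(d)[k]
  }, numeric(1))
}

# Brute-force recurrence matrix: explicit double loop over point pairs.
oracle_recurrence <- function(traj, epsilon) {
  traj <- as.matrix(traj)
  N <- nrow(traj)
  eps <- rep(epsilon, length.out = N)
  R <- matrix(0L, N, N)
  for (i in seq_len(N))
    for (j in seq_len(N))
      if (sqrt(sum((traj[i, ] - traj[j, ])^2)) < eps[i]) R[i, j] <- 1L
  R
}

# Exhaustive pairwise-concordance AUC: P(pos > neg) + 0.5 P(tie).
oracle_auc <- function(scores, truth, positive = "normal") {
  sp <- scores[truth == positive]
  sn <- scores[truth != positive]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Synthetic 64 x 64 images that are linearly separable by construction:
# class "normal" lights up the top-left quadrant, "pathological" the
# bottom-right, plus uniform noise.
separable_images <- function(n, seed = 1) {
  withr::with_seed(seed, {
    labels <- rep(c("normal", "pathological"), length.out = n)
    images <- lapply(labels, function(lb) {
      m <- matrix(runif(64 * 64, 0, 0.2), 64, 64)
      if (lb == "normal") m[1:24, 1:24] <- m[1:24, 1:24] + 0.6
      else m[41:64, 41:64] <- m[41:64, 41:64] + 0.6
      structure(pmin(m, 1), class = c("rp_image", "matrix"))
    })
    list(images = images, labels = labels)
  })
}

# Tiny WFDB (header + 16-bit signal) fixture written into `dir`.
write_wfdb_fixture <- function(dir, name = "rec1", fs = 4,
                               ph_line = "#pH 7.12", n = 16,
                               fhr_desc = "FHR") {
  adc <- as.integer(round(seq(120, 150, length.out = n) * 100))
  uc <- as.integer(seq(5, 20, length.out = n))
  hea <- c(
    sprintf("%s 2 %g %d", name, fs, n),
    sprintf("%s.dat 16 100/bpm 16 0 %d 0 0 %s", name, adc[1], fhr_desc),
    sprintf("%s.dat 16 1/mmHg 16 0 %d 0 0 UC", name, uc[1]),
    ph_line)
  writeLines(hea, file.path(dir, paste0(name, ".hea")))
  inter <- as.integer(rbind(adc, uc))
  writeBin(inter, file.path(dir, paste0(name, ".dat")), size = 2,
           endian = "little")
  list(bpm = adc / 100, n = n)
}
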