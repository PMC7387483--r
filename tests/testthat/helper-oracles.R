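# Independent brute-force oracles and small generators used across tests.

AA_LETTERS <- c("A","R","N","D","C","Q","E","G","H","I",
                "L","K","M","F","P","S","T","W","Y","V")

random_peptide <- function(n, letters = AA_LETTERS) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Direct per-window evaluator: recomputes every quantity from raw counts and
# trig sums, applies the box bounds explicitly, window by window.
oracle_scan_windows <- function(seq, box, scale, polar_set) {
  n <- nchar(seq)
  w <- min(box$window_len, n)
  chars_all <- strsplit(seq, "", fixed = TRUE)[[1]]
  hits <- list()
  for (s in 0:(n - w)) {
    chars <- chars_all[(s + 1):(s + w)]
    if (any(!chars %in% names(scale))) next  # X etc: fail closed
    if (box$forbid_cys && any(chars == "C")) next
    h <- unclass(scale)[chars]
    H <- sum(h) / w
    ang <- (0:(w - 1)) * 100 * pi / 180
    muH <- sqrt(sum(h * sin(ang))^2 + sum(h * cos(ang))^2) / w
    z <- sum(chars == "K") + sum(chars == "R") -
      sum(chars == "D") - sum(chars == "E")
    if (H < box$H_min || H > box$H_max) next
    if (muH < box$muH_min || muH > box$muH_max) next
    if (z < box$z_min || z > box$z_max) next
    if (!is.na(box$min_polar) && sum(chars %in% polar_set) < box$min_polar) next
    if (!is.na(box$min_uncharged_STNQH) &&
        sum(chars %in% c("S","T","N","Q","H")) < box$min_uncharged_STNQH) next
    if (!is.na(box$min_gly) && sum(chars == "G") < box$min_gly) next
    if (!is.na(box$max_charged) &&
        sum(chars %in% c("D","E","K","R")) > box$max_charged) next
    hits[[length(hits) + 1]] <- c(start = s, H = H, muH = muH, z = z)
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), H = numeric(), muH = numeric(),
                      z = numeric()))
  }
  as.data.frame(do.call(rbind, hits))
}

# Naive per-position window averaging for the aggregation profile.
oracle_a4v <- function(a3v, window, end_mode) {
  n <- length(a3v)
  h <- window %/% 2
  a4v <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (end_mode == "full_windows_only" && (i - h < 1 || i + h > n)) next
    idx <- max(1, i - h):min(n, i + h)
    a4v[i] <- mean(a3v[idx])
  }
  a4v
}

revcomp_dna <- function(seq) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = ""))
}

# Naive Match scorer: evaluates every offset and strand independently with
# explicit loops over positions.
oracle_match_scan <- function(seq, pwm, core_cutoff, matrix_cutoff) {
  L <- pwm$length
  n <- nchar(seq)
  f <- pwm$freqs
  I <- pwm$info
  score_word <- function(word, positions) {
    cur <- 0; mn <- 0; mx <- 0
    for (i in positions) {
      cur <- cur + I[i] * f[i, word[i]]
      mn <- mn + I[i] * min(f[i, ])
      mx <- mx + I[i] * max(f[i, ])
    }
    (cur - mn) / (mx - mn)
  }
  out <- list()
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (o in 0:(n - L)) {
    word <- chars[(o + 1):(o + L)]
    if (any(!word %in% c("A","C","G","T"))) next
    for (strand in c("+", "-")) {
      wd <- if (strand == "+") word else rev(chartr("ACGT", "TGCA", word))
      msim <- score_word(wd, seq_len(L))
      csim <- score_word(wd, pwm$core)
      if (csim >= core_cutoff && msim >= matrix_cutoff) {
        out[[length(out) + 1]] <- data.frame(
          position = o - n, strand = strand, core_sim = csim,
          matrix_sim = msim, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(position = integer(), strand = character(),
                      core_sim = numeric(), matrix_sim = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$position, res$strand), ]
}

# Write a toy count-matrix file and load it.
toy_pwm <- function(counts, dir = tempdir()) {
  path <- tempfile(fileext = ".pwm", tmpdir = dir)
  writeLines(apply(counts, 1, paste, collapse = " "), path)
  load_pwm(path)
}

fp_scale <- aa_scale("fauchere_pliska")
a3v_scale <- aa_scale("aggrescan_a3v")
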