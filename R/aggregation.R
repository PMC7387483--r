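#' AGGRESCAN-style window size for a sequence length
#'
#' Window sizes follow the AGGRESCAN publication: 5 for fewer than 75
#' residues, 7 for 75-175, 9 for 176-300, 11 above 300.
#'
#' @param n Sequence length in residues.
#' @return Odd integer window size.
#' @export
aggrescan_window <- function(n) {
  if (n < 75L) 5L else if (n <= 175L) 7L else if (n <= 300L) 9L else 11L
}

#' Aggregation-propensity profile and Na4vSS summary
#'
#' Computes per-residue aggregation propensities (`a3v`, from the shipped
#' AGGRESCAN scale), their sliding-window averages (`a4v`), the sequence sum
#' `a4vSS` and the length-normalized summary `Na4vSS = 100 * a4vSS / N` used
#' as the screening gate.
#'
#' End handling: with `end_mode = "truncate"` (default) the window shrinks
#' asymmetrically at the termini so every residue receives an `a4v` value;
#' with `"full_windows_only"` only positions with a complete centered window
#' contribute (the sum is still normalized by the full length `N`).
#'
#' @param seq Amino-acid string, length >= 3.
#' @param scale a3v [aa_scale()] (default the shipped AGGRESCAN values).
#' @param window Odd integer window size, or `"auto"` to choose by length
#'   via [aggrescan_window()].
#' @param end_mode `"truncate"` or `"full_windows_only"`.
#' @return A list of class `"aggregation_profile"` with `a3v`, `a4v`
#'   (positions, NA where not computed in full-window mode), `a4vSS`,
#'   `Na4vSS`, `window`, `end_mode`.
#' @examples
#' aggregation_profile("FRRRRRRRRHWHHHHHYHYHHHRRRRRRRRRW")$Na4vSS
#' @export
aggregation_profile <- function(seq, scale = aa_scale("aggrescan_a3v"),
                                window = "auto",
                                end_mode = c("truncate",
                                             "full_windows_only")) {
  check_seq(seq)
  end_mode <- match.arg(end_mode)
  n <- nchar(seq)
  if (n < 3L) stop("sequence shorter than 3 residues", call. = FALSE)
  if (identical(window, "auto")) window <- aggrescan_window(n)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be an odd positive integer", call. = FALSE)
  }
  if (end_mode == "full_windows_only" && n < window) {
    stop("sequence shorter than the window in full_windows_only mode",
         call. = FALSE)
  }
  a3v <- scale_values(seq, scale)
  h <- window %/% 2L
  cs <- c(0, cumsum(a3v))
  a4v <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    if (end_mode == "full_windows_only" && (i - h < 1L || i + h > n)) next
    a4v[i] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  a4vSS <- sum(a4v, na.rm = TRUE)
  structure(list(a3v = a3v, a4v = a4v, a4vSS = a4vSS,
                 Na4vSS = 100 * a4vSS / n,
                 window = window, end_mode = end_mode),
            class = "aggregation_profile")
}

#' @export
print.aggregation_profile <- function(x, ...) {
  cat(sprintf(
    "aggregation profile (N=%d, window=%d, %s): a4vSS=%.3f  Na4vSS=%.2f\n",
    length(x$a3v), x$window, x$end_mode, x$a4vSS, x$Na4vSS))
  invisible(x)
}

#' Aggregation gate on Na4vSS
#'
#' Pass iff `lo <= Na4vSS <= hi`, bounds inclusive. The screening default is
#' the box \[-30, 30\]; the broader literature range for antimicrobial
#' peptides \[-40, 60\] is available by passing those bounds.
#'
#' @param profile An [aggregation_profile()] (or a bare Na4vSS number).
#' @param lo,hi Inclusive bounds.
#' @return Logical scalar.
#' @export
na4vss_gate <- function(profile, lo = -30, hi = 30) {
  v <- if (inherits(profile, "aggregation_profile")) profile$Na4vSS
       else as.numeric(profile)
  v >= lo && v <= hi
}
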