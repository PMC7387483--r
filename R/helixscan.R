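#' Threshold box for helical-wheel window classification
#'
#' A box is the set of inclusive bounds on hydrophobicity, hydrophobic
#' moment and net charge, plus optional composition rules, that a sliding
#' window must satisfy to be classified as a helix of the given class.
#'
#' @param H_min,H_max Bounds on mean hydrophobicity.
#' @param muH_min,muH_max Bounds on hydrophobic moment.
#' @param z_min,z_max Bounds on net charge.
#' @param min_polar,min_uncharged_STNQH,min_gly,max_charged Composition
#'   rules; set to `NA` to disable an individual rule.
#' @param forbid_cys Windows containing cysteine always fail when `TRUE`.
#' @param window_len Window length in residues.
#' @param klass Class label attached to passing windows.
#' @return A list of class `"threshold_box"`.
#' @export
threshold_box <- function(H_min, H_max, muH_min, muH_max, z_min, z_max,
                          min_polar = NA, min_uncharged_STNQH = NA,
                          min_gly = NA, max_charged = NA,
                          forbid_cys = TRUE, window_len = 18L,
                          klass = "cationic") {
  stopifnot(H_min <= H_max, muH_min <= muH_max, z_min <= z_max,
            window_len >= 1L)
  structure(list(H_min = H_min, H_max = H_max,
                 muH_min = muH_min, muH_max = muH_max,
                 z_min = z_min, z_max = z_max,
                 min_polar = min_polar,
                 min_uncharged_STNQH = min_uncharged_STNQH,
                 min_gly = min_gly, max_charged = max_charged,
                 forbid_cys = forbid_cys,
                 window_len = as.integer(window_len),
                 klass = klass),
            class = "threshold_box")
}

#' Default cationic amphipathic helix box
#'
#' Hydrophobicity 0 to 0.6, hydrophobic moment 0.1 to 1.0, net charge +3 to
#' +10, at least 6 polar and 1 uncharged (S/T/N/Q/H) residues, at most 12
#' charged residues, no minimum glycine requirement, cysteine forbidden;
#' 18-residue window. These are the screening parameters calibrated on
#' known LCAMPs (cecropin A, moricin, Ci-PAP-A, Ci-MAM-A, dermaseptin SI,
#' PGLa).
#' @return A `"threshold_box"`.
#' @export
cationic_box <- function() {
  threshold_box(H_min = 0, H_max = 0.6, muH_min = 0.1, muH_max = 1.0,
                z_min = 3L, z_max = 10L,
                min_polar = 6L, min_uncharged_STNQH = 1L,
                min_gly = 0L, max_charged = 12L,
                forbid_cys = TRUE, window_len = 18L, klass = "cationic")
}

#' Default anionic helix box
#'
#' Hydrophobicity -0.7 to 0.4, hydrophobic moment 0 to 0.5, net charge -10
#' to -3; composition rules off except cysteine exclusion. Used to locate
#' the anionic helical proregion of LCAMP precursors.
#' @return A `"threshold_box"`.
#' @export
anionic_box <- function() {
  threshold_box(H_min = -0.7, H_max = 0.4, muH_min = 0, muH_max = 0.5,
                z_min = -10L, z_max = -3L,
                forbid_cys = TRUE, window_len = 18L, klass = "anionic")
}

#' Test whether a profile satisfies a threshold box
#'
#' All bounds are inclusive on both ends. A sequence containing cysteine
#' fails when the box forbids it; composition rules set to `NA` are skipped.
#'
#' @param profile A [physchem_profile()].
#' @param box A [threshold_box()].
#' @return Logical scalar.
#' @export
box_pass <- function(profile, box) {
  p <- profile
  if (isTRUE(box$forbid_cys) && p$n_cys > 0L) return(FALSE)
  ok <- p$H >= box$H_min && p$H <= box$H_max &&
    p$muH >= box$muH_min && p$muH <= box$muH_max &&
    p$z >= box$z_min && p$z <= box$z_max
  if (!ok) return(FALSE)
  if (!is.na(box$min_polar) && p$n_polar < box$min_polar) return(FALSE)
  if (!is.na(box$min_uncharged_STNQH) &&
      p$n_uncharged_STNQH < box$min_uncharged_STNQH) return(FALSE)
  if (!is.na(box$min_gly) && p$n_gly < box$min_gly) return(FALSE)
  if (!is.na(box$max_charged) && p$n_charged > box$max_charged) return(FALSE)
  TRUE
}

#' Slide a window along a sequence and keep windows inside a threshold box
#'
#' Generates one window per start offset (step 1). Sequences shorter than
#' the window length are evaluated as a single whole-sequence window, so
#' short mature peptides are still screened. Windows containing `X` (or any
#' residue without a scale value) fail closed.
#'
#' @param seq Mature amino-acid string.
#' @param box A [threshold_box()].
#' @param scale Hydrophobicity [aa_scale()].
#' @param polar_set Polar-residue set for composition counts.
#' @param parent_id Identifier copied into the output.
#' @return Data.frame of passing windows: `parent_id`, `start`, `end`
#'   (0-based half-open), `seq`, `H`, `muH`, `z`, `klass`.
#' @export
scan_windows <- function(seq, box, scale = aa_scale("fauchere_pliska"),
                         polar_set = default_polar_set(),
                         parent_id = NA_character_) {
  check_seq(seq)
  n <- nchar(seq)
  w <- min(box$window_len, n)
  starts <- 0:(n - w)
  rows <- lapply(starts, function(s) {
    sub <- substr(seq, s + 1L, s + w)
    prof <- tryCatch(physchem_profile(sub, scale, polar_set),
                     error = function(e) NULL)  # X or unknown residue: fail
    if (is.null(prof) || !box_pass(prof, box)) return(NULL)
    data.frame(parent_id = parent_id, start = s, end = s + w, seq = sub,
               H = prof$H, muH = prof$muH, z = prof$z,
               klass = box$klass, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_windows())
  do.call(rbind, rows)
}

#' @noRd
empty_windows <- function() {
  data.frame(parent_id = character(), start = integer(), end = integer(),
             seq = character(), H = numeric(), muH = numeric(),
             z = integer(), klass = character(), stringsAsFactors = FALSE)
}

#' Merge overlapping or adjacent passing windows into segments
#'
#' Windows of the same class whose intervals overlap or touch are merged
#' into maximal segments. Each segment records its best window: highest
#' hydrophobic moment, ties broken by smaller start.
#'
#' @param windows Output of [scan_windows()].
#' @return Data.frame of segments: `parent_id`, `start`, `end` (0-based
#'   half-open), `klass`, `best_start`, `best_end`, `best_seq`, `best_muH`.
#' @export
merge_windows <- function(windows) {
  empty <- data.frame(parent_id = character(), start = integer(),
                      end = integer(), klass = character(),
                      best_start = integer(), best_end = integer(),
                      best_seq = character(), best_muH = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(windows) || nrow(windows) == 0L) return(empty)
  out <- empty
  for (key in unique(paste(windows$parent_id, windows$klass, sep = "\r"))) {
    grp <- windows[paste(windows$parent_id, windows$klass, sep = "\r") == key, ]
    ir <- IRanges::reduce(IRanges::IRanges(start = grp$start + 1L,
                                           end = grp$end))
    for (k in seq_along(ir)) {
      s0 <- IRanges::start(ir)[k] - 1L
      e0 <- IRanges::end(ir)[k]
      members <- grp[grp$start >= s0 & grp$end <= e0, ]
      members <- members[order(-members$muH, members$start), ]
      best <- members[1L, ]
      out <- rbind(out, data.frame(
        parent_id = best$parent_id, start = s0, end = e0,
        klass = best$klass, best_start = best$start, best_end = best$end,
        best_seq = best$seq, best_muH = best$muH, stringsAsFactors = FALSE))
    }
  }
  out[order(out$parent_id, out$start), , drop = FALSE]
}

#' Locate the most C-terminal anionic helical segment
#'
#' Scans with the anionic box (composition rules off, cysteine still
#' excluded), merges passing windows and returns the segment closest to the
#' C-terminus, or `NULL` when none exists. LCAMP precursors carry such an
#' anionic proregion after the cationic active peptide.
#'
#' @param mature_seq Signal-less precursor sequence.
#' @param box Anionic [threshold_box()].
#' @inheritParams scan_windows
#' @return One-row segment data.frame (see [merge_windows()]) or `NULL`.
#' @export
find_anionic_tail <- function(mature_seq, box = anionic_box(),
                              scale = aa_scale("fauchere_pliska"),
                              parent_id = NA_character_) {
  wins <- scan_windows(mature_seq, box, scale, parent_id = parent_id)
  segs <- merge_windows(wins)
  if (nrow(segs) == 0L) return(NULL)
  segs <- segs[order(-segs$end, -segs$start), , drop = FALSE]
  segs[1L, , drop = FALSE]
}

#' Helicity confirmation of a candidate segment
#'
#' Built-in `"propensity"` method: mean Chou-Fasman helix propensity over
#' the segment must reach `min_mean` and the fraction of residues with
#' propensity >= 1.0 must reach `min_helix_frac`. The `"external"` method
#' instead takes a per-residue secondary-structure string (H/E/C) from any
#' predictor and computes the H fraction.
#'
#' @param segment_seq Amino-acid string.
#' @param method `"propensity"` or `"external"`.
#' @param min_helix_frac Minimum helix fraction to pass.
#' @param min_mean Minimum mean propensity (propensity method only).
#' @param external_ss Per-residue H/E/C string (external method only).
#' @param scale Helix-propensity [aa_scale()].
#' @return List with `pass`, `helix_frac`, `mean_propensity` (NA for
#'   external) and `method`.
#' @export
helicity_check <- function(segment_seq,
                           method = c("propensity", "external"),
                           min_helix_frac = 0.5, min_mean = 1.03,
                           external_ss = NULL,
                           scale = aa_scale("chou_fasman_helix")) {
  method <- match.arg(method)
  check_seq(segment_seq)
  if (method == "external") {
    if (is.null(external_ss)) {
      stop("method='external' requires an external_ss prediction string",
           call. = FALSE)
    }
    if (nchar(external_ss) != nchar(segment_seq)) {
      stop("external_ss length does not match segment", call. = FALSE)
    }
    ss <- strsplit(toupper(external_ss), "", fixed = TRUE)[[1]]
    frac <- mean(ss == "H")
    return(list(pass = frac >= min_helix_frac, helix_frac = frac,
                mean_propensity = NA_real_, method = method))
  }
  v <- tryCatch(scale_values(segment_seq, scale), error = function(e) NULL)
  if (is.null(v)) {  # X residues: fail closed
    return(list(pass = FALSE, helix_frac = 0, mean_propensity = NA_real_,
                method = method))
  }
  frac <- mean(v >= 1.0)
  m <- mean(v)
  list(pass = m >= min_mean && frac >= min_helix_frac,
       helix_frac = frac, mean_propensity = m, method = method)
}
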