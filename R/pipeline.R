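#' Screening configuration
#'
#' Builds the full funnel configuration with the published screening
#' parameters as defaults. Override any key by name; unknown keys are
#' rejected. Stages may be disabled (`disabled_stages`) but never
#' reordered.
#'
#' @param ... Named overrides of the default keys (see Details).
#' @details Keys: `min_len`/`max_len` (precursor length gate, 50-100),
#'   `cationic`/`anionic` ([threshold_box()]es), `helicity` (list: `method`,
#'   `min_helix_frac`, `min_mean`, `external` per-id H/E/C strings),
#'   `aggregation` (list: `window`, `end_mode`, `lo`, `hi`, `on` =
#'   `"segment"` or `"window"`), `predictors` (per-stage list with `mode` =
#'   `"heuristic"`/`"external"`/`"off"`, `path`, plus stage-specific knobs),
#'   `scales` (scale names or file paths), `polar_set`, `pwm` (cut-offs),
#'   `disabled_stages`, `seed`.
#' @return A list of class `"screen_config"`.
#' @export
screen_config <- function(...) {
  defaults <- list(
    min_len = 50L, max_len = 100L,
    cationic = cationic_box(),
    anionic = anionic_box(),
    helicity = list(method = "propensity", min_helix_frac = 0.5,
                    min_mean = 1.03, external = NULL),
    aggregation = list(window = "auto", end_mode = "truncate",
                       lo = -30, hi = 30, on = "segment"),
    predictors = list(
      signal = list(mode = "heuristic", path = NULL, map = NULL),
      tm = list(mode = "heuristic", path = NULL, map = NULL,
                threshold = 1.6, window = 19L),
      localization = list(mode = "off", path = NULL, map = NULL,
                          accepted = c("Extracellular", "Secreted"))),
    scales = list(hydrophobicity = "fauchere_pliska",
                  aggregation = "aggrescan_a3v",
                  hydropathy = "kyte_doolittle",
                  helix = "chou_fasman_helix"),
    polar_set = default_polar_set(),
    pwm = list(core_cutoff = 0.75, matrix_cutoff = 0.8),
    disabled_stages = character(),
    seed = 1L)
  overrides <- list(...)
  config <- merge_config(defaults, overrides, path = "")
  validate_config(config)
  structure(config, class = "screen_config")
}

#' @noRd
merge_config <- function(defaults, overrides, path) {
  if (length(overrides) == 0L) return(defaults)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)),
                collapse = ", "), call. = FALSE)
  }
  for (k in names(overrides)) {
    if (is.list(defaults[[k]]) && is.list(overrides[[k]]) &&
        !inherits(defaults[[k]], "threshold_box") &&
        !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], overrides[[k]],
                                    paste0(path, ".", k))
    } else {
      defaults[[k]] <- overrides[[k]]
    }
  }
  defaults
}

#' @noRd
validate_config <- function(config) {
  stopifnot(config$min_len <= config$max_len,
            inherits(config$cationic, "threshold_box"),
            inherits(config$anionic, "threshold_box"))
  bad <- setdiff(config$disabled_stages, FUNNEL_STAGES)
  if (length(bad)) {
    stop("unknown stage(s) in disabled_stages: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (st in c("signal", "tm", "localization")) {
    p <- config$predictors[[st]]
    if (identical(p$mode, "external") && is.null(p$path) &&
        is.null(p$map)) {
      stop("predictor stage '", st,
           "' is set to external mode but no file was given", call. = FALSE)
    }
  }
  invisible(config)
}

#' Read a screening configuration from a YAML file
#'
#' Threshold boxes appear in YAML as plain mappings of [threshold_box()]
#' arguments. Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return A `"screen_config"`.
#' @export
read_screen_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (b in c("cationic", "anionic")) {
    if (!is.null(raw[[b]]) && !inherits(raw[[b]], "threshold_box")) {
      raw[[b]] <- do.call(threshold_box, raw[[b]])
    }
  }
  do.call(screen_config, raw)
}

#' @noRd
FUNNEL_STAGES <- c("length", "secretory", "tm", "cys", "amphipathic",
                   "helical", "aggregation", "localization")

#' Run the full LCAMP screening funnel
#'
#' Applies the eight stages in fixed order: precursor length, signal
#' peptide, transmembrane elimination, cysteine exclusion over the whole
#' mature region, cationic amphipathic window scan, helicity confirmation,
#' aggregation (Na4vSS) gate, and subcellular localization. Deterministic
#' given inputs and configuration.
#'
#' @param proteome Protein record table from [read_fasta()].
#' @param config A [screen_config()].
#' @param verbose Emit per-stage in/out counts as messages.
#' @return List with `report` (one row per input record; coordinates
#'   1-based inclusive on the precursor) and `counts` (named integer
#'   vector: `input_n` then survivors after each stage; non-increasing).
#' @export
run_funnel <- function(proteome, config = screen_config(), verbose = FALSE) {
  stopifnot(inherits(config, "screen_config"))
  reset_run_state()
  scales <- list(
    hydro = aa_scale(config$scales$hydrophobicity),
    agg = aa_scale(config$scales$aggregation),
    kd = aa_scale(config$scales$hydropathy),
    helix = aa_scale(config$scales$helix))
  ext <- load_configured_predictions(config, proteome$id)
  rows <- lapply(seq_len(nrow(proteome)), function(i) {
    screen_record(proteome[i, , drop = FALSE], config, scales, ext)
  })
  report <- do.call(rbind, c(list(empty_report()), rows))
  report <- annotate_architecture(report)
  n_in <- nrow(proteome)
  reached <- factor(report$stage_reached,
                    levels = c(FUNNEL_STAGES, "candidate"))
  # survivors after stage k = records whose first failure is later than k
  fail_idx <- as.integer(reached)  # 9 == candidate
  counts <- c(input_n = n_in,
              setNames(vapply(seq_along(FUNNEL_STAGES),
                              function(k) sum(fail_idx > k), integer(1)),
                       FUNNEL_STAGES))
  if (verbose) {
    prev <- n_in
    for (st in FUNNEL_STAGES) {
      message(sprintf("stage %-13s in=%d out=%d", st, prev, counts[[st]]))
      prev <- counts[[st]]
    }
  }
  list(report = report, counts = counts)
}

#' @noRd
load_configured_predictions <- function(config, proteome_ids) {
  out <- list(signal = NULL, tm = NULL, localization = NULL)
  kinds <- c(signal = "signalp", tm = "tm", localization = "localization")
  for (st in names(kinds)) {
    p <- config$predictors[[st]]
    if (identical(p$mode, "external")) {
      out[[st]] <- if (!is.null(p$map)) p$map else {
        load_external_predictions(p$path, kinds[[st]], proteome_ids)
      }
    }
  }
  out
}

#' @noRd
empty_report <- function() {
  data.frame(id = character(), stage_reached = character(),
             cleavage = integer(), window_start = integer(),
             window_end = integer(), window_seq = character(),
             H = numeric(), muH = numeric(), z = integer(),
             Na4vSS = numeric(), anionic_start = integer(),
             anionic_end = integer(), architecture = logical(),
             verdict = character(), stringsAsFactors = FALSE)
}

#' @noRd
screen_record <- function(rec, config, scales, ext) {
  id <- rec$id; seq <- rec$seq
  on_stage <- function(st) !(st %in% config$disabled_stages)
  row <- data.frame(id = id, stage_reached = "candidate",
                    cleavage = NA_integer_, window_start = NA_integer_,
                    window_end = NA_integer_, window_seq = NA_character_,
                    H = NA_real_, muH = NA_real_, z = NA_integer_,
                    Na4vSS = NA_real_, anionic_start = NA_integer_,
                    anionic_end = NA_integer_, architecture = NA,
                    verdict = "rejected", stringsAsFactors = FALSE)
  fail <- function(st) { row$stage_reached <- st; row }

  if (on_stage("length") &&
      (rec$length < config$min_len || rec$length > config$max_len)) {
    return(fail("length"))
  }
  # signal peptide -> mature sequence
  mature_off <- 0L
  if (on_stage("secretory") &&
      !identical(config$predictors$signal$mode, "off")) {
    sp <- if (identical(config$predictors$signal$mode, "external")) {
      ext$signal[[id]]
    } else {
      heuristic_signal_peptide(seq, scales$hydro)
    }
    if (is.null(sp) || !isTRUE(sp$is_secretory)) return(fail("secretory"))
    if (!is.na(sp$cleavage_after)) {
      mature_off <- sp$cleavage_after + 1L
      row$cleavage <- sp$cleavage_after + 1L  # 1-based last SP residue
    }
  }
  mature <- substr(seq, mature_off + 1L, nchar(seq))
  if (nchar(mature) < 1L) return(fail("secretory"))

  if (on_stage("tm")) {
    tm <- if (identical(config$predictors$tm$mode, "external")) {
      ext$tm[[id]]
    } else {
      heuristic_tm_filter(mature,
                          threshold = config$predictors$tm$threshold,
                          window = config$predictors$tm$window,
                          scale = scales$kd)
    }
    if (is.null(tm) || !isTRUE(tm$keep)) return(fail("tm"))
  }
  if (on_stage("cys") && grepl("C", mature, fixed = TRUE)) {
    return(fail("cys"))
  }

  # cationic amphipathic windows -> merged segments
  segs <- merge_windows(scan_windows(mature, config$cationic, scales$hydro,
                                     config$polar_set, parent_id = id))
  anio <- find_anionic_tail(mature, config$anionic, scales$hydro,
                            parent_id = id)
  if (!is.null(anio)) {
    row$anionic_start <- anio$start + mature_off + 1L
    row$anionic_end <- anio$end + mature_off
  }
  report_segment <- function(row, seg, na4vss = NA_real_) {
    prof <- physchem_profile(seg$best_seq, scales$hydro, config$polar_set)
    row$window_start <- seg$start + mature_off + 1L
    row$window_end <- seg$end + mature_off
    row$window_seq <- substr(mature, seg$start + 1L, seg$end)
    row$H <- prof$H; row$muH <- prof$muH; row$z <- prof$z
    row$Na4vSS <- na4vss
    row
  }
  if (on_stage("amphipathic") && nrow(segs) == 0L) {
    return(fail("amphipathic"))
  }
  if (nrow(segs) == 0L) return(fail_or_pass_tail(row, config, ext, id))

  if (on_stage("helical")) {
    hp <- config$helicity
    pass <- vapply(seq_len(nrow(segs)), function(k) {
      seg_seq <- substr(mature, segs$start[k] + 1L, segs$end[k])
      if (identical(hp$method, "external")) {
        ss <- hp$external[[id]]
        if (is.null(ss)) stop("helicity method 'external' without a ",
                              "prediction for '", id, "'", call. = FALSE)
        helicity_check(seg_seq, "external", hp$min_helix_frac,
                       external_ss = substr(ss, segs$start[k] + 1L,
                                            segs$end[k]))$pass
      } else {
        helicity_check(seg_seq, "propensity", hp$min_helix_frac,
                       hp$min_mean, scale = scales$helix)$pass
      }
    }, logical(1))
    if (!any(pass)) {
      best <- segs[order(-segs$best_muH, segs$start), ][1L, ]
      return(fail("helical") |> report_segment(best))
    }
    segs <- segs[pass, , drop = FALSE]
  }

  agg_seq <- function(seg) {
    if (identical(config$aggregation$on, "window")) seg$best_seq
    else substr(mature, seg$start + 1L, seg$end)
  }
  na4 <- vapply(seq_len(nrow(segs)), function(k) {
    aggregation_profile(agg_seq(segs[k, ]), scales$agg,
                        config$aggregation$window,
                        config$aggregation$end_mode)$Na4vSS
  }, numeric(1))
  if (on_stage("aggregation")) {
    ok <- na4 >= config$aggregation$lo & na4 <= config$aggregation$hi
    if (!any(ok)) {
      best <- order(-segs$best_muH, segs$start)[1L]
      return(fail("aggregation") |>
               report_segment(segs[best, ], na4[best]))
    }
    segs <- segs[ok, , drop = FALSE]
    na4 <- na4[ok]
  }
  best <- order(-segs$best_muH, segs$start)[1L]
  row <- report_segment(row, segs[best, ], na4[best])

  if (on_stage("localization") &&
      !identical(config$predictors$localization$mode, "off")) {
    map <- if (identical(config$predictors$localization$mode, "external")) {
      ext$localization
    } else NULL
    dec <- localization_gate(id, map,
                             config$predictors$localization$accepted)
    if (!isTRUE(dec$keep)) return(fail("localization"))
  }
  row$verdict <- "candidate"
  row
}

#' @noRd
fail_or_pass_tail <- function(row, config, ext, id) {
  # amphipathic stage disabled and no segments: nothing left to score
  row$stage_reached <- "candidate"
  row$verdict <- "candidate"
  row
}

#' Annotate precursor architecture
#'
#' Sets the `architecture` flag: `TRUE` when the precursor has all three
#' regions in the canonical order signal peptide, then cationic amphipathic
#' segment, then anionic helical segment (signal cleavage before the
#' cationic segment, cationic segment ending before the anionic segment
#' starts).
#'
#' @param report Report data.frame from [run_funnel()].
#' @return The report with the `architecture` column filled.
#' @export
annotate_architecture <- function(report) {
  report$architecture <- !is.na(report$cleavage) &
    !is.na(report$window_start) & !is.na(report$anionic_start) &
    report$cleavage < report$window_start &
    report$window_end < report$anionic_start
  report
}

#' Majority-rule consensus of an alignment
#'
#' Per column, emits the residue whose frequency (over all sequences,
#' including gapped rows) reaches `threshold`, otherwise `X`. Columns in
#' which gaps are the strict majority are dropped. The 80% default is the
#' majority rule used for signal-peptide family consensus sequences.
#'
#' @param aligned Character vector of equal-length gapped sequences
#'   (gap characters `-` or `.`).
#' @param threshold Majority fraction, in (0.5, 1].
#' @return Consensus string.
#' @examples
#' consensus_sequence(c("MDRK", "MDRK", "MDRA", "MDRK", "MDRK"))
#' @export
consensus_sequence <- function(aligned, threshold = 0.8) {
  stopifnot(length(aligned) >= 1L, threshold > 0.5, threshold <= 1)
  lens <- nchar(aligned)
  if (length(unique(lens)) != 1L) {
    stop("aligned sequences must all have the same length", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(toupper(aligned), "", fixed = TRUE))
  n <- nrow(m)
  cols <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    gaps <- sum(col %in% c("-", "."))
    if (gaps > n / 2) return(NA_character_)  # gap-majority column dropped
    res <- col[!col %in% c("-", ".")]
    tab <- sort(table(res), decreasing = TRUE)
    if (length(tab) && tab[1] / n >= threshold) names(tab)[1] else "X"
  }, character(1))
  paste(cols[!is.na(cols)], collapse = "")
}

#' Relative antimicrobial activity from absorbance readings
#'
#' `RA = ((A_PC - A_NC) - A_SA) / (A_PC - A_NC)` where `A_PC`, `A_NC` and
#' `A_SA` are the absorbances of the positive control, negative control and
#' sample. RA is 1 for a sample with no growth signal and 0 when the sample
#' equals the control difference.
#'
#' @param a_pc,a_nc,a_sa Absorbances (vectorized).
#' @return Numeric RA values.
#' @export
relative_activity <- function(a_pc, a_nc, a_sa) {
  d <- a_pc - a_nc
  if (any(d == 0)) {
    stop("A_PC equals A_NC: relative activity undefined", call. = FALSE)
  }
  (d - a_sa) / d
}
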