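#' Load external predictor results from a tabular file
#'
#' Adapter for results exported from external signal-peptide, transmembrane
#' or localization predictors. Files are TSV with a header; required columns
#' per kind:
#' \describe{
#'   \item{signalp}{`id`, `sp` (Y/N), optional `cleavage` (1-based position
#'     of the last signal-peptide residue, `"22"` or SignalP-style
#'     `"22|23"` cut notation).}
#'   \item{tm}{`id`, `tm` (Y = has a transmembrane segment, record dropped).}
#'   \item{localization}{`id`, `class` (predicted compartment).}
#' }
#'
#' @param path TSV file.
#' @param kind `"signalp"`, `"tm"` or `"localization"`.
#' @param proteome_ids Optional character vector; rows whose id is not in it
#'   are warned about and skipped.
#' @return Named list keyed by id: signal predictions
#'   (`is_secretory`, `cleavage_after` 0-based, `source`), stage decisions
#'   (`stage`, `keep`, `detail`), or class strings, depending on `kind`.
#' @export
load_external_predictions <- function(path,
                                      kind = c("signalp", "tm",
                                               "localization"),
                                      proteome_ids = NULL) {
  kind <- match.arg(kind)
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
  need <- switch(kind, signalp = c("id", "sp"), tm = c("id", "tm"),
                 localization = c("id", "class"))
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("external ", kind, " file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(tab) == 0L) return(setNames(list(), character()))
  if (!is.null(proteome_ids)) {
    unknown <- !(tab$id %in% proteome_ids)
    if (any(unknown)) {
      warning("ignoring prediction rows for unknown id(s): ",
              paste(unique(tab$id[unknown]), collapse = ", "),
              call. = FALSE)
      tab <- tab[!unknown, , drop = FALSE]
    }
  }
  if (nrow(tab) == 0L) return(setNames(list(), character()))
  out <- switch(kind,
    signalp = lapply(seq_len(nrow(tab)), function(i) {
      yes <- toupper(trimws(tab$sp[i])) %in% c("Y", "YES", "TRUE", "1")
      cleave <- NA_integer_
      if (yes && "cleavage" %in% names(tab) && !is.na(tab$cleavage[i])) {
        tok <- strsplit(as.character(tab$cleavage[i]), "|", fixed = TRUE)[[1]]
        cleave <- as.integer(trimws(tok[1])) - 1L  # to 0-based last residue
      }
      list(is_secretory = yes,
           cleavage_after = if (yes) cleave else NA_integer_,
           source = "external")
    }),
    tm = lapply(seq_len(nrow(tab)), function(i) {
      has_tm <- toupper(trimws(tab$tm[i])) %in% c("Y", "YES", "TRUE", "1")
      list(stage = "transmembrane", keep = !has_tm,
           detail = if (has_tm) "external: transmembrane" else "external: no TM")
    }),
    localization = as.list(trimws(tab$class)))
  setNames(out, tab$id)
}

#' Heuristic signal-peptide prediction
#'
#' A rule-based stand-in for a trained signal-peptide predictor, modelling
#' the classic n/h/c-region architecture: a positive-or-neutral n-region
#' (net charge of the first 5 residues >= 0), a hydrophobic h-region (some
#' 7-residue stretch within positions 3-25 with mean Fauchere-Pliska
#' hydrophobicity >= `h_min`), and a c-region with small residues
#' (A/G/S/C/T) at the -3 and -1 positions of the best-scoring candidate
#' cleavage site within positions 15-35. The prediction is labelled
#' `source = "heuristic"` so reports distinguish it from external results.
#'
#' @param seq Precursor amino-acid string.
#' @param scale Hydrophobicity [aa_scale()].
#' @param h_min Minimum h-region mean hydrophobicity.
#' @return List with `is_secretory`, `cleavage_after` (0-based index of the
#'   last signal-peptide residue, `NA` when not secretory) and `source`.
#' @export
heuristic_signal_peptide <- function(seq,
                                     scale = aa_scale("fauchere_pliska"),
                                     h_min = 1.0) {
  check_seq(seq)
  not_sec <- list(is_secretory = FALSE, cleavage_after = NA_integer_,
                  source = "heuristic")
  n <- nchar(seq)
  if (n < 20L) return(not_sec)
  head45 <- substr(seq, 1L, min(45L, n))
  if (grepl("X", head45, fixed = TRUE)) return(not_sec)  # fail closed
  # n-region: first 5 residues not net-negative
  if (net_charge(substr(seq, 1L, 5L)) < 0L) return(not_sec)
  # h-region: any 7-mer wholly inside positions 3..25 with mean H >= h_min
  v <- scale_values(substr(seq, 1L, min(45L, n)), scale)
  h_ok <- FALSE
  for (i in 3:19) {
    if (i + 6L > min(25L, length(v))) break
    if (mean(v[i:(i + 6L)]) >= h_min) { h_ok <- TRUE; break }
  }
  if (!h_ok) return(not_sec)
  # c-region: small residues at -3/-1 of a cleavage site in positions 15..35;
  # candidates scored by hydrophobicity of the 7-mer ending 3 before the cut
  small <- c("A", "G", "S", "C", "T")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  cand <- integer(0); score <- numeric(0)
  for (p in 15:min(35L, n - 1L)) {
    if (chars[p] %in% small && chars[p - 2L] %in% small) {
      cand <- c(cand, p)
      score <- c(score, mean(v[(p - 9L):(p - 3L)]))
    }
  }
  if (!length(cand)) return(not_sec)
  best <- cand[which.max(score)]
  list(is_secretory = TRUE, cleavage_after = best - 1L, source = "heuristic")
}

#' Heuristic transmembrane filter
#'
#' Classic hydropathy heuristic: the record is eliminated when any
#' 19-residue window of the mature sequence has mean Kyte-Doolittle
#' hydropathy >= 1.6 (threshold inclusive). Sequences shorter than the
#' window are kept; windows containing `X` are skipped.
#'
#' @param mature_seq Signal-less sequence.
#' @param threshold Mean-hydropathy threshold.
#' @param window Window length.
#' @param scale Hydropathy [aa_scale()].
#' @return Stage decision list: `stage`, `keep`, `detail`.
#' @export
heuristic_tm_filter <- function(mature_seq, threshold = 1.6, window = 19L,
                                scale = aa_scale("kyte_doolittle")) {
  check_seq(mature_seq)
  n <- nchar(mature_seq)
  chars <- strsplit(mature_seq, "", fixed = TRUE)[[1]]
  v <- unclass(scale)[chars]  # NA for X / unknown
  if (n >= window) {
    for (s in 1:(n - window + 1L)) {
      win <- v[s:(s + window - 1L)]
      if (anyNA(win)) next
      if (mean(win) >= threshold) {
        return(list(stage = "transmembrane", keep = FALSE,
                    detail = sprintf(
                      "heuristic: KD window mean %.2f >= %.2f at %d",
                      mean(win), threshold, s)))
      }
    }
  }
  list(stage = "transmembrane", keep = TRUE, detail = "heuristic: no TM")
}

#' Subcellular-localization gate
#'
#' With an external prediction map (see [load_external_predictions()] with
#' `kind = "localization"`), a record is kept iff its predicted class is in
#' `accepted` (case-insensitive; ids absent from the map are dropped with a
#' warning). Without a map the stage is a pass-through and a once-per-run
#' warning is emitted.
#'
#' @param id Record identifier.
#' @param external_map Named list id -> class string, or `NULL`.
#' @param accepted Accepted (secreted) class names.
#' @return Stage decision list: `stage`, `keep`, `detail`.
#' @export
localization_gate <- function(id, external_map = NULL,
                              accepted = c("Extracellular", "Secreted")) {
  if (is.null(external_map)) {
    if (!isTRUE(.lcamp_state$warned_localization)) {
      warning("no external localization predictions: ",
              "localization stage is a pass-through", call. = FALSE)
      .lcamp_state$warned_localization <- TRUE
    }
    return(list(stage = "localization", keep = TRUE,
                detail = "pass-through (no external predictions)"))
  }
  cls <- external_map[[id]]
  if (is.null(cls)) {
    warning("no localization prediction for '", id, "'; dropped",
            call. = FALSE)
    return(list(stage = "localization", keep = FALSE,
                detail = "no external prediction"))
  }
  keep <- tolower(cls) %in% tolower(accepted)
  list(stage = "localization", keep = keep,
       detail = paste0("external: ", cls))
}

#' Reset once-per-run warning state
#' @noRd
reset_run_state <- function() {
  .lcamp_state$warned_localization <- FALSE
  invisible(NULL)
}
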