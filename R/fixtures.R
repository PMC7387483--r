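#' @noRd
SIGNAL_TEMPLATES <- c("MDRKIVFALXLVXXLXVSXXXA",
                      "MNKSALLXLLXXGLXVLXEXXXA")

#' Helical-wheel face assignment
#'
#' Positions (0-based) whose wheel angle at 100 degrees/residue lies within
#' +/-90 degrees of the azimuth form the "polar face"; the rest the
#' hydrophobic face.
#' @noRd
wheel_faces <- function(len, azimuth_deg = 0) {
  ang <- ((seq_len(len) - 1L) * 100 - azimuth_deg) * pi / 180
  cos(ang) > 1e-9
}

#' @noRd
fill_signal <- function() {
  tpl <- sample(SIGNAL_TEMPLATES, 1L)
  chars <- strsplit(tpl, "", fixed = TRUE)[[1]]
  chars[chars == "X"] <- sample(c("A", "V", "L", "S"),
                                sum(chars == "X"), replace = TRUE)
  paste(chars, collapse = "")
}

#' @noRd
build_face_helix <- function(len, polar_pool, hydro_pool,
                             polar_weights = NULL, hydro_weights = NULL,
                             force_polar = character()) {
  polar <- wheel_faces(len)
  chars <- character(len)
  chars[polar] <- sample(polar_pool, sum(polar), replace = TRUE,
                         prob = polar_weights)
  chars[!polar] <- sample(hydro_pool, sum(!polar), replace = TRUE,
                          prob = hydro_weights)
  # force required residues onto the polar face (e.g. one S for the
  # uncharged-residue composition rule)
  ppos <- which(polar)
  for (k in seq_along(force_polar)) {
    chars[ppos[k]] <- force_polar[k]
  }
  paste(chars, collapse = "")
}

#' Generate one synthetic LCAMP-like precursor
#'
#' Concatenates a consensus-derived signal peptide (`X` positions filled
#' from A/V/L/S), an 18-24-residue cationic amphipathic helix built by
#' placing K/R on one wheel face and L/A/F/I on the other, and an anionic
#' helical tail, then verifies the whole record against the real screening
#' operations ([run_funnel()]) and resamples until it reaches `candidate`.
#' Determinism: the same seed always yields the same record.
#'
#' @param seed Integer seed.
#' @param config A [screen_config()] the record must satisfy.
#' @param id Record identifier.
#' @param max_attempts Resampling budget before a generation error.
#' @return List with `record` (one-row table as from [read_fasta()]) and
#'   `truth` (1-based inclusive intervals `signal`, `cationic`, `anionic`).
#' @export
make_precursor <- function(seed, config = screen_config(),
                           id = sprintf("PLANT.%d", seed),
                           max_attempts = 200L) {
  set.seed(seed)
  for (attempt in seq_len(max_attempts)) {
    sig <- fill_signal()
    core_len <- sample(18:24, 1L)
    core <- build_face_helix(core_len,
                             polar_pool = c("K", "R"),
                             hydro_pool = c("L", "A", "F", "I"),
                             force_polar = "S")
    if (nrow(scan_windows(core, config$cationic)) == 0L) next
    if (!helicity_check(core, "propensity",
                        config$helicity$min_helix_frac,
                        config$helicity$min_mean)$pass) next
    if (!na4vss_gate(aggregation_profile(core,
                                         window = config$aggregation$window,
                                         end_mode = config$aggregation$end_mode),
                     config$aggregation$lo, config$aggregation$hi)) next
    tail_seq <- build_face_helix(18L,
                                 polar_pool = c("E", "D"),
                                 polar_weights = c(0.75, 0.25),
                                 hydro_pool = c("A", "S", "L", "M"),
                                 hydro_weights = c(0.5, 0.3, 0.1, 0.1))
    if (is.null(find_anionic_tail(tail_seq, config$anionic))) next
    seq <- paste0(sig, core, tail_seq)
    if (nchar(seq) < config$min_len || nchar(seq) > config$max_len) next
    rec <- data.frame(id = id, description = id, seq = seq,
                      length = nchar(seq), has_x = FALSE,
                      stringsAsFactors = FALSE)
    res <- run_funnel(rec, config)
    if (res$report$stage_reached[1] == "candidate") {
      ns <- nchar(sig)
      return(list(record = rec,
                  truth = list(
                    signal = c(1L, ns),
                    cationic = c(ns + 1L, ns + core_len),
                    anionic = c(ns + core_len + 1L, nchar(seq)))))
    }
  }
  stop("precursor generation failed after ", max_attempts, " attempts",
       call. = FALSE)
}

#' Generate a stage-specific decoy
#'
#' Emits a record that passes every funnel stage before `stage_to_fail` and
#' fails exactly there: over-long precursor (length), hydrophilic N-terminus
#' (secretory), planted 19-residue poly-leucine stretch (tm), a single
#' cysteine in the mature region (cys), a charge-free polar region
#' (amphipathic), a proline/glycine-rich amphipathic helix-breaker segment
#' (helical), or an aggregation-extreme I/F/Y-faced segment pushing Na4vSS
#' above the gate (aggregation). Each decoy is verified end-to-end with
#' [run_funnel()] and resampled until its rejection stage matches its label.
#'
#' @param stage_to_fail One of `"length"`, `"secretory"`, `"tm"`, `"cys"`,
#'   `"amphipathic"`, `"helical"`, `"aggregation"`.
#' @inheritParams make_precursor
#' @return List with `record` and `stage` (the label).
#' @export
make_decoy <- function(stage_to_fail, seed, config = screen_config(),
                       id = sprintf("DECOY.%s", stage_to_fail),
                       max_attempts = 200L) {
  stage_to_fail <- match.arg(stage_to_fail,
                             setdiff(FUNNEL_STAGES, "localization"))
  for (attempt in seq_len(max_attempts)) {
    base <- make_precursor(seed + 7919L * attempt, config,
                           id = id, max_attempts = max_attempts)
    tr <- base$truth
    seq <- base$record$seq
    sig <- substr(seq, tr$signal[1], tr$signal[2])
    core <- substr(seq, tr$cationic[1], tr$cationic[2])
    tail_seq <- substr(seq, tr$anionic[1], tr$anionic[2])
    set.seed(seed + 104729L * attempt)
    new_seq <- switch(stage_to_fail,
      length = paste0(seq, strrep("GS", ceiling((config$max_len + 1 -
                                                   nchar(seq)) / 2))),
      secretory = paste0(paste(sample(c("D", "E", "K", "N", "Q", "S"),
                                      nchar(sig), replace = TRUE),
                               collapse = ""),
                         core, tail_seq),
      tm = paste0(sig, core, strrep("L", 19L), tail_seq),
      cys = paste0(sig, core, tail_seq, "C"),
      amphipathic = paste0(sig,
                           paste(sample(c("S", "G", "T", "N", "Q"),
                                        nchar(core), replace = TRUE),
                                 collapse = ""),
                           tail_seq),
      helical = paste0(sig,
                       build_face_helix(nchar(core),
                                        polar_pool = c("K", "R"),
                                        polar_weights = c(0.9, 0.1),
                                        hydro_pool = c("P", "F", "G"),
                                        hydro_weights = c(0.45, 0.35, 0.2),
                                        force_polar = "S"),
                       tail_seq),
      aggregation = paste0(sig,
                           build_face_helix(nchar(core),
                                            polar_pool = c("K"),
                                            hydro_pool = c("I", "F", "Y"),
                                            force_polar = "H"),
                           tail_seq))
    if (stage_to_fail == "length") {
      new_seq <- substr(new_seq, 1L, config$max_len + 1L)
    }
    rec <- data.frame(id = id, description = id, seq = new_seq,
                      length = nchar(new_seq), has_x = FALSE,
                      stringsAsFactors = FALSE)
    res <- run_funnel(rec, config)
    if (res$report$stage_reached[1] == stage_to_fail) {
      return(list(record = rec, stage = stage_to_fail))
    }
  }
  stop("decoy generation for stage '", stage_to_fail, "' failed after ",
       max_attempts, " attempts", call. = FALSE)
}

#' Generate a synthetic proteome with planted precursors and decoys
#'
#' The standard offline validation fixture: `n_planted` true LCAMP-like
#' precursors plus one decoy per funnel stage (7 by default). All planted
#' records reach `candidate` and every decoy is rejected exactly at its
#' labelled stage under the given configuration, by construction
#' (generator-side verification against the real pipeline).
#'
#' @param n_planted Number of planted precursors.
#' @param seed Integer seed; generation is a pure function of
#'   `(n_planted, decoy_stages, seed)`.
#' @param config A [screen_config()].
#' @param decoy_stages Stages to build decoys for.
#' @return List with `records` (record table, planted then decoys) and
#'   `truth` (data.frame: `id`, `kind`, `stage`).
#' @export
make_fixture_proteome <- function(n_planted = 5L, seed = 1L,
                                  config = screen_config(),
                                  decoy_stages = setdiff(FUNNEL_STAGES,
                                                         "localization")) {
  planted <- lapply(seq_len(n_planted), function(k) {
    make_precursor(seed * 1000L + k, config,
                   id = sprintf("PLANT.%d", k))
  })
  decoys <- lapply(seq_along(decoy_stages), function(k) {
    make_decoy(decoy_stages[k], seed * 2000L + k, config)
  })
  records <- do.call(rbind, c(lapply(planted, `[[`, "record"),
                              lapply(decoys, `[[`, "record")))
  truth <- rbind(
    data.frame(id = vapply(planted, function(p) p$record$id, character(1)),
               kind = "planted", stage = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(id = vapply(decoys, function(d) d$record$id, character(1)),
               kind = "decoy",
               stage = vapply(decoys, `[[`, character(1), "stage"),
               stringsAsFactors = FALSE))
  list(records = records, truth = truth)
}

#' Generate an upstream DNA region with planted PWM sites
#'
#' Uniform-background DNA with `n_sites` embedded copies of the matrix's
#' per-position argmax word at non-overlapping offsets, on randomly chosen
#' strands (minus-strand sites are inserted as the reverse complement).
#'
#' @param pwm A [load_pwm()] matrix.
#' @param n_sites Number of planted sites.
#' @param seed Integer seed.
#' @param region_len Region length in bp.
#' @param gene_id Identifier.
#' @return List with `record` (DNA record table row) and `truth`
#'   (data.frame: `position` negative-from-ATG of the site's 5'-most base,
#'   `strand`).
#' @export
make_upstream_with_sites <- function(pwm, n_sites, seed, region_len = 300L,
                                     gene_id = "GENE.1") {
  set.seed(seed)
  L <- pwm$length
  stopifnot(region_len >= n_sites * (2L * L))
  chars <- sample(c("A", "C", "G", "T"), region_len, replace = TRUE)
  word <- colnames(pwm$freqs)[apply(pwm$freqs, 1, which.max)]
  # non-overlapping offsets with at least L spacing
  offsets <- integer(0)
  while (length(offsets) < n_sites) {
    cand <- sample.int(region_len - L + 1L, 1L) - 1L
    if (!any(abs(cand - offsets) < L)) offsets <- c(offsets, cand)
  }
  strands <- sample(c("+", "-"), n_sites, replace = TRUE)
  for (k in seq_len(n_sites)) {
    ins <- if (strands[k] == "+") word else rev(unname(DNA_COMP[word]))
    chars[(offsets[k] + 1L):(offsets[k] + L)] <- ins
  }
  rec <- data.frame(id = gene_id, description = gene_id,
                    seq = paste(chars, collapse = ""),
                    length = region_len, stringsAsFactors = FALSE)
  truth <- data.frame(position = sort(offsets - region_len),
                      strand = strands[order(offsets)],
                      stringsAsFactors = FALSE)
  list(record = rec, truth = truth)
}
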