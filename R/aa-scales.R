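#' Load a per-residue numeric scale
#'
#' Scales are named numeric vectors mapping each of the 20 standard amino
#' acids to a unitless value. Four scales ship with the package:
#' `"fauchere_pliska"` (hydrophobicity, the HeliQuest default),
#' `"aggrescan_a3v"` (aggregation propensity), `"kyte_doolittle"`
#' (hydropathy) and `"chou_fasman_helix"` (helix propensity).
#'
#' @param name Name of a shipped scale, or a path to a scale file
#'   (two whitespace-separated columns: residue, value; `#` comments).
#' @return Named numeric vector of length 20 with class `"aa_scale"`.
#' @examples
#' fp <- aa_scale("fauchere_pliska")
#' fp[["W"]]
#' @export
aa_scale <- function(name) {
  shipped <- c("fauchere_pliska", "aggrescan_a3v",
               "kyte_doolittle", "chou_fasman_helix")
  path <- if (name %in% shipped) {
    system.file("extdata", "scales", paste0(name, ".txt"),
                package = "lcampscan", mustWork = TRUE)
  } else if (file.exists(name)) {
    name
  } else {
    stop("unknown scale '", name, "'; shipped scales: ",
         paste(shipped, collapse = ", "), call. = FALSE)
  }
  read_scale_file(path)
}

#' Read a residue-scale file
#'
#' @param path Two-column text file (residue letter, numeric value); lines
#'   starting with `#` are ignored.
#' @return Named numeric vector with class `"aa_scale"`. All 20 standard
#'   residues must be present; duplicates are an error.
#' @export
read_scale_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\\s+")
  bad <- vapply(parts, function(p) length(p) != 2L, logical(1))
  if (any(bad)) {
    stop("malformed scale line in '", path, "': '", lines[which(bad)[1]], "'",
         call. = FALSE)
  }
  res <- toupper(vapply(parts, `[[`, character(1), 1L))
  val <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  if (anyNA(val)) {
    stop("non-numeric scale value in '", path, "'", call. = FALSE)
  }
  if (anyDuplicated(res)) {
    stop("duplicate residue '", res[duplicated(res)][1], "' in scale file",
         call. = FALSE)
  }
  missing <- setdiff(AA20, res)
  if (length(missing)) {
    stop("scale file is missing residues: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(setNames(val, res)[AA20], class = "aa_scale")
}

#' Look up scale values for a sequence, failing on unknown residues
#'
#' Lookup of a residue absent from the scale (including `X`) is an error,
#' never a silent zero.
#' @noRd
scale_values <- function(seq, scale) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  v <- unclass(scale)[chars]
  if (anyNA(v)) {
    bad <- unique(chars[is.na(v)])
    stop("residue(s) not in scale: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(v)
}
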