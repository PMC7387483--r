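#' Load a position weight matrix
#'
#' Accepts JASPAR-style letter rows (`A [ 3 5 ... ]`) or a plain whitespace
#' table (optional `A C G T` header, optional leading position index), as
#' counts or as already-normalized frequencies. Counts are normalized per
#' position after adding a pseudocount (a fraction of the position total,
#' split equally over the four bases). Per-position information content
#' `I(i) = sum_b f(i,b) ln(4 f(i,b))` (natural log, `0 ln 0 = 0`) and the
#' core — the 5 consecutive positions maximizing summed information,
#' leftmost on ties — are precomputed.
#'
#' @param path Matrix file; `#` lines are comments.
#' @param pseudocount Fraction of each position total added before
#'   normalizing counts (default 0.01); ignored for frequency matrices.
#' @return A list of class `"pwm"`: `id`, `freqs` (L x 4 matrix, columns
#'   A,C,G,T; rows sum to 1), `info`, `core` (integer positions, length 5),
#'   `length`.
#' @export
load_pwm <- function(path, pseudocount = 0.01) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  id <- sub("\\.[^.]*$", "", basename(path))
  if (length(lines) && startsWith(lines[1], ">")) {
    id <- strsplit(sub("^>\\s*", "", lines[1]), "\\s+")[[1]][1]
    lines <- lines[-1]
  }
  letter_rows <- grepl("^[ACGTacgt]\\b", lines)
  if (sum(letter_rows) == 4L) {
    rows <- lapply(lines[letter_rows], function(l) {
      base <- toupper(substr(l, 1, 1))
      nums <- as.numeric(strsplit(gsub("[^0-9.eE+-]+", " ",
                                       substr(l, 2, nchar(l))),
                                  "\\s+")[[1]] |> (\(x) x[nzchar(x)])())
      setNames(list(nums), base)
    })
    rows <- do.call(c, rows)
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L) {
      stop("PWM base rows have unequal lengths", call. = FALSE)
    }
    mat <- cbind(A = rows$A, C = rows$C, G = rows$G, T = rows$T)
  } else {
    header <- grepl("^[ACGTacgt\\s]+$", lines[1]) &&
      length(strsplit(lines[1], "\\s+")[[1]]) == 4L
    if (header) lines <- lines[-1]
    rows <- lapply(lines, function(l) {
      as.numeric(strsplit(l, "\\s+")[[1]])
    })
    if (any(vapply(rows, anyNA, logical(1)))) {
      stop("non-numeric value in PWM matrix", call. = FALSE)
    }
    lens <- lengths(rows)
    if (any(!lens %in% c(4L, 5L)) || length(unique(lens)) != 1L) {
      stop("PWM rows must have 4 values (optionally preceded by an index)",
           call. = FALSE)
    }
    mat <- do.call(rbind, rows)
    if (ncol(mat) == 5L) mat <- mat[, -1L, drop = FALSE]
    colnames(mat) <- c("A", "C", "G", "T")
  }
  if (nrow(mat) < 5L) stop("PWM must have at least 5 positions",
                           call. = FALSE)
  if (any(mat < 0)) stop("negative PWM entry", call. = FALSE)
  totals <- rowSums(mat)
  if (any(totals == 0)) stop("PWM position with all-zero counts",
                             call. = FALSE)
  is_freq <- all(abs(totals - 1) <= 1e-6)
  freqs <- if (is_freq) {
    mat
  } else {
    sweep(mat + pseudocount * totals / 4, 1,
          totals * (1 + pseudocount), "/")
  }
  info <- apply(freqs, 1, function(f) {
    t <- f * log(4 * f)
    sum(t[f > 0])
  })
  win <- vapply(seq_len(nrow(freqs) - 4L),
                function(i) sum(info[i:(i + 4L)]), numeric(1))
  core_start <- which.max(win)  # leftmost maximum
  structure(list(id = id, freqs = freqs, info = unname(info),
                 core = core_start:(core_start + 4L),
                 length = nrow(freqs)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  consensus <- paste(colnames(x$freqs)[apply(x$freqs, 1, which.max)],
                     collapse = "")
  cat(sprintf("PWM '%s': %d positions, core %d-%d, argmax word %s\n",
              x$id, x$length, min(x$core), max(x$core), consensus))
  invisible(x)
}

#' @noRd
DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Match-style PWM scan of an upstream region
#'
#' Scores every offset on both strands with the Match algorithm:
#' `matrix_sim = (Current - Min) / (Max - Min)` where
#' `Current = sum_i I(i) f(i, b_i)` and `Min`/`Max` use the per-position
#' least/most frequent base; `core_sim` is the same score restricted to the
#' 5 most informative consecutive positions. Hits must pass both cut-offs.
#' Windows containing `N` are skipped. Positions are reported as negative
#' offsets from the ATG of the 5'-most base of the site on the + strand
#' (the last upstream base is position -1).
#'
#' @param upstream One-row data.frame with `id` and `seq` (from
#'   [read_fasta()] with `alphabet = "dna"`), or a single DNA string.
#' @param pwm A [load_pwm()] matrix.
#' @param core_cutoff,matrix_cutoff Similarity cut-offs (defaults 0.75 and
#'   0.8, the published screening values).
#' @param both_strands Scan the minus strand too (default).
#' @param gene_id Identifier when `upstream` is a bare string.
#' @return Data.frame of hits: `gene_id`, `position`, `start`, `end`
#'   (1-based on the input sequence), `strand`, `core_sim`, `matrix_sim`,
#'   ordered by position.
#' @export
match_scan <- function(upstream, pwm, core_cutoff = 0.75,
                       matrix_cutoff = 0.8, both_strands = TRUE,
                       gene_id = NA_character_) {
  if (is.data.frame(upstream)) {
    stopifnot(nrow(upstream) == 1L)
    gene_id <- upstream$id
    seq <- upstream$seq
  } else {
    seq <- as.character(upstream)
  }
  L <- pwm$length
  n <- nchar(seq)
  I <- pwm$info
  f <- pwm$freqs
  fmin <- apply(f, 1, min)
  fmax <- apply(f, 1, max)
  Mx <- sum(I * fmax); Mn <- sum(I * fmin)
  cMx <- sum((I * fmax)[pwm$core]); cMn <- sum((I * fmin)[pwm$core])
  if (Mx - Mn <= 0 || cMx - cMn <= 0) {
    stop("degenerate PWM: Max == Min (no informative positions)",
         call. = FALSE)
  }
  hits <- empty_hits()
  if (n < L) return(hits)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  idx <- match(chars, c("A", "C", "G", "T"))  # NA for N
  strands <- if (both_strands) c("+", "-") else "+"
  for (o in 0:(n - L)) {
    word <- idx[(o + 1L):(o + L)]
    if (anyNA(word)) next
    for (strand in strands) {
      w <- if (strand == "+") word else (5L - rev(word))  # revcomp indices
      cur <- sum(I * f[cbind(seq_len(L), w)])
      msim <- (cur - Mn) / (Mx - Mn)
      ccur <- sum((I * f[cbind(seq_len(L), w)])[pwm$core])
      csim <- (ccur - cMn) / (cMx - cMn)
      if (csim >= core_cutoff && msim >= matrix_cutoff) {
        hits <- rbind(hits, data.frame(
          gene_id = gene_id, position = o - n, start = o + 1L,
          end = o + L, strand = strand, core_sim = csim,
          matrix_sim = msim, stringsAsFactors = FALSE))
      }
    }
  }
  hits[order(hits$position, hits$strand), , drop = FALSE]
}

#' @noRd
empty_hits <- function() {
  data.frame(gene_id = character(), position = integer(), start = integer(),
             end = integer(), strand = character(), core_sim = numeric(),
             matrix_sim = numeric(), stringsAsFactors = FALSE)
}

#' Scan a set of upstream regions
#'
#' Runs [match_scan()] over every record and returns all hits ordered by
#' gene id then position. Genes without hits are recorded in the
#' `"nd_genes"` attribute and rendered as `N.D.` by
#' [motif_position_table()].
#'
#' @param upstreams DNA record table from [read_fasta()].
#' @inheritParams match_scan
#' @return Hit data.frame (see [match_scan()]) with attribute `nd_genes`.
#' @export
scan_upstream_set <- function(upstreams, pwm, core_cutoff = 0.75,
                              matrix_cutoff = 0.8, both_strands = TRUE) {
  all_hits <- lapply(seq_len(nrow(upstreams)), function(i) {
    match_scan(upstreams[i, , drop = FALSE], pwm, core_cutoff,
               matrix_cutoff, both_strands)
  })
  hits <- do.call(rbind, c(list(empty_hits()), all_hits))
  hits <- hits[order(hits$gene_id, hits$position), , drop = FALSE]
  attr(hits, "nd_genes") <- setdiff(upstreams$id, hits$gene_id)
  hits
}

#' Per-gene motif-position summary table
#'
#' One row per gene; hits rendered as `start/end` negative-offset pairs,
#' genes with no hits as `N.D.` (not detected).
#'
#' @param upstreams DNA record table.
#' @param hits Output of [scan_upstream_set()].
#' @return Data.frame with columns `gene_id`, `positions`.
#' @export
motif_position_table <- function(upstreams, hits) {
  rows <- lapply(upstreams$id, function(g) {
    h <- hits[hits$gene_id == g, , drop = FALSE]
    pos <- if (nrow(h) == 0L) {
      "N.D."
    } else {
      paste(sprintf("%d/%d", h$position, h$position + h$end - h$start),
            collapse = ", ")
    }
    data.frame(gene_id = g, positions = pos, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
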