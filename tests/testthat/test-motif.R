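default_pwm <- load_pwm(system.file("extdata", "pwm",
                                    "nfkb_like_synthetic.pwm",
                                    package = "lcampscan", mustWork = TRUE))

argmax_word <- function(pwm) {
  paste(colnames(pwm$freqs)[apply(pwm$freqs, 1, which.max)], collapse = "")
}
argmin_word <- function(pwm) {
  paste(colnames(pwm$freqs)[apply(pwm$freqs, 1, which.min)], collapse = "")
}

test_that("count matrices are normalized and scored consistently", {
  set.seed(41)
  counts <- matrix(sample(0:50, 40, replace = TRUE), ncol = 4)
  counts[rowSums(counts) == 0, 1] <- 1
  pwm <- toy_pwm(counts)
  expect_equal(rowSums(pwm$freqs), rep(1, 10), tolerance = 1e-9)
  expect_equal(pwm$length, 10L)
  expect_length(pwm$core, 5L)
  expect_true(all(diff(pwm$core) == 1L))
})

test_that("uniform matrices carry zero information with leftmost core", {
  pwm <- toy_pwm(matrix(25, nrow = 8, ncol = 4))
  expect_equal(pwm$info, rep(0, 8))
  expect_equal(pwm$core, 1:5)
})

test_that("frequency matrices pass through unchanged", {
  freqs <- matrix(c(0.7, 0.1, 0.1, 0.1,
                    0.25, 0.25, 0.25, 0.25,
                    0.1, 0.1, 0.1, 0.7,
                    0.4, 0.3, 0.2, 0.1,
                    0.1, 0.6, 0.2, 0.1), ncol = 4, byrow = TRUE)
  path <- tempfile()
  writeLines(apply(freqs, 1, paste, collapse = " "), path)
  pwm <- load_pwm(path)
  expect_equal(unname(pwm$freqs), freqs)
})

test_that("malformed matrices are rejected", {
  path <- tempfile()
  writeLines(c("1 0 0 0", "0 1 0 0", "0 0 1 0", "0 0 0 1"), path)
  expect_error(load_pwm(path), "at least 5")
  writeLines(c("1 0 0 0", "0 0 0 0", "1 0 0 0", "1 0 0 0", "1 0 0 0"), path)
  expect_error(load_pwm(path), "all-zero")
})

test_that("argmax word scores 1.0 on both similarities, argmin scores 0", {
  hit <- match_scan(argmax_word(default_pwm), default_pwm, gene_id = "g")
  plus <- hit[hit$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$matrix_sim, 1.0)
  expect_equal(plus$core_sim, 1.0)
  expect_equal(plus$position, -default_pwm$length)

  lo <- match_scan(argmin_word(default_pwm), default_pwm, core_cutoff = 0,
                   matrix_cutoff = 0, both_strands = FALSE, gene_id = "g")
  expect_equal(lo$matrix_sim, 0)
  expect_equal(nrow(match_scan(argmin_word(default_pwm), default_pwm,
                               both_strands = FALSE, gene_id = "g")), 0L)
})

test_that("similarities stay in [0,1] and N windows are skipped", {
  set.seed(42)
  s <- paste0(random_dna(30), "NNN", random_dna(30))
  hits <- match_scan(s, default_pwm, core_cutoff = 0, matrix_cutoff = 0,
                     gene_id = "g")
  expect_true(all(hits$core_sim >= 0 & hits$core_sim <= 1))
  expect_true(all(hits$matrix_sim >= 0 & hits$matrix_sim <= 1))
  # Ns sit at 0-based 30..32; any window start in 21..32 would cover one
  expect_false(any((hits$start - 1) %in% 21:32))
})

test_that("the scanner equals the brute-force oracle on random instances", {
  set.seed(43)
  for (i in 1:200) {
    counts <- matrix(sample(0:20, 24, replace = TRUE), ncol = 4)
    counts[rowSums(counts) == 0, 2] <- 1
    pwm <- try(toy_pwm(counts), silent = TRUE)
    if (inherits(pwm, "try-error")) next  # degenerate matrix: skipped
    s <- random_dna(50)
    cc <- runif(1, 0, 0.9); mc <- runif(1, 0, 0.9)
    got <- tryCatch(match_scan(s, pwm, cc, mc, gene_id = "g"),
                    error = function(e) e)
    want <- tryCatch(oracle_match_scan(s, pwm, cc, mc),
                     error = function(e) e)
    if (inherits(want, "error")) {
      expect_s3_class(got, "error")  # degenerate Max == Min
      next
    }
    expect_equal(got$position, as.integer(want$position))
    expect_equal(got$strand, want$strand)
    expect_equal(got$core_sim, want$core_sim, tolerance = 1e-12)
    expect_equal(got$matrix_sim, want$matrix_sim, tolerance = 1e-12)
  }
})

test_that("reverse-complementing the sequence mirrors strands and scores", {
  set.seed(44)
  for (i in 1:10) {
    s <- random_dna(60)
    fwd <- match_scan(s, default_pwm, core_cutoff = 0, matrix_cutoff = 0,
                      gene_id = "g")
    rev <- match_scan(revcomp_dna(s), default_pwm, core_cutoff = 0,
                      matrix_cutoff = 0, gene_id = "g")
    expect_equal(nrow(fwd), nrow(rev))
    expect_equal(sort(fwd$matrix_sim), sort(rev$matrix_sim),
                 tolerance = 1e-12)
    expect_equal(sum(fwd$strand == "+"), sum(rev$strand == "-"))
  }
})

test_that("raising either cut-off never increases the hit count", {
  set.seed(45)
  s <- random_dna(400)
  for (cuts in list(c(0.2, 0.2), c(0.5, 0.5), c(0.75, 0.8), c(0.9, 0.95))) {
    n0 <- nrow(match_scan(s, default_pwm, cuts[1], cuts[2], gene_id = "g"))
    n1 <- nrow(match_scan(s, default_pwm, cuts[1] + 0.05, cuts[2],
                          gene_id = "g"))
    n2 <- nrow(match_scan(s, default_pwm, cuts[1], cuts[2] + 0.05,
                          gene_id = "g"))
    expect_lte(n1, n0)
    expect_lte(n2, n0)
  }
})

test_that("degenerate PWMs are refused by the scanner", {
  pwm <- toy_pwm(matrix(25, nrow = 6, ncol = 4))
  expect_error(match_scan(random_dna(20), pwm, gene_id = "g"),
               "degenerate")
})

test_that("upstream-set scans order hits and render N.D. rows", {
  set.seed(46)
  up1 <- make_upstream_with_sites(default_pwm, 2, seed = 5,
                                  gene_id = "geneA")
  up2 <- data.frame(id = "geneB", description = "geneB",
                    seq = strrep("AT", 60), length = 120L)
  ups <- rbind(up1$record, up2)
  hits <- scan_upstream_set(ups, default_pwm)
  expect_true(all(diff(order(hits$gene_id, hits$position)) > 0) ||
                nrow(hits) <= 1)
  expect_true("geneB" %in% attr(hits, "nd_genes"))
  tab <- motif_position_table(ups, hits)
  expect_equal(tab$positions[tab$gene_id == "geneB"], "N.D.")
  expect_match(tab$positions[tab$gene_id == "geneA"], "^-\\d+/-\\d+")
})
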