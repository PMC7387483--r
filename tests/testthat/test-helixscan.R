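test_that("trivial sequences fail the cationic box for the right reasons", {
  box <- cationic_box()
  expect_equal(nrow(scan_windows(strrep("G", 18), box)), 0L)  # z = 0
  expect_equal(nrow(scan_windows(strrep("K", 18), box)), 0L)  # z = 18
})

test_that("window scan equals the brute-force oracle on random sequences", {
  set.seed(101)
  boxes <- list(cationic_box(), anionic_box())
  polar <- default_polar_set()
  n_checked <- 0L
  for (i in 1:200) {
    letters_pool <- if (i %% 10 == 0) c(AA_LETTERS, "X") else AA_LETTERS
    s <- random_peptide(sample(20:120, 1), letters_pool)
    box <- boxes[[1 + i %% 2]]
    got <- scan_windows(s, box, fp_scale, polar)
    want <- oracle_scan_windows(s, box, fp_scale, polar)
    expect_equal(got$start, as.integer(want$start))
    if (nrow(got)) {
      expect_equal(got$H, want$H, tolerance = 1e-12)
      expect_equal(got$muH, want$muH, tolerance = 1e-12)
      expect_equal(got$z, as.integer(want$z))
      n_checked <- n_checked + nrow(got)
    }
  }
  expect_gt(n_checked, 0L)
})

test_that("a planted amphipathic core is found and windows re-verify", {
  # K/R on one wheel face, L/A/F/I on the other, inside a random 30-mer
  rec <- make_precursor(5)
  core_seq <- substr(rec$record$seq, rec$truth$cationic[1],
                     rec$truth$cationic[2])
  wins <- scan_windows(core_seq, cationic_box())
  expect_gt(nrow(wins), 0L)
  for (k in seq_len(nrow(wins))) {
    p <- physchem_profile(wins$seq[k])
    expect_equal(wins$H[k], p$H)
    expect_equal(wins$muH[k], p$muH)
    expect_equal(wins$z[k], p$z)
    expect_true(box_pass(p, cationic_box()))
  }
})

test_that("box bounds are inclusive at both ends", {
  # custom scale puts every residue of a poly-A window exactly at H = 0.6
  f <- tempfile()
  vals <- setNames(rep(0, 20), AA_LETTERS)
  vals["A"] <- 0.6
  writeLines(sprintf("%s %.9f", names(vals), vals), f)
  at_bound <- read_scale_file(f)
  box <- threshold_box(H_min = 0, H_max = 0.6, muH_min = 0, muH_max = 1,
                       z_min = 0, z_max = 10, window_len = 18)
  expect_equal(nrow(scan_windows(strrep("A", 18), box, at_bound)), 1L)
  vals["A"] <- 0.6 + 1e-6
  writeLines(sprintf("%s %.9f", names(vals), vals), f)
  above <- read_scale_file(f)
  expect_equal(nrow(scan_windows(strrep("A", 18), box, above)), 0L)
})

test_that("windows containing cysteine always fail the cationic box", {
  s <- paste0(strrep("K", 8), "C", strrep("L", 9))
  expect_equal(nrow(scan_windows(s, cationic_box())), 0L)
})

test_that("merge_windows unions overlapping windows of one class", {
  mk <- function(starts, len = 18) {
    do.call(rbind, lapply(starts, function(s) data.frame(
      parent_id = "p", start = s, end = s + len, seq = strrep("A", len),
      H = 0.1, muH = 0.2 + s / 100, z = 4L, klass = "cationic",
      stringsAsFactors = FALSE)))
  }
  seg <- merge_windows(mk(c(3, 4, 5)))
  expect_equal(nrow(seg), 1L)
  expect_equal(c(seg$start, seg$end), c(3L, 23L))  # union [3,21)..[5,23)
  expect_equal(seg$best_start, 5L)  # highest muH wins
  expect_equal(nrow(merge_windows(mk(c(0, 40)))), 2L)
  expect_equal(nrow(merge_windows(NULL)), 0L)
  expect_equal(nrow(merge_windows(mk(integer(0)))), 0L)
})

test_that("merged segments are disjoint and cover the window union", {
  set.seed(33)
  for (i in 1:20) {
    starts <- sort(sample(0:60, sample(1:12, 1)))
    wins <- do.call(rbind, lapply(starts, function(s) data.frame(
      parent_id = "p", start = s, end = s + 18L, seq = strrep("A", 18),
      H = 0, muH = runif(1), z = 4L, klass = "cationic",
      stringsAsFactors = FALSE)))
    segs <- merge_windows(wins)
    covered <- sort(unique(unlist(
      lapply(seq_len(nrow(segs)), function(k) segs$start[k]:(segs$end[k] - 1)))))
    union_w <- sort(unique(unlist(lapply(starts, function(s) s:(s + 17)))))
    expect_equal(covered, union_w)
    if (nrow(segs) > 1) {
      expect_true(all(segs$start[-1] > segs$end[-nrow(segs)]))
    }
  }
})

test_that("find_anionic_tail returns the most C-terminal anionic segment", {
  tail18 <- "AEELAAEQALESSEMEEL"
  expect_true(net_charge(tail18) <= -3)
  seq <- paste0(strrep("G", 10), tail18)
  seg <- find_anionic_tail(seq)
  expect_false(is.null(seg))
  expect_equal(seg$end, nchar(seq))
  expect_null(find_anionic_tail(strrep("K", 30)))
  # shorter than a window: whole-sequence evaluation
  short <- "EAEASAEA"  # z = -4
  seg2 <- find_anionic_tail(short)
  expect_false(is.null(seg2))
  expect_equal(c(seg2$start, seg2$end), c(0L, nchar(short)))
})

test_that("helicity stand-in passes helix formers and fails breakers", {
  expect_true(helicity_check(strrep("A", 18))$pass)
  expect_false(helicity_check(strrep("G", 18))$pass)
  expect_false(helicity_check(strrep("P", 18))$pass)
  ext <- helicity_check("ALALALALAL", method = "external",
                        external_ss = "HHHHHHHHCC")
  expect_true(ext$pass)
  expect_equal(ext$helix_frac, 0.8)
  expect_error(helicity_check("AAAA", method = "external"),
               "external_ss")
})
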