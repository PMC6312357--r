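test_that("EDVID matching is exact by default, degenerate on request", {
  hit <- find_edvid("AAEDVIDAA")
  expect_equal(hit$start, 3L)
  expect_equal(hit$end - hit$start + 1L, 5L)
  expect_equal(hit$mismatches, 0L)
  expect_null(find_edvid("AAEDVIEAA"))
  near <- find_edvid("AAEDVIEAA", max_mismatch = 1)
  expect_equal(near$mismatches, 1L)
  expect_equal(near$start, 3L)
  # fewest mismatches wins over leftmost
  both <- find_edvid("EDVIAAAEDVIDAA", max_mismatch = 1)
  expect_equal(both$start, 8L)
  expect_equal(both$mismatches, 0L)
})

test_that("polar stretch requires >= theta of the 10 upstream residues", {
  mk <- function(stretch) stretch %+% "EDVID"
  all_polar <- find_polar_stretch(mk("SSTTNNQQDD"),
                                  find_edvid(mk("SSTTNNQQDD")))
  expect_equal(all_polar$start, 1L)
  expect_equal(all_polar$end, 10L)
  expect_null(find_polar_stretch(mk("LLLLLLLLLL"),
                                 find_edvid(mk("LLLLLLLLLL"))))
  # exactly 8 polar of 10 is a hit at the default threshold
  eight <- mk("SSTTNNQQLL")
  expect_false(is.null(find_polar_stretch(eight, find_edvid(eight))))
  seven <- mk("SSTTNNQLLL")
  expect_null(find_polar_stretch(seven, find_edvid(seven)))
  # fewer than 10 residues before EDVID: absent
  short <- "SSS" %+% "EDVID"
  expect_null(find_polar_stretch(short, find_edvid(short)))
})

test_that("pre-P-loop consensus matches V/IG x8 L/I x3 L", {
  hit <- find_preploop("VGAAAAAAAAIAAAL")
  expect_equal(hit$start, 1L)
  expect_equal(hit$vg, 1L)
  expect_equal(hit$end, 15L)
  expect_false(is.null(find_preploop("IGAAAAAAAALAAAL")))
  expect_null(find_preploop("VGAAAAAAAAAAAAL"))  # position 11 not L/I
  # leftmost match wins
  two <- "AAVGAAAAAAAALAAALAAAVGAAAAAAAALAAAL"
  expect_equal(find_preploop(two)$vg, 3L)
})

test_that("Walker A defines the ECC boundary after the pre-P-loop", {
  s <- "AAVGSSSSSSSSLSSSL" %+% "GMGGLGKTT"
  pre <- find_preploop(s)
  hit <- find_ploop(s, pre)
  expect_equal(hit$start, 18L)
  expect_equal(hit$matched_text, "GMGGLGKT")
  expect_null(find_ploop("MKLVNNNN"))
  # with two Walker A matches the leftmost after the pre-P-loop is chosen
  s2 <- s %+% "AAAGMGGLGKTT"
  expect_equal(find_ploop(s2, pre)$start, 18L)
})

test_that("charged window sits at -11..-3 of VG and counts D/E vs K/R", {
  s <- strrep("A", 88) %+% "EEDKRDEKE" %+% "AA" %+% "VG" %+% strrep("A", 13)
  ch <- locate_charged_motif(s, 100L)
  expect_equal(ch$start, 89L)
  expect_equal(ch$end, 97L)
  expect_equal(ch$end - ch$start + 1L, 9L)
  expect_equal(ch$n_acidic, 6L)
  expect_equal(ch$n_basic, 3L)
  expect_equal(ch$charged_fraction, 1)
  none <- locate_charged_motif(strrep("A", 120), 100L)
  expect_equal(none$charged_fraction, 0)
  expect_error(locate_charged_motif(strrep("A", 30), 10L), "out of range")
})

test_that("CC-END is the last a/d hydrophobic of the last helix", {
  set.seed(33)
  for (i in 1:20) {
    len <- sample(12:25, 1)
    chars <- sample(c("L", "I", "V", "A", "E", "Q"), len, replace = TRUE)
    s <- strrep("P", 5) %+% paste(chars, collapse = "") %+% strrep("P", 5)
    helices <- tibble::tibble(label = "H2b", start = 6L,
                              end = 5L + len)
    reg <- assign_heptad_register(s, helices)
    cc <- find_cc_end(s, reg, helices)
    # oracle: enumerate a/d hydrophobics directly
    regv <- strsplit(reg, "")[[1]]
    sv <- strsplit(s, "")[[1]]
    idx <- 6:(5 + len)
    ok <- idx[sv[idx] %in% c("L", "I", "V") & regv[idx] %in% c("a", "d")]
    if (length(ok) == 0L) {
      expect_null(cc)
    } else {
      expect_equal(cc, max(ok))
      expect_lte(cc, 5L + len)
    }
  }
  # helix with no hydrophobics at all
  s <- strrep("A", 20)
  helices <- tibble::tibble(label = "H2b", start = 1L, end = 20L)
  expect_null(find_cc_end(s, assign_heptad_register(s, helices), helices))
})

test_that("CCVX segment arithmetic and canonical flag", {
  s <- strrep("A", 200)
  charged <- locate_charged_motif(s, 149L)  # window 138..146
  ccvx <- extract_ccvx(s, 120L, charged)
  expect_equal(ccvx$start, 121L)
  expect_equal(ccvx$end, 137L)
  expect_equal(ccvx$length, 17L)
  expect_true(ccvx$canonical)
  far <- locate_charged_motif(s, 171L)  # window starts at 160
  long <- extract_ccvx(s, 120L, far)
  expect_equal(long$length, 39L)
  expect_false(long$canonical)
  expect_error(extract_ccvx(s, 140L, charged), "precede")
})

test_that("acylation motifs read positions 2-4", {
  a <- detect_acylation("MGGCS")
  expect_true(a$myristoylation)
  expect_true(a$palmitoylation)
  expect_false(detect_acylation("MAGCS")$myristoylation)
  expect_false(detect_acylation("MGGAS")$palmitoylation)
  expect_true(detect_acylation("MGGSA")$palmitoylation)  # Ser-4 counts
  expect_error(detect_acylation("MGG"), "shorter")
})
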