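test_that("FASTA records parse in order with residue validation", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">seq1 first", "ACDEFGHIKL", ">seq2", "MNPQR", "STVWY"), f)
  seqs <- read_fasta(f)
  expect_length(seqs, 2)
  expect_equal(names(seqs), c("seq1", "seq2"))
  expect_equal(nchar(seqs[["seq1"]]), 10)
  expect_equal(seqs[["seq2"]], "MNPQRSTVWY")
  writeLines(c(">bad", "ACDB"), f)
  expect_error(read_fasta(f), "non-standard residue")
  expect_silent(read_fasta(f, permissive = TRUE))
})

test_that("gravy matches hand-computed means and the scale definition", {
  expect_equal(gravy("AAAA"), 1.8)
  expect_equal(gravy("GI"), 2.05)
  expect_equal(gravy("ARNDCQEGHILKMFPSTWYV"), mean(kyte_doolittle))
  expect_error(gravy("ACDB"), "non-standard")
  expect_error(gravy(""), "empty")
  # concatenation: gravy is the length-weighted mean of the parts
  s1 <- "MKLVII"; s2 <- "DDEERRA"
  expect_equal(gravy(paste0(s1, s2)),
               (nchar(s1) * gravy(s1) + nchar(s2) * gravy(s2)) /
                 nchar(paste0(s1, s2)))
})

test_that("hydropathy profiles follow the sliding-window definition", {
  s <- "ACDEFGHIKLMNPQRSTVWY"
  p1 <- hydropathy_profile(s, window = 1)
  expect_equal(p1$scores, unname(kyte_doolittle[strsplit(s, "")[[1]]]))
  expect_equal(p1$positions, 1:20)
  expect_equal(mean(p1$scores), gravy(s))
  p9 <- hydropathy_profile(s, window = 9)
  expect_length(p9$scores, 20 - 9 + 1)
  expect_equal(p9$positions, 5:16)
  expect_equal(p9$scores[1],
               mean(kyte_doolittle[strsplit(substr(s, 1, 9), "")[[1]]]))
  expect_true(all(p9$scores >= -4.5 & p9$scores <= 4.5))
  # homopolymer: constant profile at the residue's scale value
  expect_equal(hydropathy_profile(strrep("L", 15), 5)$scores, rep(3.8, 11))
  # reversal reverses the window-1 profile
  rs <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(hydropathy_profile(rs, 1)$scores, rev(p1$scores))
  expect_error(hydropathy_profile(s, window = 4), "odd")
  expect_error(hydropathy_profile("ACD", window = 9), "longer")
})

test_that("low-hydropathy segments are maximal runs above a length floor", {
  # construct a profile from a synthetic sequence: K stretches are strongly
  # hydrophilic (-3.9), I stretches strongly hydrophobic (+4.5)
  seq <- paste0(strrep("I", 10), strrep("K", 14), strrep("I", 5),
                strrep("K", 12), strrep("I", 10))
  prof <- hydropathy_profile(seq, window = 1)
  segs <- low_hydropathy_segments(prof, threshold = -1.5, min_length = 10)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$start, c(11, 30))
  expect_equal(segs$end, c(24, 41))
  expect_equal(segs$mean_score, c(-3.9, -3.9))
  # raising the floor above the runs empties the list
  expect_equal(nrow(low_hydropathy_segments(prof, -1.5, 15)), 0)
  # all scores above threshold -> empty
  hot <- hydropathy_profile(strrep("I", 30), 9)
  expect_equal(nrow(low_hydropathy_segments(hot, -1.5, 3)), 0)
  # two runs separated by a single supra-threshold window stay separate
  seq2 <- paste0(strrep("K", 4), "I", strrep("K", 4))
  segs2 <- low_hydropathy_segments(hydropathy_profile(seq2, 1), 0, 2)
  expect_equal(nrow(segs2), 2)
})

test_that("the bundled RelA sequence behaves like a hydrophilic probe", {
  seqs <- read_fasta(rela_fasta())
  rela <- unname(seqs[1])
  expect_equal(nchar(rela), 551)
  g <- gravy(rela)
  expect_lt(g, 0)  # moderately hydrophilic overall
  prof <- hydropathy_profile(rela, window = 9)
  expect_length(prof$scores, 551 - 9 + 1)
  expect_equal(prof$gravy, g)
})
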