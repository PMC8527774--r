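test_that("aligned FASTA round-trips through read and write", {
  seqs <- c(mel = "ACGT-ACGTN", sim = "ACGTTAC--N", yak = "A--TTACGTN")
  path <- write_fixture_fasta(seqs)
  aln <- read_alignment(path)
  expect_s3_class(aln, "divscan_aln")
  expect_equal(aln$L, 10L)
  expect_equal(aln$seq, seqs)

  out <- tempfile(fileext = ".fasta")
  write_alignment(aln, out)
  again <- read_alignment(out)
  expect_equal(again$seq, aln$seq)
  expect_equal(again$L, aln$L)
})

test_that("alignment validation catches malformed input", {
  expect_equal(new_alignment(c(a = "ACGT", b = "ACGT"))$L, 4L)
  expect_error(new_alignment(c(a = "ACGT", b = "ACGTA")), "alignment-shape")
  expect_error(new_alignment(c(a = "ACXT", b = "ACGT")),
               "column 3.*|'X'")
  expect_error(new_alignment(c(a = "ACGT")), "at least 2")
  expect_error(new_alignment(c(a = "ACGT", a = "ACGT")), "duplicate")
  # empty file is a format error
  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_alignment(empty), "format error|no FASTA|no line")
  # lower case and U are normalised
  aln <- new_alignment(c(a = "acgu", b = "ACGT"))
  expect_equal(unname(aln$seq[1]), "ACGT")
})

test_that("extract_events finds substitutions and respects masking", {
  aln <- new_alignment(c(a = "ACGTACGT", b = "ACGTACGT"))
  ev <- extract_events(aln, "a", "b")
  expect_equal(ev$n, 0L)
  expect_equal(ev$L, 8L)

  aln <- new_alignment(c(a = "ACGTAC", b = "AGGTAT"))
  ev <- extract_events(aln, "a", "b")
  expect_equal(ev$positions, c(2L, 6L))
  expect_equal(ev$events$ref, c("C", "C"))
  expect_equal(ev$events$alt, c("G", "T"))

  aln <- new_alignment(c(a = "ANGT", b = "ACGT"))
  expect_equal(extract_events(aln, "a", "b")$n, 0L)

  expect_error(extract_events(aln, "a", "a"), "degenerate-input")
  expect_error(extract_events(aln, "a", "zzz"), "lookup")
})

test_that("indel runs are maximal, single events at their start column", {
  aln <- new_alignment(c(a = "AC--GT", b = "ACTAGT"))
  ev <- extract_events(aln, "a", "b", include_indels = TRUE)
  ind <- ev$events[ev$events$kind == "indel", ]
  expect_equal(nrow(ind), 1L)
  expect_equal(ind$column, 3L)
  expect_equal(ind$end, 4L)
  expect_equal(ind$inserted_in, "b")  # b carries the bases
  expect_equal(ev$positions, 3L)
  expect_equal(ev$n, 1L)
  # by default indels are not counted as events
  expect_equal(extract_events(aln, "a", "b")$n, 0L)

  # columns gapped in both sequences contribute nothing but stay in L
  aln2 <- new_alignment(c(a = "AC--GT", b = "AC--GA"))
  ev2 <- extract_events(aln2, "a", "b", include_indels = TRUE)
  expect_equal(ev2$L, 6L)
  expect_equal(ev2$positions, 6L)  # only the substitution
  expect_equal(ev2$universe, c(1L, 2L, 5L, 6L))

  # abutting gap runs in opposite sequences are two separate indels
  aln3 <- new_alignment(c(a = "A--TTT", b = "ATT--T"))
  ev3 <- extract_events(aln3, "a", "b", include_indels = TRUE)
  ind3 <- ev3$events[ev3$events$kind == "indel", ]
  expect_equal(ind3$column, c(2L, 4L))
  expect_equal(ind3$end, c(3L, 5L))
})

test_that("event extraction is symmetric and recovers planted mismatches", {
  set.seed(101)
  for (rep in 1:25) {
    L <- sample(20:80, 1)
    base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    other <- base
    k <- sample(0:8, 1)
    planted <- sort(sample(L, k))
    for (p in planted) {
      other[p] <- sample(setdiff(c("A", "C", "G", "T"), base[p]), 1)
    }
    aln <- new_alignment(c(x = paste(base, collapse = ""),
                           y = paste(other, collapse = "")))
    ev_xy <- extract_events(aln, "x", "y")
    ev_yx <- extract_events(aln, "y", "x")
    expect_identical(ev_xy$positions, planted)
    expect_identical(ev_yx$positions, ev_xy$positions)
    expect_identical(ev_xy$events$ref, ev_yx$events$alt)
    expect_lte(ev_xy$n, length(ev_xy$universe))
  }
})

test_that("coordinate maps anchor reference offsets and flag insertions", {
  aln <- new_alignment(c(ref = "AC-GT", oth = "ACTGT"))
  cm <- map_to_reference(aln, "ref", anchor_offset = -5L)
  expect_equal(cm$offset, c(-5L, -4L, -4L, -3L, -2L))
  expect_equal(cm$insertion, c(FALSE, FALSE, TRUE, FALSE, FALSE))

  gapless <- new_alignment(c(ref = "ACGTT", oth = "ACGTA"))
  cm2 <- map_to_reference(gapless, "ref", anchor_offset = 1L)
  expect_equal(cm2$offset, 1:5)

  allgap <- new_alignment(c(ref = "-----", oth = "ACGTA"))
  expect_error(map_to_reference(allgap, "ref"), "all gaps")
  expect_error(map_to_reference(aln, "nope"), "lookup")

  # leading insertions have no preceding reference base
  lead <- new_alignment(c(ref = "--ACG", oth = "TTACG"))
  cm3 <- map_to_reference(lead, "ref", anchor_offset = 10L)
  expect_true(all(is.na(cm3$offset[1:2])))
  expect_equal(cm3$offset[3:5], 10:12)

  expect_equal(map_interval(cm, 1, 5), c(-5L, -2L))
  expect_error(map_interval(cm, 0, 2), "out of range")
})

test_that("events and intervals export as TSV and 0-based half-open BED", {
  aln <- new_alignment(c(a = "ACGTAC", b = "AGGTAT"))
  ev <- extract_events(aln, "a", "b")
  tsv <- tempfile(fileext = ".tsv")
  write_events_tsv(ev, tsv)
  back <- read.delim(tsv)
  expect_equal(back$column, c(2L, 6L))
  expect_equal(back$kind, rep("substitution", 2))

  bed <- tempfile(fileext = ".bed")
  write_bed(data.frame(start = 2L, end = 6L, name = "hs1", score = 0.5), bed)
  b <- read.delim(bed, header = FALSE)
  expect_equal(b$V2, 1L)   # 0-based start
  expect_equal(b$V3, 6L)   # half-open end

  cm <- map_to_reference(aln, "a", anchor_offset = -100L)
  write_bed(data.frame(start = 2L, end = 6L), bed, cm)
  b2 <- read.delim(bed, header = FALSE)
  expect_equal(b2$V1, "a")
  expect_equal(b2$V2, -100L)  # ref offset -99, 0-based
  expect_equal(b2$V3, -95L)
})
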