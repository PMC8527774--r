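test_that("single-step codon changes classify by the genetic code", {
  expect_equal(classify_codon_change("TTA", "CTA"), c(syn = 1, nonsyn = 0))
  expect_equal(classify_codon_change("ATG", "ATA"), c(syn = 0, nonsyn = 1))
  expect_equal(classify_codon_change("AAA", "AAA"), c(syn = 0, nonsyn = 0))
  expect_error(classify_codon_change("TAA", "AAA"), "stop-codon")
  expect_error(classify_codon_change("ANA", "AAA"), "ambiguity")
  expect_error(classify_codon_change("AA", "AAA"), "ambiguity")
})

test_that("pathway averaging matches the brute-force enumerator", {
  set.seed(77)
  sense <- sense_codons()
  pairs <- cbind(sample(sense, 250, replace = TRUE),
                 sample(sense, 250, replace = TRUE))
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    got <- classify_codon_change(a, b)
    want <- oracle_classify(a, b)
    expect_equal(got, want, tolerance = 1e-12,
                 info = paste(a, "->", b))
    k <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(unname(got[["syn"]] + got[["nonsyn"]]), k)
  }
})

test_that("stop-skirting pathways are excluded from the average", {
  # TGT -> TGG and TAT -> TAG are… both TGG/TAG sense? TAG is stop; craft a
  # pair whose orderings differ in stop exposure: TGC (Cys) -> TTA (Leu)
  # passes through TGA (stop) on one ordering.
  got <- classify_codon_change("TGC", "TTA")
  want <- oracle_classify("TGC", "TTA")
  expect_equal(got, want, tolerance = 1e-12)
  # the valid-pathway set is a strict subset here, so the average must
  # differ from the all-pathways average
  all_paths <- oracle_pathways("TGC", "TTA")
  expect_true(any(vapply(all_paths, `[[`, logical(1), "hit_stop")))
})

test_that("count_mk tallies polymorphism and divergence per codon", {
  # no variation at all
  p0 <- codon_panel(c(a = "ATGAAA", b = "ATGAAA", c = "ATGAAA"), "ATGAAA")
  t0 <- count_mk(p0)
  expect_equal(unlist(t0[c("Dn", "Ds", "Pn", "Ps")]),
               c(Dn = 0, Ds = 0, Pn = 0, Ps = 0))

  # one fixed nonsynonymous difference
  p1 <- codon_panel(c(a = "ATG", b = "ATG", c = "ATG"), "ATA")
  t1 <- count_mk(p1)
  expect_equal(unlist(t1[c("Dn", "Ds", "Pn", "Ps")]),
               c(Dn = 1, Ds = 0, Pn = 0, Ps = 0))

  # one synonymous polymorphism
  p2 <- codon_panel(c(a = "TTA", b = "TTA", c = "CTA"), "TTA")
  t2 <- count_mk(p2)
  expect_equal(unlist(t2[c("Dn", "Ds", "Pn", "Ps")]),
               c(Dn = 0, Ds = 0, Pn = 0, Ps = 1))

  # polymorphic AND divergent counts as polymorphic only
  p3 <- codon_panel(c(a = "TTA", b = "TTA", c = "CTA"), "TTG")
  t3 <- count_mk(p3)
  expect_equal(unlist(t3[c("Dn", "Ds", "Pn", "Ps")]),
               c(Dn = 0, Ds = 0, Pn = 0, Ps = 1))

  # codons with gaps in the outgroup are skipped with a warning
  p4 <- codon_panel(c(a = "ATGTTA", b = "ATGTTA", c = "ATGCTA"), "ATG---")
  expect_warning(t4 <- count_mk(p4), "skipped")
  expect_equal(unlist(t4[c("Dn", "Ds", "Pn", "Ps")]),
               c(Dn = 0, Ds = 0, Pn = 0, Ps = 0))

  expect_error(codon_panel(c(a = "ATGA", b = "ATGA"), "ATGA"), "frame")
})

test_that("allele-frequency filtering is monotone and drops rare alleles", {
  # 1 derived allele among 10 strains: frequency 0.1
  ing <- c(rep("TTA", 9), "CTA")
  names(ing) <- sprintf("s%02d", 1:10)
  panel <- codon_panel(ing, "TTA")
  at0 <- count_mk(panel, maf_threshold = 0)
  expect_equal(at0$Ps, 1)
  # threshold at or above the allele frequency removes it
  filtered <- count_mk(panel, maf_threshold = 0.1)
  expect_equal(filtered$Ps, 0)
  expect_equal(filtered$Pn, 0)
  # the site reverts to monomorphic-and-equal-to-outgroup: no divergence
  expect_equal(filtered$Dn + filtered$Ds, 0)
  # monotone: higher threshold never increases Pn or Ps
  for (th in c(0, 0.05, 0.1, 0.3)) {
    tt <- count_mk(panel, maf_threshold = th)
    expect_lte(tt$Ps, at0$Ps)
    expect_lte(tt$Pn, at0$Pn)
  }
})

test_that("mk_significance reproduces textbook chi-square arithmetic", {
  # equal ratios: statistic 0, p 1
  r0 <- mk_significance(mk_table(Dn = 10, Ds = 40, Pn = 2, Ps = 8))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # maximally unbalanced: all expected cells are 5, chi-square 20
  r1 <- mk_significance(mk_table(Dn = 10, Ds = 0, Pn = 0, Ps = 10))
  expect_equal(r1$statistic, 20)
  expect_lt(r1$p_value, 1e-4)

  expect_error(mk_significance(mk_table(0, 0, 0, 0)), "degenerate-table")
  expect_error(mk_significance(mk_table(Dn = 3, Ds = 4, Pn = 0, Ps = 0)),
               "fisher")

  # random integer tables match stats::chisq.test without correction
  set.seed(55)
  for (rep in 1:50) {
    m <- matrix(sample(1:30, 4, replace = TRUE), 2, 2)
    got <- mk_significance(m, method = "chi2")
    ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-10)
  }

  # G-test agrees with the likelihood-ratio form
  g <- mk_significance(mk_table(Dn = 12, Ds = 5, Pn = 3, Ps = 14),
                       method = "gtest")
  expect_gt(g$statistic, 0)
  expect_lt(g$p_value, 0.05)

  # Fisher on fractional counts warns about rounding
  expect_warning(
    f <- mk_significance(mk_table(Dn = 10.5, Ds = 3, Pn = 2, Ps = 8),
                         method = "fisher"),
    "rounded")
  expect_true(f$p_value > 0 && f$p_value <= 1)
})

test_that("region-based counting contrasts upstream with silent sites", {
  # layout: columns 1-6 upstream, 7-12 intron, 13-21 cds (3 codons)
  up_in <- "AAAAAA"; up_in2 <- "AAAAAC"          # 1 upstream polymorphism
  up_out <- "TTTAAA"                             # 3 upstream fixed
  intr_in <- "GGGGGG"
  intr_out <- "CCGGGG"                           # 2 intron fixed
  # cds: codon1 TTA/TTA vs TTG (syn fixed); codon2 polymorphic CTA~TTA
  # (syn, x2 via two strains? no: one minor allele = 1 change); use two
  # polymorphic codons for 2 synonymous polymorphisms
  cds_a <- paste0("TTA", "CTA", "GGA")
  cds_b <- paste0("TTA", "TTA", "GGG")           # strains differ at codons 2,3
  cds_o <- paste0("TTG", "CTA", "GGA")
  seqs <- c(s1 = paste0(up_in, intr_in, cds_a),
            s2 = paste0(up_in2, intr_in, cds_b),
            s3 = paste0(up_in, intr_in, cds_a),
            out = paste0(up_out, intr_out, cds_o))
  aln <- new_alignment(seqs)
  regions <- data.frame(label = c("upstream", "intron", "cds"),
                        start = c(1L, 7L, 13L), end = c(6L, 12L, 21L))
  tab <- count_region_mk(aln, "out", regions)
  expect_equal(tab$counts["fixed", "upstream"], 3)
  expect_equal(tab$counts["polymorphic", "upstream"], 1)
  expect_equal(tab$counts["fixed", "silent"], 2 + 1)   # introns + synonymous
  expect_equal(tab$counts["polymorphic", "silent"], 2) # CTA~TTA, GGA~GGG
  res <- mk_significance(tab)
  expect_true(res$p_value > 0 && res$p_value <= 1)

  overlapping <- data.frame(label = c("upstream", "intron"),
                            start = c(1L, 5L), end = c(6L, 12L))
  expect_error(count_region_mk(aln, "out", overlapping), "overlapping")
  bad_label <- data.frame(label = "promoter", start = 1L, end = 6L)
  expect_error(count_region_mk(aln, "out", bad_label), "unknown region")
})
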