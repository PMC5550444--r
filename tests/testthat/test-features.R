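ctx_for <- function(tg, pos, alt = NULL) {
  ref <- get_sequence(tg$genome, "chrT", pos, pos)
  if (is.null(alt)) alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  v <- list(contig = "chrT", pos = pos, ref = ref, alt = alt)
  list(v = v, ctx = locate_variant(v, tg$transcripts)[[1]])
}

test_that("donor GT core disruption lowers the donor score", {
  tg <- toy_gene("+")
  pssms <- toy_pssms("+")
  # exon2 donor junction: exon2 ends at 73, intron2 starts 74 with GT
  x <- ctx_for(tg, 75L, alt = "C")     # the T of the GT core
  expect_equal(x$v$ref, "T")
  d <- splice_site_delta(x$ctx, tg$genome, pssms)
  expect_lt(d[["don_score_alt"]], d[["don_score_ref"]])
  expect_lt(d[["don_delta"]], 0)
  expect_equal(d[["acc_delta"]], 0)
})

test_that("variants outside both splice windows leave all deltas at zero", {
  tg <- toy_gene("+")
  pssms <- toy_pssms("+")
  x <- ctx_for(tg, 65L)                # mid-exon2, outside both windows
  d <- splice_site_delta(x$ctx, tg$genome, pssms)
  expect_equal(d[["acc_delta"]], 0)
  expect_equal(d[["don_delta"]], 0)
  expect_equal(d[["acc_score_alt"]], d[["acc_score_ref"]])
})

test_that("cryptic donor creation is gated on a GT core change and can be strong", {
  tg <- toy_gene("+")
  pssms <- toy_pssms("+")
  # exon2 carries ATCGAAAGT at exon offsets 4-12; offset 8 (genomic 65)
  # A>T completes ATCGTAAGT, the per-position argmax of the toy matrices
  x <- ctx_for(tg, 65L, alt = "T")
  expect_equal(x$v$ref, "A")
  cs <- cryptic_site_scan(x$v, x$ctx, tg$genome, pssms)
  expect_gt(cs[["cryptic5_score"]], 84)   # a strong cryptic donor
  expect_equal(cs[["cryptic3_score"]], 0)
  expect_equal(cs[["cryptic5_lost"]], 0)

  # a substitution changing no AG/GT core scores zero everywhere
  y <- ctx_for(tg, 59L, alt = "C")        # exon2 offset 2: A>C, coreless
  cs0 <- cryptic_site_scan(y$v, y$ctx, tg$genome, pssms)
  expect_true(all(cs0 == 0))
})

test_that("interaction summaries follow the weak-site weighting logic", {
  splice <- c(acc_score_ref = 80, acc_score_alt = 80, don_score_ref = 95,
              don_score_alt = 95, acc_delta = 0, don_delta = 0)
  cryptic <- c(cryptic5_score = 90, cryptic3_score = 0,
               cryptic5_lost = 0, cryptic3_lost = 0)
  # strong existing donor (95) nullifies a cryptic at 90
  i1 <- interaction_scores(splice, cryptic)
  expect_equal(i1[["splice_site_overall"]], 0)
  # weak existing donor (60): contribution 30
  splice["don_score_ref"] <- 60
  i2 <- interaction_scores(splice, cryptic)
  expect_equal(i2[["splice_site_overall"]], 30)
  # engineered fixture arithmetic: weak donor 55, cryptic 88 -> 33
  splice["don_score_ref"] <- 55
  cryptic["cryptic5_score"] <- 88
  i3 <- interaction_scores(splice, cryptic)
  expect_equal(i3[["variant_splice_score"]], 33)
  # worst-damage summary picks up losses and negative deltas
  splice["don_delta"] <- -40
  i4 <- interaction_scores(splice, cryptic)
  expect_equal(i4[["variant_splice_score"]], 40)
})

test_that("regulatory scan counts per-offset k-mer gains and losses", {
  tg <- toy_gene("+")
  motifs <- trapscore:::toy_motif_sets()
  # exon1 = CTCCATACCTTCATC carries SRSF2 CTCCAT (offset 1) and
  # SRSF5 ACCTTC (offset 7)
  x <- ctx_for(tg, 25L, alt = "A")   # exon offset 10 T>A breaks ACCTTC
  expect_equal(x$v$ref, "T")
  e <- esr_scan(x$v, x$ctx, tg$genome, motifs)
  expect_equal(e[["esr_disrupted"]], 1)
  expect_equal(e[["esr_created"]], 0)
  expect_equal(e[["combined_esr_score"]], -1)
  expect_equal(e[["negated_esr_score"]], -1)

  # intronic variants are gated to all zeros
  xi <- ctx_for(tg, 45L)
  expect_equal(xi$ctx$region, "intronic")
  ei <- esr_scan(xi$v, xi$ctx, tg$genome, motifs)
  expect_true(all(ei == 0))

  # a variant overlapping no motif in either allele counts nothing
  xn <- ctx_for(tg, 70L, alt = "A")
  en <- esr_scan(xn$v, xn$ctx, tg$genome, motifs)
  expect_true(all(en == 0))
})

test_that("a variant destroying an enhancer and creating a silencer scores -2", {
  # custom sets sharing one flip: enhancer ACCTCA, silencer ACGTCA... use
  # exon sequence containing ACCTCA; C>T at offset 3 yields ATCTCA (silencer)
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">c1", paste0("CCCCC", "AAGCACCTCACTT", "GTAAGTCC",
                             "TTTTTTTTTTTTTTCTCCAG", "GTTCCAAAA")), fa)
  genome <- load_genome(fa)
  tx <- structure(list(id = "t", gene_id = "g", contig = "c1", strand = "+",
                       exons = data.frame(start = c(6L, 47L),
                                          end = c(18L, 55L))),
                  class = "transcript")
  enh <- structure(list(name = "E", role = "enhancer", k = 6L,
                        kmers = c(ACCTCA = 1)), class = "motif_set")
  sil <- structure(list(name = "S", role = "silencer", k = 6L,
                        kmers = c(ATCTCA = 1)), class = "motif_set")
  v <- list(contig = "c1", pos = 11L, ref = "C", alt = "T")
  ctx <- locate_variant(v, list(tx))[[1]]
  e <- esr_scan(v, ctx, genome, list(enh, sil))
  expect_equal(e[["esr_disrupted"]], 1)
  expect_equal(e[["silencer_created"]], 1)
  expect_equal(e[["combined_esr_score"]], -2)
})

test_that("CpG gains and losses classify across both frames", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">c1", "ATCGATTTGA"), fa)
  genome <- load_genome(fa)
  expect_equal(cpg_feature(list(contig = "c1", pos = 3L, ref = "C",
                                alt = "T"), genome), "destroys_cpg")
  expect_equal(cpg_feature(list(contig = "c1", pos = 8L, ref = "T",
                                alt = "C"), genome), "creates_cpg")
  expect_equal(cpg_feature(list(contig = "c1", pos = 6L, ref = "T",
                                alt = "A"), genome), "none")
})

test_that("swapping ref and alt swaps created and disrupted counts", {
  tg <- toy_gene("+")
  pssms <- toy_pssms("+")
  motifs <- trapscore:::toy_motif_sets()
  set.seed(7)
  span <- 16:115
  for (pos in sample(span, 20)) {
    ref <- get_sequence(tg$genome, "chrT", pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      v <- list(contig = "chrT", pos = pos, ref = ref, alt = alt)
      ctx <- locate_variant(v, tg$transcripts)[[1]]
      fwd <- esr_scan(v, ctx, tg$genome, motifs)
      cfwd <- cryptic_site_scan(v, ctx, tg$genome, pssms)
      # mutate the genome, then assess the reverse substitution
      mut <- as.character(tg$genome$seq[["chrT"]])
      substr(mut, pos, pos) <- alt
      g2 <- structure(list(seq = Biostrings::DNAStringSet(c(chrT = mut))),
                      class = "genome")
      v2 <- list(contig = "chrT", pos = pos, ref = alt, alt = ref)
      ctx2 <- locate_variant(v2, list(tg$tx))[[1]]
      rev <- esr_scan(v2, ctx2, g2, motifs)
      crev <- cryptic_site_scan(v2, ctx2, g2, pssms)
      expect_equal(fwd[["esr_created"]], rev[["esr_disrupted"]])
      expect_equal(fwd[["esr_disrupted"]], rev[["esr_created"]])
      expect_equal(cfwd[["cryptic5_score"]], crev[["cryptic5_lost"]])
      expect_equal(cfwd[["cryptic5_lost"]], crev[["cryptic5_score"]])
    }
  }
})

test_that("a variant and its mirror-image counterpart produce identical vectors", {
  tgp <- toy_gene("+")
  tgm <- toy_gene("-")
  pp <- toy_pssms("+")
  pm <- toy_pssms("-")
  expect_equal(pp$donor$freq, pm$donor$freq)   # same sites, mirrored genome
  motifs <- trapscore:::toy_motif_sets()
  L <- nchar(toy_contig_string())
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  set.seed(8)
  for (pos in sample(16:115, 15)) {
    ref <- get_sequence(tgp$genome, "chrT", pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    v <- list(contig = "chrT", pos = pos, ref = ref, alt = alt)
    fp <- assemble_features(v, locate_variant(v, tgp$transcripts),
                            tgp$genome, pp, motifs, NULL)
    vm <- list(contig = "chrT", pos = L - pos + 1L,
               ref = comp[[ref]], alt = comp[[alt]])
    fm <- assemble_features(vm, locate_variant(vm, tgm$transcripts),
                            tgm$genome, pm, motifs, NULL)
    expect_equal(fp[, feature_registry()], fm[, feature_registry()],
                 tolerance = 1e-9)
  }
})

test_that("every SNV on the toy gene matches the brute-force oracle", {
  for (strand in c("+", "-")) {
    tg <- toy_gene(strand)
    pssms <- toy_pssms(strand)
    motifs <- trapscore:::toy_motif_sets()
    span <- if (strand == "+") 16:115
            else (nchar(toy_contig_string()) - 115 + 1):(
              nchar(toy_contig_string()) - 16 + 1)
    mism <- 0L
    for (pos in span) {
      ref <- get_sequence(tg$genome, "chrT", pos, pos)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        v <- list(contig = "chrT", pos = pos, ref = ref, alt = alt)
        got <- assemble_features(v, locate_variant(v, tg$transcripts),
                                 tg$genome, pssms, motifs, NULL)
        want <- oracle_features(v, tg$tx, tg$genome, pssms, motifs)
        ok <- isTRUE(all.equal(unlist(got[1, feature_registry()]),
                               want[feature_registry()],
                               tolerance = 1e-9,
                               check.attributes = FALSE))
        if (!ok) mism <- mism + 1L
      }
    }
    expect_equal(mism, 0L)
  }
})

test_that("assembled vectors impute missing conservation with a flag", {
  tg <- toy_gene("+")
  pssms <- toy_pssms("+")
  tsv <- tempfile(fileext = ".tsv")
  writeLines("chrT\t65\t4.2", tsv)
  cons <- load_conservation(tsv)
  v <- list(contig = "chrT", pos = 65L, ref = "A", alt = "T")
  f1 <- assemble_features(v, locate_variant(v, tg$transcripts),
                          tg$genome, pssms, list(), cons)
  expect_equal(f1$gerp_rs, 4.2)
  expect_equal(f1$gerp_missing, 0L)
  v2 <- list(contig = "chrT", pos = 66L, ref = "A", alt = "T")
  f2 <- assemble_features(v2, locate_variant(v2, tg$transcripts),
                          tg$genome, pssms, list(), cons)
  expect_equal(f2$gerp_rs, 0)
  expect_equal(f2$gerp_missing, 1L)
  expect_equal(names(f2)[7:26], feature_registry())
})
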