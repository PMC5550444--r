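test_that("only G[T/C]..AG introns train the matrices", {
  # two genes: one GT..AG intron, one AT..AC intron
  mk <- function(intron_core) {
    paste0("CCCCCAAGCTT",                       # exon1 (11)
           intron_core,                         # intron (30)
           "GTTCCCCCCCC")                       # exon2 (11)
  }
  good_intron <- paste0("GTAAGT", "CCCC", "TTTTTTTTTTTTTTCTCC", "AG")
  expect_equal(nchar(good_intron), 30)
  bad_intron <- paste0("AT", substr(good_intron, 3, 28), "AC")
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">g1", mk(good_intron), ">g2", mk(bad_intron)), fa)
  genome <- load_genome(fa)
  tx <- function(contig) {
    structure(list(id = paste0(contig, ".t"), gene_id = contig,
                   contig = contig, strand = "+",
                   exons = data.frame(start = c(1L, 42L),
                                      end = c(11L, 52L))),
              class = "transcript")
  }
  pssms <- build_pssms(list(tx("g1"), tx("g2")), genome)
  expect_equal(pssms$donor$n_sites, 1L)        # only the GT..AG intron
  expect_equal(pssms$acceptor$n_sites, 1L)
  # all donor windows identical -> dominant base probability (1+1)/(1+4)
  expect_equal(max(pssms$donor$freq), 2 / 5)

  # a genome with zero qualifying introns errors
  writeLines(c(">g2", mk(bad_intron)), fa)
  expect_error(build_pssms(list(tx("g2")), load_genome(fa)),
               "no qualifying")
})

test_that("matrix frequencies equal hand-tallied counts with pseudocount", {
  fx <- small_fixture()
  pssms <- fx$pssms
  # hand tally: re-extract every qualifying donor window by brute force
  wins <- character(0)
  for (tx in fx$transcripts) {
    introns <- trapscore:::tx_introns(tx)
    for (j in seq_len(nrow(introns))) {
      iseq <- get_sequence(fx$genome, tx$contig, introns$start[j],
                           introns$end[j], tx$strand)
      first2 <- substr(iseq, 1, 2)
      last2 <- substr(iseq, nchar(iseq) - 1, nchar(iseq))
      if (!(first2 %in% c("GT", "GC")) || last2 != "AG") next
      if (tx$strand == "+") {
        e <- tx$exons$end[j]
        w <- get_sequence(fx$genome, tx$contig, e - 2, e + 6, "+")
      } else {
        s <- tx$exons$start[j]
        w <- get_sequence(fx$genome, tx$contig, s - 6, s + 2, "-")
      }
      wins <- c(wins, w)
    }
  }
  expect_equal(length(wins), pssms$donor$n_sites)
  tally <- matrix(0, 9, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (w in wins) {
    b <- strsplit(w, "")[[1]]
    for (i in 1:9) tally[i, b[i]] <- tally[i, b[i]] + 1
  }
  expect_equal(pssms$donor$freq,
               (tally + 1) / (length(wins) + 4), tolerance = 1e-12)
})

test_that("raw and normalized scores match brute-force enumeration", {
  # closed form: uniform frequencies, K = 9
  unif <- structure(list(site_class = "u", K = 9L,
                         freq = matrix(0.25, 9, 4,
                                       dimnames = list(NULL,
                                                       c("A", "C", "G", "T"))),
                         pseudocount = 0, n_sites = NA, bounds = "analytic",
                         min_raw = 9 * log2(0.25), max_raw = 9 * log2(0.25)),
                    class = "pssm")
  expect_equal(raw_score(unif, "ACGTACGTA"), -18)
  expect_error(normalized_score(unif, "ACGTACGTA"), "degenerate")

  for (K in c(3L, 4L, 6L)) {
    p <- toy_pssm(K, seed = K)
    motifs <- do.call(expand.grid,
                      rep(list(c("A", "C", "G", "T")), K))
    motifs <- apply(motifs, 1, paste, collapse = "")
    raws <- vapply(motifs, function(m) {
      b <- strsplit(m, "")[[1]]
      s <- 0
      for (i in seq_len(K)) s <- s + log2(p$freq[i, b[i]])
      s
    }, 0)
    expect_equal(min(raws), p$min_raw, tolerance = 1e-9)
    expect_equal(max(raws), p$max_raw, tolerance = 1e-9)
    impl_raw <- vapply(motifs, raw_score, 0, pssm = p)
    expect_equal(unname(impl_raw), unname(raws), tolerance = 1e-9)
    impl_norm <- vapply(motifs, normalized_score, 0, pssm = p)
    expect_equal(unname(impl_norm),
                 unname(100 * (raws - min(raws)) / (max(raws) - min(raws))),
                 tolerance = 1e-9)
  }
})

test_that("argmax motif scores exactly 100 and argmin exactly 0", {
  p <- toy_pssm(6L, seed = 42)
  bases <- c("A", "C", "G", "T")
  argmax <- paste(bases[apply(p$freq, 1, which.max)], collapse = "")
  argmin <- paste(bases[apply(p$freq, 1, which.min)], collapse = "")
  expect_identical(normalized_score(p, argmax), 100)
  expect_identical(normalized_score(p, argmin), 0)
})

test_that("replacing a base by a higher-frequency base never lowers scores", {
  p <- toy_pssm(5L, seed = 9)
  bases <- c("A", "C", "G", "T")
  set.seed(1)
  for (rep in 1:25) {
    m <- paste(sample(bases, 5, replace = TRUE), collapse = "")
    i <- sample(5, 1)
    cur <- substr(m, i, i)
    higher <- bases[p$freq[i, ] >= p$freq[i, cur]]
    for (b in higher) {
      m2 <- m
      substr(m2, i, i) <- b
      expect_gte(raw_score(p, m2), raw_score(p, m) - 1e-12)
      expect_gte(normalized_score(p, m2), normalized_score(p, m) - 1e-12)
    }
  }
})

test_that("site windows follow the 23/9-nt definitions on both strands", {
  for (strand in c("+", "-")) {
    tg <- toy_gene(strand)
    pos <- if (strand == "+") 65L else nchar(toy_contig_string()) - 65L + 1L
    v <- list(contig = "chrT", pos = pos,
              ref = get_sequence(tg$genome, "chrT", pos, pos), alt = "N")
    ctx <- locate_variant(v, tg$transcripts)[[1]]
    expect_equal(ctx$exon_index, 2L)
    w <- site_windows(ctx, tg$genome)
    parts <- toy_gene_parts()
    # acceptor: last 20 nt of intron1 + first 3 nt of exon2 (oriented)
    expect_equal(w$acceptor$ref,
                 paste0(substr(parts$intron1, 8, 27),
                        substr(parts$exon2, 1, 3)))
    # donor: last 3 nt of exon2 + first 6 nt of intron2
    expect_equal(w$donor$ref,
                 paste0(substr(parts$exon2, 14, 16),
                        substr(parts$intron2, 1, 6)))
  }
})

test_that("terminal exons have missing acceptor/donor windows", {
  tg <- toy_gene("+")
  v1 <- list(contig = "chrT", pos = 20L, ref = "N", alt = "N")
  ctx1 <- locate_variant(v1, tg$transcripts)[[1]]
  w1 <- site_windows(ctx1, tg$genome)
  expect_true(is.na(w1$acceptor$ref))
  expect_false(is.na(w1$donor$ref))
  v3 <- list(contig = "chrT", pos = 110L, ref = "N", alt = "N")
  ctx3 <- locate_variant(v3, tg$transcripts)[[1]]
  w3 <- site_windows(ctx3, tg$genome)
  expect_false(is.na(w3$acceptor$ref))
  expect_true(is.na(w3$donor$ref))
})

test_that("identical inputs rebuild bit-identical matrices and serialization round-trips", {
  tg <- toy_gene("+")
  p1 <- build_pssms(tg$transcripts, tg$genome)
  p2 <- build_pssms(tg$transcripts, tg$genome)
  expect_identical(p1, p2)

  f <- tempfile(fileext = ".tsv")
  write_pssms(p1, f)
  back <- read_pssms(f)
  expect_equal(back$donor$freq, p1$donor$freq, tolerance = 1e-12)
  expect_equal(back$acceptor$min_raw, p1$acceptor$min_raw, tolerance = 1e-12)
  expect_equal(back$donor$K, 9L)
  expect_equal(back$acceptor$K, 23L)
})

test_that("annotated-bounds option normalizes observed sites into [0, 100]", {
  fx <- small_fixture()
  pa <- build_pssms(fx$transcripts, fx$genome, bounds = "annotated")
  expect_true(pa$donor$min_raw >= fx$pssms$donor$min_raw)
  expect_true(pa$donor$max_raw <= fx$pssms$donor$max_raw)
  for (tx in fx$transcripts[1:2]) {
    introns <- trapscore:::tx_introns(tx)
    for (j in seq_len(nrow(introns))) {
      if (tx$strand == "+") {
        e <- tx$exons$end[j]
        w <- get_sequence(fx$genome, tx$contig, e - 2, e + 6, "+")
      } else {
        s <- tx$exons$start[j]
        w <- get_sequence(fx$genome, tx$contig, s - 6, s + 2, "-")
      }
      sc <- normalized_score(pa$donor, w)
      expect_gte(sc, 0)
      expect_lte(sc, 100)
    }
  }
})
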