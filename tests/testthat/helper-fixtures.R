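# Shared fixtures, built in code.

# A hand-built 3-exon toy gene on a 130-nt contig (gene span 100 nt).
# Layout (1-based, + strand):
#   flank 1-15 | exon1 16-30 | intron1 31-57 | exon2 58-73 |
#   intron2 74-100 | exon3 101-115 | flank 116-130
# Both introns are GT..AG.  Donor/acceptor windows carry consensus-like
# cores; exon2 carries a pre-cryptic donor (GA proto-core).
toy_gene_parts <- function() {
  list(
    flank1  = "CACCTACTACCATCA",
    exon1   = "CTCCATACCTTCATC",                       # 15
    intron1 = paste0("GTAAGT", "C", "TTTTTTTTTTTTTTCTCC", "AG"),  # 27
    exon2   = "CACATCGAAAGTCACC",                      # 16, GA proto-core
    intron2 = paste0("GTAAGT", "C", "TTCTTTTTTTTCTTCTCC", "AG"),  # 27
    exon3   = "GTCCTCACCATCTCA",                       # 15
    flank2  = "CATTCACCATCCACT")
}

toy_contig_string <- function() {
  paste(unlist(toy_gene_parts()), collapse = "")
}

# genome + transcripts for the toy gene, either strand orientation.
# The "-" version is the reverse complement of the same contig with all
# exon coordinates mirrored, so both describe the same transcript.
toy_gene <- function(strand = "+") {
  s <- toy_contig_string()
  L <- nchar(s)
  exons_plus <- data.frame(start = c(16L, 58L, 101L),
                           end = c(30L, 73L, 115L))
  if (strand == "+") {
    contig_seq <- s
    exons <- exons_plus
  } else {
    contig_seq <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    # mirroring preserves transcription order: tx exon i maps to the
    # mirrored coordinates of plus-strand exon i (descending genomic start)
    exons <- data.frame(start = L - exons_plus$end + 1L,
                        end = L - exons_plus$start + 1L)
  }
  genome <- structure(
    list(seq = Biostrings::DNAStringSet(c(chrT = contig_seq))),
    class = "genome")
  tx <- structure(list(id = "toy.t1", gene_id = "toy", contig = "chrT",
                       strand = strand, exons = exons),
                  class = "transcript")
  list(genome = genome, transcripts = list(toy.t1 = tx), tx = tx)
}

toy_pssms <- function(strand = "+") {
  tg <- toy_gene(strand)
  build_pssms(tg$transcripts, tg$genome)
}

# A small random-frequency PSSM for brute-force oracle tests.
toy_pssm <- function(K = 4L, seed = 1L) {
  set.seed(seed)
  counts <- matrix(sample(1:9, K * 4, replace = TRUE), K, 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  freq <- counts / rowSums(counts)
  structure(list(site_class = "toy", K = K, freq = freq, pseudocount = 0,
                 n_sites = NA_integer_, bounds = "analytic",
                 min_raw = sum(apply(log2(freq), 1, min)),
                 max_raw = sum(apply(log2(freq), 1, max))),
            class = "pssm")
}

# Cached synthetic bundles (generated once per test run).
.fixture_cache <- new.env(parent = emptyenv())

small_fixture <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- end_to_end_fixture(
      sim_config(n_genes = 6L, n_variants = 60L, seed = 3L),
      dir = file.path(tempdir(), "trapscore-small-fixture"))
  }
  .fixture_cache$small
}

default_fixture <- function() {
  if (is.null(.fixture_cache$default)) {
    .fixture_cache$default <- end_to_end_fixture(
      sim_config(seed = 11L),
      dir = file.path(tempdir(), "trapscore-default-fixture"))
  }
  .fixture_cache$default
}

default_features <- function() {
  if (is.null(.fixture_cache$default_feats)) {
    fx <- default_fixture()
    cons <- load_conservation(fx$paths[["conservation"]])
    .fixture_cache$default_feats <- featurize_variants(
      fx$variants, fx$transcripts, fx$genome, fx$pssms, fx$motif_sets, cons)
  }
  .fixture_cache$default_feats
}
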