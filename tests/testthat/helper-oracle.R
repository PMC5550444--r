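# Independent brute-force feature oracle.
#
# Recomputes the 20-feature vector for a variant by a completely different
# route than the package: the whole contig is re-oriented into transcript
# direction once, the full mutated sequence is rebuilt, windows are
# re-extracted from scratch, and the cryptic/motif scans compare the entire
# dinucleotide/k-mer space of both alleles rather than variant-centred
# windows.  No incremental logic is shared with the implementation.

oracle_rc <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

oracle_norm <- function(freq, seq_chars) {
  v <- log2(freq)
  raw <- 0
  for (i in seq_along(seq_chars))
    raw <- raw + v[i, seq_chars[i]]
  mn <- sum(apply(v, 1, min))
  mx <- sum(apply(v, 1, max))
  min(100, max(0, 100 * (raw - mn) / (mx - mn)))
}

# All features for one variant against one transcript; conservation/track
# handled by the caller.  Returns NULL if the variant is outside the gene
# span.
oracle_features <- function(variant, tx, genome, pssms, motif_sets,
                            cons_lookup = function(contig, pos) NA_real_) {
  contig <- as.character(genome$seq[[tx$contig]])
  L <- nchar(contig)
  # orient everything into transcription direction
  if (tx$strand == "+") {
    oseq <- contig
    opos <- variant$pos
    oalt <- variant$alt
    ex <- data.frame(start = pmin(tx$exons$start, tx$exons$end),
                     end = pmax(tx$exons$start, tx$exons$end))
    ex <- ex[order(ex$start), ]
  } else {
    oseq <- oracle_rc(contig)
    opos <- L - variant$pos + 1L
    oalt <- chartr("ACGT", "TGCA", variant$alt)
    ex <- data.frame(start = L - pmax(tx$exons$start, tx$exons$end) + 1L,
                     end = L - pmin(tx$exons$start, tx$exons$end) + 1L)
    ex <- ex[order(ex$start), ]
  }
  n_ex <- nrow(ex)
  span <- c(ex$start[1], ex$end[n_ex])
  if (opos < span[1] || opos > span[2]) return(NULL)
  alt_seq <- oseq
  substr(alt_seq, opos, opos) <- oalt

  # region and harboring/nearest exon
  in_ex <- which(opos >= ex$start & opos <= ex$end)
  if (length(in_ex)) {
    i <- in_ex[1]
    region <- "exonic"
  } else {
    region <- "intronic"
    i_up <- max(which(ex$end < opos))
    d_up <- opos - ex$end[i_up]
    d_dn <- ex$start[i_up + 1L] - opos
    i <- if (d_up <= d_dn) i_up else i_up + 1L
  }
  dist_acc <- if (i > 1L) opos - ex$start[i] else NA_real_
  dist_don <- if (i < n_ex) opos - ex$end[i] else NA_real_

  # splice-site windows of exon i (all-"+" logic on the oriented sequence)
  win <- function(s, from, to) {
    if (from < 1L || to > L) return(NA_character_)
    substr(s, from, to)
  }
  score23 <- function(s) {
    if (is.na(s)) return(0)
    oracle_norm(pssms$acceptor$freq, strsplit(s, "")[[1]])
  }
  score9 <- function(s) {
    if (is.na(s)) return(0)
    oracle_norm(pssms$donor$freq, strsplit(s, "")[[1]])
  }
  acc_ref <- acc_alt <- 0
  if (i > 1L) {
    acc_ref <- score23(win(oseq, ex$start[i] - 20L, ex$start[i] + 2L))
    acc_alt <- score23(win(alt_seq, ex$start[i] - 20L, ex$start[i] + 2L))
  }
  don_ref <- don_alt <- 0
  if (i < n_ex) {
    don_ref <- score9(win(oseq, ex$end[i] - 2L, ex$end[i] + 6L))
    don_alt <- score9(win(alt_seq, ex$end[i] - 2L, ex$end[i] + 6L))
  }

  # cryptic scan: compare the complete dinucleotide space of both alleles
  cry <- c(cryptic5_score = 0, cryptic3_score = 0,
           cryptic5_lost = 0, cryptic3_lost = 0)
  dinuc_at <- function(s, u) substr(s, u, u + 1L)
  for (u in seq_len(L - 1L)) {
    rd <- dinuc_at(oseq, u)
    ad <- dinuc_at(alt_seq, u)
    if (rd == ad) next                    # only variant frames can differ
    for (core in c("GT", "AG")) {
      gain <- ad == core && rd != core
      loss <- rd == core && ad != core
      if (!gain && !loss) next
      if (core == "GT") {
        w <- win(if (gain) alt_seq else oseq, u - 3L, u + 5L)
        sc <- score9(w)
        key <- if (gain) "cryptic5_score" else "cryptic5_lost"
      } else {
        w <- win(if (gain) alt_seq else oseq, u - 18L, u + 4L)
        sc <- score23(w)
        key <- if (gain) "cryptic3_score" else "cryptic3_lost"
      }
      if (is.na(w)) next
      cry[key] <- max(cry[key], sc)
    }
  }

  overall <- max(0, cry[["cryptic5_score"]] - don_ref,
                 cry[["cryptic3_score"]] - acc_ref)
  vss <- max(overall, -(acc_alt - acc_ref), -(don_alt - don_ref),
             cry[["cryptic5_lost"]], cry[["cryptic3_lost"]])

  # regulatory scan: offset-by-offset over the entire exon, both alleles
  ec <- ed <- sc_ <- sd_ <- 0
  if (region == "exonic") {
    rex <- substr(oseq, ex$start[i], ex$end[i])
    aex <- substr(alt_seq, ex$start[i], ex$end[i])
    for (ms in motif_sets) {
      k <- ms$k
      if (nchar(rex) < k) next
      for (o in seq_len(nchar(rex) - k + 1L)) {
        rk <- substr(rex, o, o + k - 1L)
        ak <- substr(aex, o, o + k - 1L)
        r_in <- rk %in% names(ms$kmers)
        a_in <- ak %in% names(ms$kmers)
        if (a_in && !r_in) {
          if (ms$role == "enhancer") ec <- ec + 1 else sc_ <- sc_ + 1
        }
        if (r_in && !a_in) {
          if (ms$role == "enhancer") ed <- ed + 1 else sd_ <- sd_ + 1
        }
      }
    }
  }

  g <- cons_lookup(variant$contig, variant$pos)
  dists <- c(dist_acc, dist_don)
  c(acc_score_ref = acc_ref, acc_score_alt = acc_alt,
    don_score_ref = don_ref, don_score_alt = don_alt,
    acc_delta = acc_alt - acc_ref, don_delta = don_alt - don_ref,
    cry,
    splice_site_overall = overall, variant_splice_score = vss,
    esr_created = ec, esr_disrupted = ed,
    silencer_created = sc_, silencer_disrupted = sd_,
    combined_esr_score = ec - ed - sc_ + sd_,
    negated_esr_score = -(ec + ed),
    gerp_rs = if (is.na(g)) 0 else g,
    dist_nearest_ss = if (all(is.na(dists))) 0
                      else min(abs(dists), na.rm = TRUE))
}
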