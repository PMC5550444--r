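# The 20-feature vector computed per variant-in-transcript.
#
# Feature blocks:
#   splice-site strength before/after the substitution (normalized 0-100),
#   cryptic splice-site creation/disruption (gated on an AG/GT core change),
#   interaction summaries (splice_site_overall, variant_splice_score),
#   exonic splicing enhancer/silencer k-mer gains and losses,
#   conservation at the position, distance to the nearest splice site.
# Missing components (window absent, N in window, no conservation value)
# are imputed as 0; conservation carries an explicit gerp_missing flag.

#' The 20-feature registry
#'
#' Deterministic order of the model's feature columns.
#'
#' @param gerpless Drop the conservation feature (19-feature registry)?
#' @return Character vector of feature names.
#' @export
feature_registry <- function(gerpless = FALSE) {
  reg <- c("acc_score_ref", "acc_score_alt", "don_score_ref", "don_score_alt",
           "acc_delta", "don_delta",
           "cryptic5_score", "cryptic3_score", "cryptic5_lost", "cryptic3_lost",
           "splice_site_overall", "variant_splice_score",
           "esr_created", "esr_disrupted",
           "silencer_created", "silencer_disrupted",
           "combined_esr_score", "negated_esr_score",
           "gerp_rs", "dist_nearest_ss")
  if (gerpless) setdiff(reg, "gerp_rs") else reg
}

score_or_zero <- function(pssm, seq) {
  if (is.na(seq)) return(0)
  s <- suppressWarnings(normalized_score(pssm, seq))
  if (is.na(s)) 0 else s
}

#' Splice-site strength before and after a variant
#'
#' Scores the acceptor and donor windows of the harboring (or nearest)
#' exon.  The post-substitution score is computed only when the variant
#' lies inside the corresponding window; otherwise the alt score equals
#' the ref score and the delta is 0.  Windows that do not exist (first
#' exon's acceptor, last exon's donor) score 0.
#'
#' @param context A `variant_context`.
#' @param genome A `genome`.
#' @param pssms List with `acceptor` and `donor` `pssm` objects.
#' @return Named numeric vector: acc_score_ref, acc_score_alt,
#'   don_score_ref, don_score_alt, acc_delta, don_delta.
#' @export
splice_site_delta <- function(context, genome, pssms) {
  w <- site_windows(context, genome)
  one <- function(win, pssm) {
    ref <- score_or_zero(pssm, win$ref)
    in_window <- !is.null(win$range) &&
      context$variant$pos >= win$range[1] && context$variant$pos <= win$range[2]
    alt <- if (in_window) score_or_zero(pssm, win$alt) else ref
    c(ref = ref, alt = alt, delta = alt - ref)
  }
  a <- one(w$acceptor, pssms$acceptor)
  d <- one(w$donor, pssms$donor)
  c(acc_score_ref = unname(a["ref"]), acc_score_alt = unname(a["alt"]),
    don_score_ref = unname(d["ref"]), don_score_alt = unname(d["alt"]),
    acc_delta = unname(a["delta"]), don_delta = unname(d["delta"]))
}

# Oriented local sequences around the variant (radius nt each side, clipped
# at contig ends), plus the variant's index within the oriented string.
oriented_local <- function(variant, tx, genome, radius = 25L) {
  len <- contig_length(genome, tx$contig)
  lo <- max(1L, variant$pos - radius)
  hi <- min(len, variant$pos + radius)
  fwd <- get_sequence(genome, tx$contig, lo, hi, "+")
  i <- variant$pos - lo + 1L
  stopifnot(substr(fwd, i, i) == variant$ref)
  alt_fwd <- fwd
  substr(alt_fwd, i, i) <- variant$alt
  if (tx$strand == "-") {
    rc <- function(s) as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    list(ref = rc(fwd), alt = rc(alt_fwd), center = nchar(fwd) - i + 1L)
  } else {
    list(ref = fwd, alt = alt_fwd, center = i)
  }
}

#' Cryptic splice-site creation and disruption scores
#'
#' The scan is gated on a canonical core change: for each of the two
#' dinucleotide frames overlapping the variant base (strand-oriented), a
#' `GT` present in the alt allele but not the ref is a candidate new donor
#' core, and an `AG` a candidate new acceptor core; the implied full window
#' (9-mer donor with the core at positions 4-5; 23-mer acceptor with the
#' core at positions 19-20) is scored on the alt sequence.  Cores present
#' in ref but absent in alt symmetrically populate the `lost` scores using
#' the ref sequence.  The maximum normalized score per class is kept; a
#' variant changing no core scores 0 everywhere.
#'
#' @param variant One-row data.frame/list with contig, pos, ref, alt.
#' @param context A `variant_context` for this variant.
#' @param genome A `genome`.
#' @param pssms List with `acceptor` and `donor` `pssm` objects.
#' @return Named numeric vector: cryptic5_score, cryptic3_score,
#'   cryptic5_lost, cryptic3_lost.
#' @export
cryptic_site_scan <- function(variant, context, genome, pssms) {
  loc <- oriented_local(variant, context$transcript, genome, radius = 25L)
  n <- nchar(loc$ref)
  out <- c(cryptic5_score = 0, cryptic3_score = 0,
           cryptic5_lost = 0, cryptic3_lost = 0)
  score_window <- function(seq_str, from, to, pssm) {
    if (from < 1L || to > n) return(NA_real_)   # truncated by contig edge
    s <- suppressWarnings(normalized_score(pssm, substr(seq_str, from, to)))
    s
  }
  for (u in c(loc$center - 1L, loc$center)) {
    if (u < 1L || u + 1L > n) next
    rd <- substr(loc$ref, u, u + 1L)
    ad <- substr(loc$alt, u, u + 1L)
    if (rd == ad) next
    cand <- list(
      list(core = "GT", gained = "cryptic5_score", lost = "cryptic5_lost",
           pssm = pssms$donor, from = u - 3L, to = u + 5L),
      list(core = "AG", gained = "cryptic3_score", lost = "cryptic3_lost",
           pssm = pssms$acceptor, from = u - 18L, to = u + 4L))
    for (cc in cand) {
      if (ad == cc$core && rd != cc$core) {
        s <- score_window(loc$alt, cc$from, cc$to, cc$pssm)
        if (!is.na(s)) out[cc$gained] <- max(out[cc$gained], s)
      }
      if (rd == cc$core && ad != cc$core) {
        s <- score_window(loc$ref, cc$from, cc$to, cc$pssm)
        if (!is.na(s)) out[cc$lost] <- max(out[cc$lost], s)
      }
    }
  }
  out
}

#' Splice interaction summaries
#'
#' `splice_site_overall` weighs a newly created cryptic site against the
#' strength of the existing site of the same class: a strong existing site
#' nullifies the cryptic gain, a weak one is highly affected.
#' `variant_splice_score` is the single worst-damage summary across all
#' splice features.
#'
#' @param splice Named vector from [splice_site_delta()].
#' @param cryptic Named vector from [cryptic_site_scan()].
#' @return Named numeric vector: splice_site_overall, variant_splice_score.
#' @export
interaction_scores <- function(splice, cryptic) {
  overall <- max(0,
                 cryptic[["cryptic5_score"]] - splice[["don_score_ref"]],
                 cryptic[["cryptic3_score"]] - splice[["acc_score_ref"]])
  vss <- max(overall,
             -splice[["acc_delta"]], -splice[["don_delta"]],
             cryptic[["cryptic5_lost"]], cryptic[["cryptic3_lost"]])
  c(splice_site_overall = overall, variant_splice_score = vss)
}

#' Enhancer/silencer motif gains and losses
#'
#' For each motif set of length `k`, the `2k-1`-nt windows centered on the
#' variant (truncated to exon bounds) are compared between the ref and alt
#' alleles: a set k-mer present in alt but not ref at the same offset is a
#' creation, the reverse a disruption.  Counts are summed over enhancer
#' sets and over silencer sets.  Intronic variants score all zeros.
#'
#' @param variant One-row data.frame/list.
#' @param context A `variant_context`.
#' @param genome A `genome`.
#' @param motif_sets List of `motif_set` objects.
#' @return Named numeric vector: esr_created, esr_disrupted,
#'   silencer_created, silencer_disrupted, combined_esr_score,
#'   negated_esr_score.
#' @export
esr_scan <- function(variant, context, genome, motif_sets) {
  zero <- c(esr_created = 0, esr_disrupted = 0,
            silencer_created = 0, silencer_disrupted = 0,
            combined_esr_score = 0, negated_esr_score = 0)
  if (context$region != "exonic" || !length(motif_sets)) return(zero)
  tx <- context$transcript
  ex <- tx$exons[context$exon_index, ]
  ref_exon <- get_sequence(genome, tx$contig, ex$start, ex$end, tx$strand)
  vi <- if (tx$strand == "+") variant$pos - ex$start + 1L
        else ex$end - variant$pos + 1L
  alt_exon <- ref_exon
  substr(alt_exon, vi, vi) <- variant$alt
  if (tx$strand == "-")
    substr(alt_exon, vi, vi) <- as.character(
      Biostrings::complement(Biostrings::DNAString(variant$alt)))
  ec <- ed <- sc <- sd <- 0
  for (ms in motif_sets) {
    k <- ms$k
    from <- max(1L, vi - k + 1L)
    to <- min(nchar(ref_exon) - k + 1L, vi)
    if (from > to) next
    for (o in from:to) {
      rk <- substr(ref_exon, o, o + k - 1L)
      ak <- substr(alt_exon, o, o + k - 1L)
      r_in <- rk %in% names(ms$kmers)
      a_in <- ak %in% names(ms$kmers)
      if (a_in && !r_in) {
        if (ms$role == "enhancer") ec <- ec + 1 else sc <- sc + 1
      }
      if (r_in && !a_in) {
        if (ms$role == "enhancer") ed <- ed + 1 else sd <- sd + 1
      }
    }
  }
  c(esr_created = ec, esr_disrupted = ed,
    silencer_created = sc, silencer_disrupted = sd,
    combined_esr_score = ec - ed - sc + sd,
    negated_esr_score = -(ec + ed))
}

#' CpG dinucleotide gain/loss classification
#'
#' Classifies whether the substitution creates or destroys a CpG across the
#' two overlapping dinucleotide frames on the forward strand.  Computed and
#' exported for completeness but excluded from the default 20-feature
#' registry.
#'
#' @param variant One-row data.frame/list.
#' @param genome A `genome`.
#' @return One of `"creates_cpg"`, `"destroys_cpg"`, `"none"`.
#' @export
cpg_feature <- function(variant, genome) {
  len <- contig_length(genome, variant$contig)
  lo <- max(1L, variant$pos - 1L)
  hi <- min(len, variant$pos + 1L)
  ref <- get_sequence(genome, variant$contig, lo, hi, "+")
  alt <- ref
  i <- variant$pos - lo + 1L
  substr(alt, i, i) <- variant$alt
  count_cg <- function(s) {
    n <- 0L
    for (j in seq_len(nchar(s) - 1L))
      if (substr(s, j, j + 1L) == "CG") n <- n + 1L
    n
  }
  d <- count_cg(alt) - count_cg(ref)
  if (d > 0L) "creates_cpg" else if (d < 0L) "destroys_cpg" else "none"
}

#' Assemble the full feature matrix for a variant
#'
#' One row per transcript context, with key columns (contig, pos, ref, alt,
#' transcript, region) followed by the 20 registry features in
#' [feature_registry()] order, the `gerp_missing` flag and the CpG class.
#'
#' @param variant One-row data.frame/list with contig, pos, ref, alt.
#' @param contexts List of `variant_context` from [locate_variant()], or
#'   `NULL` to locate against `transcripts`.
#' @param genome A `genome`.
#' @param pssms List with `acceptor` and `donor` `pssm` objects.
#' @param motif_sets List of `motif_set` objects (may be empty).
#' @param conservation A `conservation_track`, or `NULL` (all scores
#'   missing, imputed 0).
#' @return A data.frame with one row per context (zero rows when the
#'   variant lies outside all gene spans).
#' @export
assemble_features <- function(variant, contexts, genome, pssms,
                              motif_sets = list(), conservation = NULL) {
  rows <- lapply(contexts, function(ctx) {
    splice <- splice_site_delta(ctx, genome, pssms)
    cryptic <- cryptic_site_scan(variant, ctx, genome, pssms)
    inter <- interaction_scores(splice, cryptic)
    esr <- esr_scan(variant, ctx, genome, motif_sets)
    g <- if (is.null(conservation)) NA_real_
         else conservation_at(conservation, variant$contig, variant$pos)
    dists <- c(ctx$dist_to_acceptor, ctx$dist_to_donor)
    dnn <- if (all(is.na(dists))) 0 else min(abs(dists), na.rm = TRUE)
    vals <- c(splice, cryptic, inter, esr,
              gerp_rs = if (is.na(g)) 0 else g,
              dist_nearest_ss = dnn)
    cbind(data.frame(contig = variant$contig, pos = variant$pos,
                     ref = variant$ref, alt = variant$alt,
                     transcript = ctx$transcript$id, region = ctx$region,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(vals[c(names(splice), names(cryptic),
                                       names(inter), names(esr),
                                       "gerp_rs", "dist_nearest_ss")])),
          data.frame(gerp_missing = as.integer(is.na(g)),
                     cpg = cpg_feature(variant, genome)))
  })
  if (!length(rows)) {
    empty <- data.frame(contig = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        transcript = character(0), region = character(0))
    for (f in feature_registry()) empty[[f]] <- numeric(0)
    empty$gerp_missing <- integer(0)
    empty$cpg <- character(0)
    return(empty)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Feature matrix for a set of variants
#'
#' Convenience wrapper running [locate_variant()] and
#' [assemble_features()] over a variant table.
#'
#' @param variants Data.frame with contig, pos, ref, alt.
#' @param transcripts Named list of `transcript` objects.
#' @inheritParams assemble_features
#' @return Row-bound feature data.frame for all variant-transcript pairs.
#' @export
featurize_variants <- function(variants, transcripts, genome, pssms,
                               motif_sets = list(), conservation = NULL) {
  out <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, , drop = FALSE]
    ctxs <- locate_variant(v, transcripts)
    assemble_features(v, ctxs, genome, pssms, motif_sets, conservation)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
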