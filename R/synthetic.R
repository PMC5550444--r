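# Synthetic mini-genome generator.
#
# Produces self-contained fixtures: multi-exon genes with G[T/C]..AG introns
# whose donor/acceptor strengths are tuned to target normalized scores,
# engineered variant classes (donor/acceptor disruption, cryptic-site
# creation, enhancer/silencer motif hits, neutral), a conservation track
# elevated at functional positions, and toy splicing-regulatory motif sets.
# Everything is deterministic per seed.

DONOR_CONSENSUS <- "AAGGTAAGT"        # 3 exonic + GT + 4 intronic
DONOR_CONSENSUS_GC <- "AAGGCAAGT"
ACCEPTOR_CONSENSUS <- paste0("TTTTTTTTTTTTTTCTCC", "AG", "GTC")  # K = 23
PRE_CRYPTIC <- "AAGGAAAGT"            # pos 5 A>T completes a consensus donor

# Toy enhancer/silencer hexamer sets.  Deliberately synthetic stand-ins for
# SR-protein binding catalogs: G-free so that motif hits never create or
# destroy an AG/GT splice core, keeping feature blocks orthogonal.
toy_motif_sets <- function() {
  sets <- list(
    SRSF1 = c("TCCTCA", "CATCCT", "ACTCCA", "TCACCT"),
    SRSF2 = c("CTCCAT", "TACCTC", "CCATCT", "ATCCTA"),
    SRSF5 = c("CCTACT", "TCTCAC", "ACCTTC", "CACTTC"),
    SRSF6 = c("CTTCCA", "TTCACC", "CCTCTA", "ATCTCC"),
    silencer = c("TTCCTT", "CTTTCA", "TCATTC", "CATTTC"))
  lapply(names(sets), function(nm) {
    structure(list(name = nm,
                   role = if (nm == "silencer") "silencer" else "enhancer",
                   k = 6L,
                   kmers = stats::setNames(rep(1, length(sets[[nm]])),
                                           sets[[nm]])),
              class = "motif_set")
  })
}

#' Simulation configuration
#'
#' Defaults define the study conditions used throughout the test-suite:
#' 30 four-exon genes (strand chosen at random), exon lengths 90-150 nt,
#' intron lengths 60-120 nt, donor strength levels 95/85/72 and acceptor
#' levels 90/75/60 normalized units (tolerance +-5 after PSSM rebuild; the
#' invariant GT core keeps the feasible donor population mean high, hence
#' the higher donor levels), 500 variants mixed over the five engineered
#' classes, conservation elevated by 3 at splice windows with 20% of sites
#' left unelevated.
#'
#' @param ... Overrides for any default field.
#' @return A `sim_config` list.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_genes = 30L, exons_per_gene = 4L,
    exon_len = c(90L, 150L), intron_len = c(60L, 120L),
    donor_strengths = c(95, 85, 72), acceptor_strengths = c(90, 75, 60),
    gc_donor_frac = 0.05, minus_strand_frac = 0.5,
    n_variants = 500L,
    class_mix = c(donor_disrupt = 0.15, acceptor_disrupt = 0.15,
                  cryptic_create = 0.15, esr_hit = 0.15, neutral = 0.40),
    donor_min_effect = 5, acceptor_min_effect = 3, cryptic_min_score = 84,
    cons_elevation = 3, cons_sd = 1, cons_unelevated_frac = 0.2,
    flank = 50L, strength_tol = 5, seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  stopifnot(abs(sum(cfg$class_mix) - 1) < 1e-9,
            cfg$intron_len[1] >= 26L, cfg$exon_len[1] >= 60L,
            cfg$exons_per_gene >= 2L)
  structure(cfg, class = "sim_config")
}

# ---- gene assembly in transcript orientation --------------------------------

rand_bases <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

str_assign <- function(s, at, value) {
  substr(s, at, at + nchar(value) - 1L) <- value
  s
}

rc_string <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Materialize contigs from transcript-oriented gene strings.
materialize_genome <- function(genes) {
  seqs <- vapply(genes, function(g) {
    body <- if (g$strand == "+") g$string else rc_string(g$string)
    paste0(g$flank5, body, g$flank3)
  }, "")
  structure(list(seq = Biostrings::DNAStringSet(seqs)), class = "genome")
}

# Transcript-oriented coordinate t (1..L in gene body) -> genomic position.
tx_to_genomic <- function(g, t) {
  if (g$strand == "+") nchar(g$flank5) + t
  else nchar(g$flank5) + g$L - t + 1L
}

build_gene <- function(cfg, name, strength_cycle) {
  n_ex <- cfg$exons_per_gene
  ex_len <- sample(seq(cfg$exon_len[1], cfg$exon_len[2]), n_ex, replace = TRUE)
  in_len <- sample(seq(cfg$intron_len[1], cfg$intron_len[2]), n_ex - 1L,
                   replace = TRUE)
  strand <- if (stats::runif(1) < cfg$minus_strand_frac) "-" else "+"
  L <- sum(ex_len) + sum(in_len)
  s <- rand_bases(L)
  # transcript-oriented exon bounds
  starts <- cumsum(c(1L, utils::head(ex_len + c(in_len, 0L), -1L)))
  ends <- starts + ex_len - 1L
  sites <- list()
  for (j in seq_len(n_ex - 1L)) {
    gc_core <- stats::runif(1) < cfg$gc_donor_frac
    dcons <- if (gc_core) DONOR_CONSENSUS_GC else DONOR_CONSENSUS
    dtar <- strength_cycle$donor[(j - 1L) %% length(strength_cycle$donor) + 1L]
    if (gc_core) dtar <- min(dtar, 82)
    atar <- strength_cycle$acceptor[(j - 1L) %%
                                      length(strength_cycle$acceptor) + 1L]
    s <- str_assign(s, ends[j] - 2L, dcons)   # placeholder; windows are
    s <- str_assign(s, starts[j + 1L] - 20L,  # re-designed jointly later
                    ACCEPTOR_CONSENSUS)
    sites[[length(sites) + 1L]] <-
      list(type = "donor", win_start = ends[j] - 2L, K = DONOR_K,
           core_off = 4:5, target = dtar, exon = j)
    sites[[length(sites) + 1L]] <-
      list(type = "acceptor", win_start = starts[j + 1L] - 20L,
           K = ACCEPTOR_K, core_off = 19:20, target = atar, exon = j + 1L)
  }
  # plant pre-cryptic donors in internal exons (three slots per exon)
  for (j in seq_len(n_ex)[-c(1L, n_ex)]) {
    interior <- (starts[j] + 10L):(ends[j] - 10L - nchar(PRE_CRYPTIC))
    slots <- round(seq(interior[1], interior[length(interior)], length.out = 3))
    for (at in slots) s <- str_assign(s, as.integer(at), PRE_CRYPTIC)
  }
  # plant exact and near-miss regulatory hexamers in terminal exons
  motifs <- toy_motif_sets()
  all_kmers <- unlist(lapply(motifs, function(m) names(m$kmers)))
  for (j in c(1L, n_ex)) {
    interior <- (starts[j] + 6L):(ends[j] - 6L - 10L)
    slots <- round(seq(interior[1], interior[length(interior)], length.out = 4))
    for (si in seq_along(slots)) {
      km <- sample(all_kmers, 1L)
      if (si %% 2L == 0L) {   # near-miss: one base off, completed by a variant
        d <- sample(2:5, 1L)
        repl <- sample(setdiff(c("A", "C", "T"), substr(km, d, d)), 1L)
        substr(km, d, d) <- repl
      }
      s <- str_assign(s, as.integer(slots[si]), paste0("CC", km, "CC"))
    }
  }
  list(name = name, strand = strand, L = L, string = s,
       flank5 = rand_bases(cfg$flank), flank3 = rand_bases(cfg$flank),
       ex_starts = starts, ex_ends = ends, sites = sites)
}

genes_to_transcripts <- function(genes) {
  out <- lapply(genes, function(g) {
    gs <- vapply(g$ex_starts, function(t) tx_to_genomic(g, t), 0L)
    ge <- vapply(g$ex_ends, function(t) tx_to_genomic(g, t), 0L)
    structure(list(id = paste0(g$name, ".t1"), gene_id = g$name,
                   contig = g$name, strand = g$strand,
                   exons = data.frame(start = pmin(gs, ge),
                                      end = pmax(gs, ge))),
              class = "transcript")
  })
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

# Largest-remainder rounding of n * props to integers summing to n.
int_counts <- function(props, n) {
  raw <- props * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1L
  }
  as.integer(base)
}

# Design the site-window population for one splice-site class.
#
# The per-position base-count matrix is fixed first (a consensus-weighted
# profile whose weight rho is calibrated so the implied mean normalized
# score matches the mean of the site targets); the PSSM the annotation will
# induce is therefore known in advance.  Bases are then assigned to sites
# (best bases to the strongest targets) and refined by count-preserving
# swaps between sites, which leave the matrix -- and hence every score --
# exact and stable.
design_windows <- function(targets, cores, consensus, core_off, K,
                           tol, pseudocount = 1) {
  n <- length(targets)
  cons <- strsplit(consensus, "")[[1]]
  free <- setdiff(seq_len(K), core_off)
  core_chars <- do.call(rbind, strsplit(cores, ""))  # n x length(core_off)
  second <- NULL   # per-position "second" base; redrawn per design round
  counts_for <- function(rho) {
    m <- matrix(0L, K, 4, dimnames = list(NULL, BASES))
    for (ci in seq_along(core_off)) {
      tab <- table(factor(core_chars[, ci], levels = BASES))
      m[core_off[ci], ] <- as.integer(tab)
    }
    for (fi in seq_along(free)) {
      p <- free[fi]
      props <- stats::setNames(numeric(4), BASES)
      props[cons[p]] <- rho
      props[second[[fi]]] <- (1 - rho) * c(0.6, 0.2, 0.2)
      m[p, ] <- int_counts(props[BASES], n)
    }
    m
  }
  mean_norm <- function(m) {
    p <- new_pssm("design", m, pseudocount)
    raw <- sum(m / n * log2(p$freq))
    100 * (raw - p$min_raw) / (p$max_raw - p$min_raw)
  }
  target_mean <- mean(targets)
  m <- NULL; value <- NULL; offset <- NULL
  draw_design <- function() {
    # redraw the off-consensus structure, then calibrate rho: the
    # population mean score is fixed by the count matrix, so pick the
    # consensus weight whose implied mean best matches the mean target
    # (grid search; the relationship is not monotone at low rho)
    second <<- lapply(free, function(p)
      sample(setdiff(BASES, cons[p])))   # weight order per position
    grid <- seq(0.4, 0.96, by = 0.005)
    gaps <- vapply(grid, function(r) abs(mean_norm(counts_for(r)) -
                                           target_mean), 0)
    m <<- counts_for(grid[which.min(gaps)])
    pssm <- new_pssm("design", m, pseudocount)
    value <<- 100 * log2(pssm$freq) / (pssm$max_raw - pssm$min_raw)  # K x 4
    offset <<- 100 * (-pssm$min_raw) / (pssm$max_raw - pssm$min_raw)
  }
  attempt <- function() {
    # initial assignment: strongest targets take the best bases, with a
    # dash of noise so restarts explore different local optima
    ord <- order(targets + stats::runif(n, 0, 1e-3), decreasing = TRUE)
    assign <- matrix("", n, K)
    for (ci in seq_along(core_off)) assign[, core_off[ci]] <- core_chars[, ci]
    for (p in free) {
      pool <- rep(BASES, m[p, ])
      pool <- pool[order(value[p, match(pool, BASES)] +
                           stats::runif(length(pool), 0, 1e-6),
                         decreasing = TRUE)]
      assign[ord, p] <- pool
    }
    scores <- vapply(seq_len(n), function(s)
      sum(value[cbind(seq_len(K), match(assign[s, ], BASES))]) + offset, 0)
    # count-preserving swap refinement, hill-climbing on the sum of
    # squared gaps; two-position swaps with the same partner compose
    # adjustments finer than any single base exchange
    pair_idx <- if (length(free) >= 2L) utils::combn(free, 2L) else NULL
    for (step in seq_len(6000L)) {
      gaps <- abs(scores - targets)
      worst <- order(gaps, decreasing = TRUE)
      if (gaps[worst[1]] <= tol * 0.6) break
      moved <- FALSE
      for (s in worst[seq_len(min(5L, n))]) {
        if (gaps[s] <= tol * 0.6) next
        vrow <- function(p) value[p, match(assign[, p], BASES)]
        best_gain <- 1e-9; best_move <- NULL
        consider <- function(d, ps) {
          # d: per-partner score change for s (vector over sites)
          ssq_old <- gaps[s]^2 + gaps^2
          ssq_new <- (scores[s] + d - targets[s])^2 +
            (scores - d - targets)^2
          gain <- ssq_old - ssq_new
          gain[s] <- -Inf
          j <- which.max(gain)
          if (gain[j] > best_gain) {
            best_gain <<- gain[j]
            best_move <<- list(ps = ps, j = j, d = d[j])
          }
        }
        for (p in free) consider(vrow(p) - value[p, match(assign[s, p],
                                                          BASES)], p)
        if (!is.null(pair_idx)) {
          for (ci in seq_len(ncol(pair_idx))) {
            p1 <- pair_idx[1, ci]; p2 <- pair_idx[2, ci]
            d <- (vrow(p1) - value[p1, match(assign[s, p1], BASES)]) +
              (vrow(p2) - value[p2, match(assign[s, p2], BASES)])
            consider(d, c(p1, p2))
          }
        }
        if (!is.null(best_move)) {
          j <- best_move$j
          for (p in best_move$ps) {
            tmp <- assign[s, p]
            assign[s, p] <- assign[j, p]
            assign[j, p] <- tmp
          }
          scores[s] <- scores[s] + best_move$d
          scores[j] <- scores[j] - best_move$d
          moved <- TRUE
          break
        }
      }
      if (!moved) break
    }
    list(assign = assign, worst = max(abs(scores - targets)))
  }
  best <- list(worst = Inf)
  for (round in seq_len(4L)) {
    if (best$worst <= tol) break
    draw_design()
    for (restart in seq_len(8L)) {
      cand <- attempt()
      if (cand$worst < best$worst) best <- cand
      if (best$worst <= tol) break
    }
  }
  if (best$worst > tol)
    stop("infeasible splice-site strength targets (worst gap ",
         round(best$worst, 1), ")")
  apply(best$assign, 1, paste, collapse = "")
}

#' Generate a synthetic mini-genome and annotation
#'
#' Builds `n_genes` multi-exon genes (one per contig, strand at random),
#' all introns GT..AG with a configurable GC..AG fraction, and iteratively
#' tunes every donor/acceptor window so that, after rebuilding the PSSMs
#' from the emitted annotation, each site scores within
#' `cfg$strength_tol` normalized units of its target strength level.
#' Internal exons carry planted pre-cryptic donor nonamers (one
#' substitution away from consensus); terminal exons carry planted exact
#' and near-miss regulatory hexamers.
#'
#' @param cfg A [sim_config()].
#' @return List with `genome`, `transcripts`, `pssms` (rebuilt from the
#'   final sequence) and `sites` (data.frame of per-site class, target and
#'   achieved normalized score).
#' @export
generate_genome <- function(cfg) {
  set.seed(as.integer(cfg$seed))
  cycle <- list(donor = cfg$donor_strengths, acceptor = cfg$acceptor_strengths)
  genes <- lapply(seq_len(cfg$n_genes), function(i)
    build_gene(cfg, sprintf("gene%02d", i), cycle))
  names(genes) <- vapply(genes, `[[`, "", "name")
  transcripts <- genes_to_transcripts(genes)
  # Design all site windows of each class jointly against a fixed count
  # matrix, then write them into the gene bodies; rebuilding the PSSMs from
  # the emitted annotation reproduces the designed matrix, so every site
  # scores its designed strength.
  refs <- do.call(rbind, lapply(seq_along(genes), function(gi)
    data.frame(gi = gi, si = seq_along(genes[[gi]]$sites))))
  get_site <- function(k) genes[[refs$gi[k]]]$sites[[refs$si[k]]]
  wins <- vapply(seq_len(nrow(refs)), function(k) {
    st <- get_site(k)
    substr(genes[[refs$gi[k]]]$string, st$win_start,
           st$win_start + st$K - 1L)
  }, "")
  types <- vapply(seq_len(nrow(refs)), function(k) get_site(k)$type, "")
  for (type in c("donor", "acceptor")) {
    ks <- which(types == type)
    st1 <- get_site(ks[1])
    targets <- vapply(ks, function(k) get_site(k)$target, 0)
    cores <- vapply(ks, function(k)
      paste(substring(wins[k], st1$core_off, st1$core_off), collapse = ""),
      "")
    wins[ks] <- design_windows(
      targets, cores,
      consensus = if (type == "donor") DONOR_CONSENSUS else ACCEPTOR_CONSENSUS,
      core_off = st1$core_off, K = st1$K, tol = cfg$strength_tol - 0.5)
  }
  for (k in seq_len(nrow(refs))) {
    st <- get_site(k)
    gi <- refs$gi[k]
    genes[[gi]]$string <- str_assign(genes[[gi]]$string, st$win_start,
                                     wins[k])
  }
  genome <- materialize_genome(genes)
  pssms <- build_pssms(transcripts, genome)
  sites <- do.call(rbind, lapply(genes, function(g) {
    do.call(rbind, lapply(g$sites, function(st) {
      win <- substr(g$string, st$win_start, st$win_start + st$K - 1L)
      pssm <- if (st$type == "donor") pssms$donor else pssms$acceptor
      data.frame(gene = g$name, type = st$type, exon = st$exon,
                 target = st$target,
                 achieved = normalized_score(pssm, win))
    }))
  }))
  rownames(sites) <- NULL
  bad <- abs(sites$achieved - sites$target) > cfg$strength_tol
  if (any(bad))
    stop(sum(bad), " splice site(s) missed their strength target after ",
         "bounded search")
  list(genome = genome, transcripts = transcripts, pssms = pssms,
       sites = sites, genes = genes)
}

# ---- engineered variants ----------------------------------------------------

# Feature-block profile of a candidate variant (no conservation).
variant_blocks <- function(v, transcripts, genome, pssms, motif_sets) {
  ctxs <- locate_variant(v, transcripts)
  if (!length(ctxs)) return(NULL)
  fv <- assemble_features(v, ctxs, genome, pssms, motif_sets, NULL)
  list(acc_delta = min(fv$acc_delta), don_delta = min(fv$don_delta),
       cryptic5 = max(fv$cryptic5_score), cryptic3 = max(fv$cryptic3_score),
       cryptic_lost = max(fv$cryptic5_lost, fv$cryptic3_lost),
       esr_n = max(fv$esr_created + fv$esr_disrupted +
                     fv$silencer_created + fv$silencer_disrupted))
}

class_accepts <- function(class, b, cfg) {
  zero_cryptic <- b$cryptic5 == 0 && b$cryptic3 == 0 && b$cryptic_lost == 0
  zero_splice <- b$acc_delta == 0 && b$don_delta == 0
  switch(class,
    donor_disrupt = b$don_delta <= -cfg$donor_min_effect &&
      b$acc_delta == 0 && zero_cryptic && b$esr_n == 0,
    acceptor_disrupt = b$acc_delta <= -cfg$acceptor_min_effect &&
      b$don_delta == 0 && zero_cryptic && b$esr_n == 0,
    cryptic_create = b$cryptic5 >= cfg$cryptic_min_score && zero_splice &&
      b$cryptic3 == 0 && b$cryptic_lost == 0 && b$esr_n == 0,
    esr_hit = b$esr_n >= 1 && zero_splice && zero_cryptic,
    neutral = zero_splice && zero_cryptic && b$esr_n == 0)
}

class_magnitude <- function(class, b) {
  switch(class,
    donor_disrupt = -b$don_delta,
    acceptor_disrupt = -b$acc_delta,
    cryptic_create = b$cryptic5,
    esr_hit = b$esr_n,
    neutral = 0)
}

# Candidate (pos, alt) pools per class, genomic coordinates.
candidate_pool <- function(class, transcripts, genome, motif_sets) {
  rows <- list()
  add <- function(contig, pos, alt) {
    ref <- get_sequence(genome, contig, pos, pos)
    if (ref != alt)
      rows[[length(rows) + 1L]] <<- data.frame(
        contig = contig, pos = pos, ref = ref, alt = alt,
        stringsAsFactors = FALSE)
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (tx in transcripts) {
    n_ex <- nrow(tx$exons)
    if (class %in% c("donor_disrupt", "acceptor_disrupt")) {
      for (j in seq_len(n_ex - 1L)) {
        rng <- if (class == "donor_disrupt") donor_window_range(tx, j)
               else acceptor_window_range(tx, j + 1L)
        intr <- tx_introns(tx)[j, ]
        core <- if (class == "donor_disrupt") {
          if (tx$strand == "+") c(intr$start, intr$start + 1L)
          else c(intr$end - 1L, intr$end)
        } else {
          if (tx$strand == "+") c(intr$end - 1L, intr$end)
          else c(intr$start, intr$start + 1L)
        }
        for (pos in setdiff(seq(rng[1], rng[2]), core)) {
          ref <- get_sequence(genome, tx$contig, pos, pos)
          for (alt in setdiff(BASES, ref)) add(tx$contig, pos, alt)
        }
      }
    } else if (class == "cryptic_create") {
      for (j in seq_len(n_ex)) {
        ex <- tx$exons[j, ]
        es <- get_sequence(genome, tx$contig, ex$start, ex$end, tx$strand)
        hits <- gregexpr(PRE_CRYPTIC, es, fixed = TRUE)[[1]]
        for (h in hits[hits > 0]) {
          t_in_exon <- h + 4L          # the A of the GA proto-core
          pos <- if (tx$strand == "+") ex$start + t_in_exon - 1L
                 else ex$end - t_in_exon + 1L
          alt <- if (tx$strand == "+") "T" else comp[["T"]]
          add(tx$contig, pos, alt)
        }
      }
    } else if (class == "esr_hit") {
      kmers <- unlist(lapply(motif_sets, function(m) names(m$kmers)))
      kmat <- vapply(kmers, function(k) strsplit(k, "")[[1]],
                     character(6))
      for (j in seq_len(n_ex)) {
        ex <- tx$exons[j, ]
        es <- get_sequence(genome, tx$contig, ex$start, ex$end, tx$strand)
        chars <- strsplit(es, "")[[1]]
        n_off <- length(chars) - 5L
        if (n_off < 1L) next
        for (o in seq_len(n_off)) {
          hex <- chars[o:(o + 5L)]
          dists <- colSums(kmat != hex)
          t_of <- function(d) o + d - 1L
          to_genomic <- function(t) if (tx$strand == "+") ex$start + t - 1L
                                    else ex$end - t + 1L
          if (any(dists == 0L)) {       # disruption: break the hexamer
            for (d in c(3L, 4L)) {
              for (b in setdiff(c("A", "C", "T"), hex[d])) {
                ob <- if (tx$strand == "+") b else comp[[b]]
                add(tx$contig, to_genomic(t_of(d)), ob)
              }
            }
          } else if (any(dists == 1L)) {  # creation: complete the hexamer
            ki <- which(dists == 1L)[1]
            d <- which(kmat[, ki] != hex)
            ob <- if (tx$strand == "+") kmat[d, ki] else comp[[kmat[d, ki]]]
            add(tx$contig, to_genomic(t_of(d)), ob)
          }
        }
      }
    } else if (class == "neutral") {
      span <- range(c(tx$exons$start, tx$exons$end))
      pool <- seq(span[1], span[2])
      pool <- sample(pool, min(length(pool), 60L))
      for (pos in pool) {
        ref <- get_sequence(genome, tx$contig, pos, pos)
        add(tx$contig, pos, sample(setdiff(BASES, ref), 1L))
      }
    }
  }
  if (!length(rows)) return(NULL)
  unique(do.call(rbind, rows))
}

#' Generate engineered, labeled variants for a synthetic genome
#'
#' Draws `cfg$n_variants` SNVs according to `cfg$class_mix`.  Every
#' candidate is verified against the feature machinery before acceptance so
#' each class activates exactly its designated feature block: donor/acceptor
#' disruptors lower the corresponding site score by at least
#' `cfg$donor_min_effect` / `cfg$acceptor_min_effect` units (the acceptor
#' minimum is lower because a single base carries only a few normalized
#' units of a 23-position motif) and touch nothing else; cryptic creators
#' complete a GT core scoring at least `cfg$cryptic_min_score` (strong);
#' regulatory hits change enhancer/silencer k-mer counts only; neutral
#' variants change no block.  Pathogenic label = class != neutral.
#'
#' @param cfg A [sim_config()].
#' @param genome,transcripts From [generate_genome()].
#' @param pssms PSSMs for the genome (rebuilt if `NULL`).
#' @param motif_sets Motif sets (default: the toy sets).
#' @return List with `variants` (contig/pos/ref/alt data.frame, sorted),
#'   `truth` (id, class, magnitude, pathogenic) and `manifest` (id,
#'   expected nonzero feature block).
#' @export
generate_variants <- function(cfg, genome, transcripts, pssms = NULL,
                              motif_sets = toy_motif_sets()) {
  if (is.null(pssms)) pssms <- build_pssms(transcripts, genome)
  set.seed(as.integer(cfg$seed) + 101L)
  counts <- round(cfg$class_mix * cfg$n_variants)
  counts[length(counts)] <- cfg$n_variants - sum(counts[-length(counts)])
  taken <- character(0)
  out <- list()
  blocks <- c(donor_disrupt = "splice_donor", acceptor_disrupt =
                "splice_acceptor", cryptic_create = "cryptic",
              esr_hit = "esr", neutral = "none")
  for (class in names(counts)) {
    need <- counts[[class]]
    if (need == 0L) next
    pool <- candidate_pool(class, transcripts, genome, motif_sets)
    if (is.null(pool)) stop("no candidates for class ", class)
    pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
    got <- 0L
    for (i in seq_len(nrow(pool))) {
      if (got >= need) break
      v <- pool[i, , drop = FALSE]
      key <- paste0(v$contig, ":", v$pos)
      if (key %in% taken) next
      b <- variant_blocks(v, transcripts, genome, pssms, motif_sets)
      if (is.null(b) || !class_accepts(class, b, cfg)) next
      taken <- c(taken, key)
      got <- got + 1L
      out[[length(out) + 1L]] <- cbind(
        v, data.frame(class = class,
                      magnitude = class_magnitude(class, b),
                      block = blocks[[class]], stringsAsFactors = FALSE))
    }
    if (got < need)
      stop(sprintf("class %s: only %d of %d candidates verified", class,
                   got, need))
  }
  all <- do.call(rbind, out)
  all <- all[order(all$contig, all$pos), ]
  rownames(all) <- NULL
  id <- paste(all$contig, all$pos, all$ref, all$alt, sep = "-")
  list(variants = all[, c("contig", "pos", "ref", "alt")],
       truth = data.frame(id = id, class = all$class,
                          magnitude = all$magnitude,
                          pathogenic = as.integer(all$class != "neutral"),
                          stringsAsFactors = FALSE),
       manifest = data.frame(id = id, block = all$block,
                             stringsAsFactors = FALSE))
}

#' Generate a conservation track elevated at functional positions
#'
#' Baseline scores are Normal(0, `cons_sd`) over every gene-span position;
#' positions inside splice-site windows get a `cons_elevation` mean shift,
#' except a `cons_unelevated_frac` fraction of sites drawn at random and
#' left at baseline (so some truly functional sites look unconserved).
#'
#' @param cfg A [sim_config()].
#' @param transcripts Transcript list.
#' @return Data.frame with columns chrom, pos, score.
#' @export
generate_conservation <- function(cfg, transcripts) {
  set.seed(as.integer(cfg$seed) + 202L)
  out <- lapply(transcripts, function(tx) {
    span <- range(c(tx$exons$start, tx$exons$end))
    pos <- seq(span[1], span[2])
    score <- stats::rnorm(length(pos), 0, cfg$cons_sd)
    for (j in seq_len(nrow(tx$exons))) {
      for (rng in list(acceptor_window_range(tx, j),
                       donor_window_range(tx, j))) {
        if (is.null(rng)) next
        if (stats::runif(1) < cfg$cons_unelevated_frac) next
        sel <- pos >= rng[1] & pos <= rng[2]
        score[sel] <- score[sel] + cfg$cons_elevation
      }
    }
    data.frame(chrom = tx$contig, pos = pos, score = score,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write motif sets as plain-text files
#'
#' One two-column (k-mer, weight) file per set, named
#' `motifs_synthetic_<name>.txt` to flag them as synthetic stand-ins.
#'
#' @param motif_sets List of `motif_set` objects.
#' @param dir Output directory.
#' @return Named character vector of file paths.
#' @export
write_motif_sets <- function(motif_sets, dir) {
  vapply(motif_sets, function(ms) {
    path <- file.path(dir, sprintf("motifs_synthetic_%s.txt", ms$name))
    writeLines(sprintf("%s\t%g", names(ms$kmers), ms$kmers), path)
    path
  }, "")
}

#' Write variants as a minimal VCF v4.2 file
#'
#' @param variants Data.frame with contig, pos, ref, alt.
#' @param genome The matching `genome` (for contig header lines).
#' @param path Output path.
#' @param seed Seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, genome, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  if (!is.na(seed)) writeLines(sprintf("##trapscore_seed=%s", seed), con)
  for (nm in names(genome$seq))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", nm,
                       length(genome$seq[[nm]])), con)
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", variants$contig,
                     variants$pos, variants$ref, variants$alt), con)
  invisible(path)
}

#' Generate the complete end-to-end fixture bundle
#'
#' One call produces every file the pipeline needs: FASTA genome, GTF
#' annotation, VCF variants, conservation TSV, motif files, a truth table
#' and a per-variant manifest of expected nonzero feature blocks.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return List with all in-memory objects plus a `paths` vector.
#' @export
end_to_end_fixture <- function(cfg = sim_config(), dir = tempfile("fixture")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gg <- generate_genome(cfg)
  vv <- generate_variants(cfg, gg$genome, gg$transcripts, gg$pssms)
  cons <- generate_conservation(cfg, gg$transcripts)
  paths <- c(
    fasta = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    vcf = file.path(dir, "variants.vcf"),
    conservation = file.path(dir, "conservation.tsv"),
    truth = file.path(dir, "truth.tsv"),
    manifest = file.path(dir, "manifest.tsv"))
  Biostrings::writeXStringSet(gg$genome$seq, paths[["fasta"]])
  write_annotation(gg$transcripts, paths[["gtf"]])
  write_vcf(vv$variants, gg$genome, paths[["vcf"]], seed = cfg$seed)
  utils::write.table(cons, paths[["conservation"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(vv$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(vv$manifest, paths[["manifest"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  motif_paths <- write_motif_sets(toy_motif_sets(), dir)
  c(gg, vv,
    list(conservation = cons, motif_sets = toy_motif_sets(),
         paths = c(paths, motifs = unname(motif_paths))))
}

#' Simulate score-linked minor allele frequencies
#'
#' A simple linear-with-noise MAF generator for evaluating the binned
#' score-MAF correlation: `maf = pmax(0, intercept + slope * score +
#' Normal(0, noise_sd))`.
#'
#' @param scores Numeric vector.
#' @param intercept,slope,noise_sd Model parameters.
#' @param seed Seed.
#' @return Numeric vector of MAFs.
#' @export
sim_maf <- function(scores, intercept = 0.05, slope = -0.04,
                    noise_sd = 0.005, seed = 1L) {
  set.seed(as.integer(seed))
  pmax(0, intercept + slope * scores + stats::rnorm(length(scores), 0,
                                                    noise_sd))
}
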