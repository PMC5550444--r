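# Splice-site position-specific scoring matrices.
#
# Window definitions (strand-oriented):
#   acceptor (3'ss): last 20 intronic nt + first 3 exonic nt, K = 23; the
#     invariant AG core sits at window positions 19-20.
#   donor (5'ss): last 3 exonic nt + first 6 intronic nt, K = 9; the GT/GC
#     core sits at window positions 4-5.
# Only introns whose first two bases are GT or GC and whose last two are AG
# contribute to the matrices.

BASES <- c("A", "C", "G", "T")
ACCEPTOR_K <- 23L
DONOR_K <- 9L

new_pssm <- function(site_class, counts, pseudocount = 1) {
  K <- nrow(counts)
  n <- sum(counts[1, ])
  freq <- (counts + pseudocount) / (n + 4 * pseudocount)
  stopifnot(all(abs(rowSums(freq) - 1) < 1e-9), all(freq > 0))
  p <- structure(list(site_class = site_class, K = K, freq = freq,
                      pseudocount = pseudocount, n_sites = n,
                      bounds = "analytic"),
                 class = "pssm")
  p$min_raw <- sum(apply(log2(freq), 1, min))
  p$max_raw <- sum(apply(log2(freq), 1, max))
  p
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM <%s> K=%d, %d training sites, raw range [%.3f, %.3f]\n",
              x$site_class, x$K, x$n_sites, x$min_raw, x$max_raw))
  invisible(x)
}

# Strand-oriented acceptor/donor window genomic coordinates for exon i of tx.
# Returns NULL when the flanking intron does not exist.
acceptor_window_range <- function(tx, i) {
  if (i <= 1L) return(NULL)
  if (tx$strand == "+") {
    s <- tx$exons$start[i]
    c(s - 20L, s + 2L)
  } else {
    e <- tx$exons$end[i]
    c(e - 2L, e + 20L)
  }
}

donor_window_range <- function(tx, i) {
  if (i >= nrow(tx$exons)) return(NULL)
  if (tx$strand == "+") {
    e <- tx$exons$end[i]
    c(e - 2L, e + 6L)
  } else {
    s <- tx$exons$start[i]
    c(s - 6L, s + 2L)
  }
}

# Oriented window sequence with an optional substituted variant base.
window_seq <- function(genome, tx, rng, variant = NULL) {
  if (is.null(rng)) return(NA_character_)
  len <- contig_length(genome, tx$contig)
  if (rng[1] < 1L || rng[2] > len) stop("window extends past contig end")
  s <- get_sequence(genome, tx$contig, rng[1], rng[2], "+")
  if (!is.null(variant) && variant$pos >= rng[1] && variant$pos <= rng[2]) {
    i <- variant$pos - rng[1] + 1L
    stopifnot(substr(s, i, i) == variant$ref)
    substr(s, i, i) <- variant$alt
  }
  if (tx$strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

# First two / last two intron bases, strand-oriented.
intron_dinucs <- function(genome, tx, intron) {
  seq <- get_sequence(genome, tx$contig, intron$start, intron$end, tx$strand)
  n <- nchar(seq)
  list(first2 = substr(seq, 1L, 2L), last2 = substr(seq, n - 1L, n))
}

#' Build acceptor and donor PSSMs from annotated introns
#'
#' Every intron whose strand-oriented boundary dinucleotides are GT/GC..AG
#' contributes its acceptor window (20 intronic + 3 exonic nt) and donor
#' window (3 exonic + 6 intronic nt) to the respective frequency matrix.
#' An add-one (Laplace) pseudocount per base per position is applied before
#' normalization so `log2` never sees zero.
#'
#' Normalization bounds: with `bounds = "analytic"` (default), `Min`/`Max`
#' are the analytic extremes over all possible K-mers
#' (`sum_i min_b log2 f(i,b)` and `sum_i max_b log2 f(i,b)`), so every
#' genomic motif's normalized score lies in \[0, 100\].  With
#' `bounds = "annotated"` they are the observed extremes over the annotated
#' training sites.
#'
#' @param transcripts Named list of `transcript` objects.
#' @param genome A `genome` object.
#' @param pseudocount Per-base per-position pseudocount (default 1).
#' @param bounds `"analytic"` or `"annotated"`.
#' @return A list with elements `acceptor` and `donor`, each a `pssm`.
#' @export
build_pssms <- function(transcripts, genome, pseudocount = 1,
                        bounds = c("analytic", "annotated")) {
  bounds <- match.arg(bounds)
  acc <- matrix(0L, ACCEPTOR_K, 4, dimnames = list(NULL, BASES))
  don <- matrix(0L, DONOR_K, 4, dimnames = list(NULL, BASES))
  acc_seqs <- character(0)
  don_seqs <- character(0)
  for (tx in transcripts) {
    introns <- tx_introns(tx)
    for (j in seq_len(nrow(introns))) {
      intr <- introns[j, ]
      if (intr$end - intr$start + 1L < 4L) next
      dn <- intron_dinucs(genome, tx, intr)
      if (!(dn$first2 %in% c("GT", "GC")) || dn$last2 != "AG") next
      dwin <- tryCatch(window_seq(genome, tx, donor_window_range(tx, j)),
                       error = function(e) NA_character_)
      awin <- tryCatch(window_seq(genome, tx, acceptor_window_range(tx, j + 1L)),
                       error = function(e) NA_character_)
      if (!is.na(dwin) && !grepl("[^ACGT]", dwin)) don_seqs <- c(don_seqs, dwin)
      if (!is.na(awin) && !grepl("[^ACGT]", awin)) acc_seqs <- c(acc_seqs, awin)
    }
  }
  if (!length(don_seqs) || !length(acc_seqs))
    stop("no qualifying G[T/C]..AG introns in the annotation")
  count_into <- function(mat, seqs) {
    for (s in seqs) {
      b <- strsplit(s, "")[[1]]
      idx <- cbind(seq_len(nrow(mat)), match(b, BASES))
      mat[idx] <- mat[idx] + 1L
    }
    mat
  }
  acc <- count_into(acc, acc_seqs)
  don <- count_into(don, don_seqs)
  ap <- new_pssm("acceptor_3ss", acc, pseudocount)
  dp <- new_pssm("donor_5ss", don, pseudocount)
  if (bounds == "annotated") {
    ap$bounds <- dp$bounds <- "annotated"
    ap$min_raw <- min(vapply(acc_seqs, raw_score, 0, pssm = ap))
    ap$max_raw <- max(vapply(acc_seqs, raw_score, 0, pssm = ap))
    dp$min_raw <- min(vapply(don_seqs, raw_score, 0, pssm = dp))
    dp$max_raw <- max(vapply(don_seqs, raw_score, 0, pssm = dp))
  }
  list(acceptor = ap, donor = dp)
}

#' Raw log2 PSSM score of a K-mer
#'
#' `score = sum_{i=1..K} log2 f(i, A_i)` where `A_i` is the base at motif
#' position `i`.
#'
#' @param pssm A `pssm` object.
#' @param seq A K-length string over `{A,C,G,T}`; a window containing `N`
#'   (or any other character) returns `NA` with a warning.
#' @return The raw score (numeric scalar).
#' @export
raw_score <- function(pssm, seq) {
  stopifnot(inherits(pssm, "pssm"))
  if (nchar(seq) != pssm$K)
    stop(sprintf("sequence length %d != K = %d", nchar(seq), pssm$K))
  b <- strsplit(toupper(seq), "")[[1]]
  idx <- match(b, BASES)
  if (anyNA(idx)) {
    warning("window contains non-ACGT base; score is missing")
    return(NA_real_)
  }
  sum(log2(pssm$freq[cbind(seq_len(pssm$K), idx)]))
}

#' Normalized PSSM score on the 0-100 scale
#'
#' `100 * (raw - Min) / (Max - Min)`, clamped to \[0, 100\].
#'
#' @inheritParams raw_score
#' @return Numeric scalar in \[0, 100\], or `NA` for windows containing `N`.
#' @export
normalized_score <- function(pssm, seq) {
  if (pssm$max_raw <= pssm$min_raw)
    stop("degenerate PSSM: max_raw <= min_raw")
  r <- raw_score(pssm, seq)
  if (is.na(r)) return(NA_real_)
  min(100, max(0, 100 * (r - pssm$min_raw) / (pssm$max_raw - pssm$min_raw)))
}

#' Extract the acceptor and donor windows around a variant's exon
#'
#' Returns the strand-oriented 23-mer acceptor window and 9-mer donor window
#' of the harboring (or nearest) exon, both before and after substituting
#' the variant base.  Windows whose flanking intron does not exist (acceptor
#' of the first exon, donor of the last) are `NA`.
#'
#' @param context A `variant_context`.
#' @param genome A `genome` object.
#' @return A list with elements `acceptor` and `donor`, each a list of
#'   `ref`, `alt` (oriented window strings or `NA`) and `range` (genomic
#'   start/end or `NULL`).
#' @export
site_windows <- function(context, genome) {
  tx <- context$transcript
  i <- context$exon_index
  v <- context$variant
  one <- function(rng) {
    if (is.null(rng)) return(list(ref = NA_character_, alt = NA_character_,
                                  range = NULL))
    ref <- window_seq(genome, tx, rng)
    alt <- window_seq(genome, tx, rng, variant = v)
    list(ref = ref, alt = alt, range = rng)
  }
  list(acceptor = one(acceptor_window_range(tx, i)),
       donor = one(donor_window_range(tx, i)))
}

#' Serialize PSSMs to a TSV file
#'
#' One row per (site_class, position) with the four base frequencies;
#' `#`-prefixed header lines record the pseudocount and normalization
#' bounds.
#'
#' @param pssms List with `acceptor` and `donor` `pssm` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pssms <- function(pssms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pssms) {
    writeLines(sprintf("# %s K=%d pseudocount=%g n_sites=%d min_raw=%.17g max_raw=%.17g bounds=%s",
                       p$site_class, p$K, p$pseudocount, p$n_sites,
                       p$min_raw, p$max_raw, p$bounds), con)
  }
  rows <- do.call(rbind, lapply(pssms, function(p) {
    data.frame(site_class = p$site_class, position = seq_len(p$K),
               A = p$freq[, "A"], C = p$freq[, "C"],
               G = p$freq[, "G"], T = p$freq[, "T"])
  }))
  utils::write.table(format(rows, digits = 17), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read PSSMs written by [write_pssms()]
#' @param path TSV path.
#' @return A list with `acceptor` and `donor` `pssm` objects.
#' @export
read_pssms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- lines[grepl("^#", lines)]
  tab <- utils::read.delim(textConnection(lines[!grepl("^#", lines)]),
                           stringsAsFactors = FALSE)
  parse_meta <- function(class_name) {
    m <- meta[grepl(paste0("^# ", class_name, " "), meta)]
    kv <- regmatches(m, gregexpr("[a-z_]+=[^ ]+", m))[[1]]
    vals <- sub("^[a-z_]+=", "", kv)
    names(vals) <- sub("=.*$", "", kv)
    vals
  }
  one <- function(class_name) {
    d <- tab[tab$site_class == class_name, ]
    d <- d[order(d$position), ]
    mv <- parse_meta(class_name)
    freq <- as.matrix(d[, BASES])
    dimnames(freq) <- list(NULL, BASES)
    structure(list(site_class = class_name, K = nrow(freq), freq = freq,
                   pseudocount = as.numeric(mv[["pseudocount"]]),
                   n_sites = as.integer(mv[["n_sites"]]),
                   bounds = mv[["bounds"]],
                   min_raw = as.numeric(mv[["min_raw"]]),
                   max_raw = as.numeric(mv[["max_raw"]])),
              class = "pssm")
  }
  list(acceptor = one("acceptor_3ss"), donor = one("donor_5ss"))
}
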