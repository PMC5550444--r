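# Input/output and variant-to-transcript mapping.
#
# Coordinates are 1-based inclusive throughout (GTF/VCF convention).  All
# sequence-window helpers take (contig, start, end, strand) and return the
# strand-oriented sequence (reverse complement for "-").

#' Load a reference genome from FASTA
#'
#' Reads all contigs of a FASTA file into a genome object.  Sequences are
#' uppercased; `N` is allowed and propagates into windows (windows containing
#' `N` score as missing downstream).
#'
#' @param path Path to a FASTA file.
#' @return An object of class `genome`: a named [Biostrings::DNAStringSet]
#'   with one entry per contig.
#' @export
load_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no FASTA records in ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate contig names in ", path)
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty FASTA record in ", path)
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  structure(list(seq = seqs), class = "genome")
}

#' Extract a strand-oriented genomic sequence
#'
#' @param genome A `genome` object from [load_genome()].
#' @param contig Contig name.
#' @param start,end 1-based inclusive genomic coordinates (`start <= end`).
#' @param strand `"+"` or `"-"`; for `"-"` the reverse complement is returned.
#' @return A character scalar of length `end - start + 1`.
#' @export
get_sequence <- function(genome, contig, start, end, strand = "+") {
  stopifnot(inherits(genome, "genome"))
  if (!contig %in% names(genome$seq)) stop("unknown contig: ", contig)
  len <- length(genome$seq[[contig]])
  if (start < 1L || end > len || start > end)
    stop(sprintf("coordinates [%d,%d] out of bounds for contig %s (length %d)",
                 start, end, contig, len))
  s <- as.character(Biostrings::subseq(genome$seq[[contig]], start, end))
  if (strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

contig_length <- function(genome, contig) {
  length(genome$seq[[contig]])
}

#' Load transcript models from GTF/GFF3
#'
#' Exon features are grouped per transcript and ordered in transcription
#' order: ascending genomic start on `+`, descending on `-`.  Coordinates are
#' kept 1-based inclusive as in the file.
#'
#' @param path Path to a GTF or GFF3 file whose exon features carry
#'   transcript and gene identifiers.
#' @return A named list of `transcript` objects, each a list with fields
#'   `id`, `gene_id`, `contig`, `strand` and `exons` (data.frame of
#'   `start`/`end` in transcription order).
#' @export
load_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  check_annotation_lines(path)
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e) stop("failed to parse ", path, ": ",
                                          conditionMessage(e)))
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(gr) == 0L) stop("no exon features in ", path)
  tid <- as.character(gr$transcript_id)
  if (is.null(gr$transcript_id) || anyNA(tid) || any(tid == ""))
    stop("exon feature without transcript_id in ", path)
  gid <- if (!is.null(gr$gene_id)) as.character(gr$gene_id) else tid
  df <- data.frame(
    transcript = tid, gene = gid,
    contig = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  out <- lapply(split(df, df$transcript), function(d) {
    strand <- d$strand[1]
    if (!strand %in% c("+", "-"))
      stop("transcript ", d$transcript[1], " has no strand")
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1] <= d$end[-nrow(d)]))
      stop("overlapping exons in transcript ", d$transcript[1])
    if (strand == "-") d <- d[rev(seq_len(nrow(d))), , drop = FALSE]
    structure(list(id = d$transcript[1], gene_id = d$gene[1],
                   contig = d$contig[1], strand = strand,
                   exons = data.frame(start = d$start, end = d$end)),
              class = "transcript")
  })
  out[order(names(out))]
}

# Light pre-validation so malformed lines are reported with a line number.
check_annotation_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nf < 8L]
  if (length(bad))
    stop("malformed annotation line ", bad[1], " in ", path,
         " (expected >= 8 tab-separated fields)")
  invisible(TRUE)
}

#' Re-emit transcripts as GTF
#'
#' Writes one `exon` feature per exon, so that
#' `load_annotation(write_annotation(tx, f))` round-trips the exon sets.
#'
#' @param transcripts Named list of `transcript` objects.
#' @param path Output path (`.gtf`).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(transcripts, path) {
  rows <- do.call(rbind, lapply(transcripts, function(tx) {
    data.frame(contig = tx$contig, start = tx$exons$start, end = tx$exons$end,
               strand = tx$strand, transcript = tx$id, gene = tx$gene_id,
               stringsAsFactors = FALSE)
  }))
  gr <- GenomicRanges::GRanges(
    seqnames = rows$contig,
    ranges = IRanges::IRanges(pmin(rows$start, rows$end),
                              pmax(rows$start, rows$end)),
    strand = rows$strand)
  gr$source <- "trapscore"
  gr$type <- "exon"
  gr$transcript_id <- rows$transcript
  gr$gene_id <- rows$gene
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

# Introns of a transcript, in transcription order.  Returns a data.frame of
# genomic start/end (start <= end); zero rows for single-exon transcripts.
tx_introns <- function(tx) {
  n <- nrow(tx$exons)
  if (n < 2L) return(data.frame(start = integer(0), end = integer(0)))
  if (tx$strand == "+") {
    data.frame(start = tx$exons$end[-n] + 1L, end = tx$exons$start[-1L] - 1L)
  } else {
    # transcription order runs right to left: intron j lies genomically
    # between exon j+1 (left) and exon j (right)
    data.frame(start = tx$exons$end[-1L] + 1L, end = tx$exons$start[-n] - 1L)
  }
}

#' Load SNVs from a VCF file
#'
#' Multi-allelic rows are split into one record per alternate allele;
#' non-SNV alleles (indels, symbolic) are skipped with a warning.
#'
#' @param path Path to a VCF v4.x file.
#' @param genome Optional `genome`; when given, each record's REF is checked
#'   against the reference sequence.
#' @return A data.frame with columns `contig`, `pos`, `ref`, `alt`.
#' @export
load_variants <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alts <- strsplit(as.character(fix[, "ALT"]), ",", fixed = TRUE)
  idx <- rep(seq_len(nrow(fix)), lengths(alts))
  out <- data.frame(contig = as.character(fix[idx, "CHROM"]),
                    pos = as.integer(fix[idx, "POS"]),
                    ref = as.character(fix[idx, "REF"]),
                    alt = unlist(alts),
                    stringsAsFactors = FALSE)
  snv <- nchar(out$ref) == 1L & nchar(out$alt) == 1L &
    out$ref %in% c("A", "C", "G", "T") & out$alt %in% c("A", "C", "G", "T") &
    out$ref != out$alt
  if (any(!snv))
    warning(sum(!snv), " non-SNV allele(s) skipped")
  out <- out[snv, , drop = FALSE]
  if (!is.null(genome)) {
    for (i in seq_len(nrow(out))) {
      obs <- get_sequence(genome, out$contig[i], out$pos[i], out$pos[i])
      if (obs != out$ref[i])
        stop(sprintf("REF mismatch at %s:%d (VCF %s, genome %s)",
                     out$contig[i], out$pos[i], out$ref[i], obs))
    }
  }
  rownames(out) <- NULL
  out
}

#' Map a variant into transcript coordinate context
#'
#' One context is produced per transcript whose gene span (first exon start
#' to last exon end) contains the variant.  Distances are strand-oriented
#' offsets from the harboring (or nearest) exon's boundaries:
#' `dist_to_acceptor` is the offset from the exon's first base (0 at the
#' first exonic base, negative in the upstream intron) and `dist_to_donor`
#' the offset from the exon's last base (0 at the last exonic base, positive
#' in the downstream intron).  Distances to a junction that does not exist
#' (acceptor of the first exon, donor of the last) are `NA`.
#'
#' Intronic variants attach to the nearest exon by minimal distance; ties
#' attach to the upstream exon.
#'
#' @param variant A one-row data.frame (or list) with `contig`, `pos`,
#'   `ref`, `alt`.
#' @param transcripts Named list of `transcript` objects.
#' @return A list of `variant_context` objects (empty if the variant lies
#'   outside all gene spans).
#' @export
locate_variant <- function(variant, transcripts) {
  out <- list()
  for (tx in transcripts) {
    if (tx$contig != variant$contig) next
    span <- range(c(tx$exons$start, tx$exons$end))
    if (variant$pos < span[1] || variant$pos > span[2]) next
    ctx <- variant_context(variant, tx)
    if (!is.null(ctx)) out[[length(out) + 1L]] <- ctx
  }
  out
}

# Oriented position: monotone increasing along the direction of transcription.
oriented_pos <- function(pos, strand) if (strand == "+") pos else -pos

variant_context <- function(variant, tx) {
  n <- nrow(tx$exons)
  opos <- oriented_pos(variant$pos, tx$strand)
  # oriented first/last base of each exon (first <= last along transcription)
  if (tx$strand == "+") {
    first <- tx$exons$start; last <- tx$exons$end
  } else {
    first <- -tx$exons$end; last <- -tx$exons$start
  }
  inside <- which(opos >= first & opos <= last)
  if (length(inside)) {
    i <- inside[1]
    region <- "exonic"
  } else {
    up <- which(last < opos)           # exons fully upstream of the variant
    if (!length(up) || length(up) == n) return(NULL)
    i_up <- max(up)
    d_up <- opos - last[i_up]
    d_down <- first[i_up + 1L] - opos
    i <- if (d_up <= d_down) i_up else i_up + 1L
    region <- "intronic"
  }
  structure(list(
    variant = variant, transcript = tx, region = region, exon_index = i,
    dist_to_acceptor = if (i > 1L) opos - first[i] else NA_real_,
    dist_to_donor   = if (i < n) opos - last[i] else NA_real_),
    class = "variant_context")
}

#' Load a per-position conservation track
#'
#' Reads a tab-delimited file with columns chrom, pos, score (a rejected
#' substitutions style conservation score).  Duplicate positions keep the
#' last value, with a warning.
#'
#' @param path Path to the TSV file.  A header line is detected (non-numeric
#'   third field) and skipped.
#' @return An object of class `conservation_track`.
#' @export
load_conservation <- function(path) {
  if (!file.exists(path)) stop("conservation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  env <- new.env(parent = emptyenv())
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 3L)) stop("conservation rows need 3 columns")
    m <- do.call(rbind, parts)
    # tolerate a single header line (both pos and score fields non-numeric)
    if (is.na(suppressWarnings(as.numeric(m[1, 2]))) &&
        is.na(suppressWarnings(as.numeric(m[1, 3])))) {
      m <- m[-1, , drop = FALSE]
    }
    if (nrow(m)) {
      score <- suppressWarnings(as.numeric(m[, 3]))
      if (anyNA(score)) stop("non-numeric conservation score at row ",
                             which(is.na(score))[1])
      key <- paste0(m[, 1], ":", m[, 2])
      if (anyDuplicated(key))
        warning("duplicate conservation positions; last value wins")
      for (i in seq_along(key)) assign(key[i], score[i], envir = env)
    }
  }
  structure(list(table = env), class = "conservation_track")
}

#' Query a conservation track
#'
#' @param track A `conservation_track`.
#' @param contig,pos Position to query.
#' @return The score, or `NA_real_` when the position is absent.
#' @export
conservation_at <- function(track, contig, pos) {
  key <- paste0(contig, ":", pos)
  if (exists(key, envir = track$table, inherits = FALSE))
    get(key, envir = track$table) else NA_real_
}

#' Load a splicing-regulatory motif set
#'
#' Reads a two-column text file (k-mer, weight); the motif length `k` is
#' inferred and must be uniform.
#'
#' @param path Path to the motif file.
#' @param name Set name (e.g. `"SRSF1"` or `"silencer"`).
#' @param role `"enhancer"` or `"silencer"`; used when summing gain/loss
#'   counts across sets.
#' @return An object of class `motif_set` with fields `name`, `role`, `k`,
#'   and `kmers` (named numeric vector of weights).
#' @export
load_motif_set <- function(path, name, role = c("enhancer", "silencer")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("motif file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (!length(lines)) stop("empty motif file: ", path)
  parts <- strsplit(lines, "[\t ]+")
  kmers <- toupper(vapply(parts, `[`, "", 1L))
  w <- vapply(parts, function(p) {
    if (length(p) >= 2L) suppressWarnings(as.numeric(p[2])) else 1
  }, 0)
  if (anyNA(w) || any(!is.finite(w))) stop("non-finite motif weight in ", path)
  if (length(unique(nchar(kmers))) != 1L)
    stop("mixed k-mer lengths in ", path)
  if (any(grepl("[^ACGT]", kmers)))
    stop("invalid characters in motif k-mers in ", path)
  structure(list(name = name, role = role, k = nchar(kmers[1]),
                 kmers = stats::setNames(w, kmers)),
            class = "motif_set")
}

#' Write a variant score table
#'
#' Writes one row per variant-in-transcript with the deterministic column
#' order: contig, pos, ref, alt, transcript, trap, tier, then the 20
#' registry features.  The file round-trips through [read_scores()].
#'
#' @param records A data.frame containing at least those columns (as
#'   produced by scoring [assemble_features()] output with a model).
#' @param path Output TSV path.
#' @param header Optional character vector of `#`-prefixed provenance lines.
#' @return `path`, invisibly.
#' @export
write_scores <- function(records, path, header = NULL) {
  cols <- c("contig", "pos", "ref", "alt", "transcript", "trap", "tier",
            feature_registry())
  missing <- setdiff(cols, names(records))
  if (length(missing)) stop("missing score columns: ",
                            paste(missing, collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", sub("^#\\s*", "", header)), con)
  utils::write.table(records[, cols, drop = FALSE], con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a variant score table written by [write_scores()]
#' @param path TSV path.
#' @return A data.frame.
#' @export
read_scores <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
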