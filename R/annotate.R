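#' Transcript models table
#'
#' Transcript structures are exchanged as a tidy data.frame with one row
#' per feature interval: columns `gene_id`, `transcript_id`, `chrom`,
#' `strand` (`"+"`/`"-"`), `type` (`exon`, `CDS`, `five_prime_UTR`,
#' `three_prime_UTR`), `start`, `end`. Coordinates are 0-based half-open
#' internally; GFF3 I/O converts to 1-based inclusive.
#'
#' @param df data.frame with the columns above.
#' @return The validated data.frame (class `transcript_models`).
#' @export
transcript_models <- function(df) {
  need <- c("gene_id", "transcript_id", "chrom", "strand", "type",
            "start", "end")
  if (!all(need %in% names(df)))
    .stopf("transcript models need columns: %s", paste(need, collapse = ", "))
  if (!all(df$type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")))
    .stopf("unknown feature type in transcript models")
  if (any(df$end <= df$start)) .stopf("empty or reversed feature interval")
  class(df) <- c("transcript_models", "data.frame")
  df
}

#' Longest open reading frame
#'
#' Scans the given nucleotide sequence (one strand) in all three frames
#' for the longest span starting with `ATG` and ending with an in-frame
#' canonical stop (`TAA`/`TAG`/`TGA`), stop included.
#'
#' @param x A single nucleotide string over `A,C,G,T,N` (case-insensitive).
#' @return `list(start, end, frame)` with 0-based half-open coordinates
#'   and `frame = start %% 3`, or `NULL` when no complete ORF exists.
#' @export
longest_orf <- function(x) {
  x <- toupper(as.character(x))
  if (!grepl("^[ACGTN]*$", x)) .stopf("sequence must be over A,C,G,T,N")
  n <- nchar(x)
  best <- NULL
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 2L) next
    codons <- substring(x, frame + 3L * (seq_len(ncod) - 1L) + 1L,
                        frame + 3L * seq_len(ncod))
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    starts <- which(codons == "ATG")
    if (!length(stops) || !length(starts)) next
    prev_stop <- 0L
    for (st in stops) {
      cand <- starts[starts > prev_stop & starts < st]
      if (length(cand)) {
        a <- cand[1]
        len <- (st - a + 1L) * 3L
        if (is.null(best) || len > best$len) {
          s0 <- frame + (a - 1L) * 3L
          best <- list(start = s0, end = s0 + len, frame = frame, len = len)
        }
      }
      prev_stop <- st
    }
  }
  if (is.null(best)) return(NULL)
  best$len <- NULL
  best
}

#' One transcript per gene, by length
#'
#' Keeps, for each gene, the transcript with the largest summed exon
#' length; ties break toward the lexicographically smallest transcript id
#' (deterministic).
#'
#' @param models A [transcript_models()] data.frame.
#' @return The models restricted to the selected transcripts.
#' @export
select_longest_transcript <- function(models) {
  models <- transcript_models(models)
  ex <- models[models$type == "exon", ]
  if (!nrow(ex)) .stopf("models contain no exon features")
  len <- tapply(ex$end - ex$start,
                list(tx = ex$transcript_id), sum)
  tx_gene <- unique(models[, c("gene_id", "transcript_id")])
  tx_gene$len <- as.numeric(len[tx_gene$transcript_id])
  keep <- unlist(lapply(split(tx_gene, tx_gene$gene_id), function(g) {
    g <- g[order(-g$len, g$transcript_id), ]
    g$transcript_id[1]
  }))
  out <- models[models$transcript_id %in% keep, ]
  rownames(out) <- NULL
  out
}

# intron intervals (0-based half-open) of one transcript, ordered 5'->3'
# on the transcript strand
.introns_of <- function(exons, strand) {
  exons <- exons[order(exons$start), ]
  if (nrow(exons) < 2L) return(NULL)
  iv <- data.frame(start = head(exons$end, -1), end = tail(exons$start, -1))
  iv <- iv[iv$end > iv$start, ]
  if (!nrow(iv)) return(NULL)
  if (strand == "-") iv <- iv[rev(seq_len(nrow(iv))), ]
  iv
}

#' Per-site sequence-class map
#'
#' Labels every position of a chromosome with one sequence class, using
#' the precedence CDS > UTR > intron > intergenic across overlapping
#' genes. Bases 8--30 (1-based, inclusive; 23 bases) of introns shorter
#' than 70 bp, counted from the intron's 5' end on the transcript strand,
#' form the short-intron neutral class `SI8_30` (a subset of intron
#' sites); introns shorter than 30 bp contribute nothing. Transcripts
#' should first be reduced to one per gene
#' ([select_longest_transcript()]).
#'
#' @param models A [transcript_models()] data.frame (one chromosome).
#' @param genome_length Chromosome length in bp.
#' @param si_max_intron Introns strictly shorter than this are short
#'   introns (default 70 bp).
#' @return A `site_class_map`: list with `class` (character vector of
#'   length `genome_length`; labels `CDS`, `five_prime_UTR`,
#'   `three_prime_UTR`, `intron`, `SI8_30`, `intergenic`), `transcript`
#'   (source transcript id or `NA`), and `codon_pos` (1--3 for CDS sites,
#'   `NA` elsewhere).
#' @export
classify_sites <- function(models, genome_length, si_max_intron = 70L) {
  models <- transcript_models(models)
  L <- as.integer(genome_length)
  class <- rep("intergenic", L)
  transcript <- rep(NA_character_, L)
  codon_pos <- rep(NA_integer_, L)
  rank <- c(intergenic = 0, intron = 1, SI8_30 = 1.5,
            three_prime_UTR = 2, five_prime_UTR = 2, CDS = 3)
  assign_label <- function(idx, label, tx) {
    idx <- idx[idx >= 1L & idx <= L]
    up <- idx[rank[class[idx]] < rank[label]]
    class[up] <<- label
    transcript[up] <<- tx
    up
  }
  for (tx in unique(models$transcript_id)) {
    m <- models[models$transcript_id == tx, ]
    strand <- m$strand[1]
    exons <- m[m$type == "exon", c("start", "end")]
    introns <- .introns_of(exons, strand)
    if (!is.null(introns)) for (i in seq_len(nrow(introns))) {
      iv <- introns[i, ]
      assign_label(seq.int(iv$start + 1L, iv$end), "intron", tx)
      len <- iv$end - iv$start
      if (len >= 30L && len < si_max_intron) {
        si <- if (strand == "+") seq.int(iv$start + 8L, iv$start + 30L)
              else seq.int(iv$end - 29L, iv$end - 7L)
        keep <- si[class[si] == "intron"]
        class[keep] <- "SI8_30"
        transcript[keep] <- tx
      }
    }
    for (ut in c("five_prime_UTR", "three_prime_UTR")) {
      u <- m[m$type == ut, ]
      if (nrow(u)) for (i in seq_len(nrow(u)))
        assign_label(seq.int(u$start[i] + 1L, u$end[i]), ut, tx)
    }
    cds <- m[m$type == "CDS", c("start", "end")]
    if (nrow(cds)) {
      cds <- cds[order(cds$start), ]
      if (strand == "-") cds <- cds[rev(seq_len(nrow(cds))), ]
      offset <- 0L
      for (i in seq_len(nrow(cds))) {
        pos0 <- seq.int(cds$start[i], cds$end[i] - 1L)  # 0-based
        if (strand == "-") pos0 <- rev(pos0)
        idx <- pos0 + 1L
        placed <- assign_label(idx, "CDS", tx)
        cp <- ((offset + seq_along(idx) - 1L) %% 3L) + 1L
        codon_pos[idx] <- cp
        offset <- offset + length(idx)
      }
    }
  }
  structure(list(class = class, transcript = transcript,
                 codon_pos = codon_pos, L = L),
            class = "site_class_map")
}

#' @export
print.site_class_map <- function(x, ...) {
  cat("site_class_map over", x$L, "bp\n")
  print(table(x$class))
  invisible(x)
}

#' Read transcript models from GFF3
#'
#' Parses a GFF3 annotation into the internal [transcript_models()] table,
#' converting 1-based inclusive coordinates to 0-based half-open. Feature
#' parents are taken from the `Parent` attribute (transcripts) and gene
#' ids from the transcript's own `Parent`.
#'
#' @param path GFF3 file.
#' @return A [transcript_models()] data.frame.
#' @export
read_gff_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  is_tx <- type %in% c("mRNA", "transcript")
  tx_gene <- setNames(vapply(md$Parent[is_tx], function(p)
    if (length(p)) as.character(p[1]) else NA_character_, ""),
    as.character(md$ID[is_tx]))
  is_feat <- type %in% c("exon", "CDS", "five_prime_UTR", "three_prime_UTR")
  parent <- vapply(md$Parent[is_feat], function(p)
    if (length(p)) as.character(p[1]) else NA_character_, "")
  transcript_models(data.frame(
    gene_id = unname(tx_gene[parent]),
    transcript_id = parent,
    chrom = as.character(GenomicRanges::seqnames(gr))[is_feat],
    strand = as.character(GenomicRanges::strand(gr))[is_feat],
    type = type[is_feat],
    start = GenomicRanges::start(gr)[is_feat] - 1L,
    end = GenomicRanges::end(gr)[is_feat]))
}

#' Write transcript models to GFF3
#'
#' Emits gene, mRNA and feature records with 1-based inclusive
#' coordinates and CDS phase computed from the running in-frame offset.
#'
#' @param models A [transcript_models()] data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gff_models <- function(models, path) {
  models <- transcript_models(models)
  lines <- c("##gff-version 3")
  for (g in unique(models$gene_id)) {
    mg <- models[models$gene_id == g, ]
    lines <- c(lines, sprintf("%s\tfasterx\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              mg$chrom[1], min(mg$start) + 1L, max(mg$end),
                              mg$strand[1], g))
    for (tx in unique(mg$transcript_id)) {
      m <- mg[mg$transcript_id == tx, ]
      lines <- c(lines, sprintf(
        "%s\tfasterx\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        m$chrom[1], min(m$start) + 1L, max(m$end), m$strand[1], tx, g))
      cds <- m[m$type == "CDS", ]
      cds <- cds[order(cds$start), ]
      if (m$strand[1] == "-") cds <- cds[rev(seq_len(nrow(cds))), ]
      phase <- setNames(rep(".", nrow(m)), rownames(m))
      off <- 0L
      for (i in seq_len(nrow(cds))) {
        phase[rownames(cds)[i]] <- as.character((3L - off %% 3L) %% 3L)
        off <- off + (cds$end[i] - cds$start[i])
      }
      for (i in seq_len(nrow(m)))
        lines <- c(lines, sprintf(
          "%s\tfasterx\t%s\t%d\t%d\t.\t%s\t%s\tParent=%s",
          m$chrom[i], m$type[i], m$start[i] + 1L, m$end[i], m$strand[i],
          phase[rownames(m)[i]], tx))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
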