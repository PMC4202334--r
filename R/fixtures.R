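#' Simulate a compact gene annotation
#'
#' Lays non-overlapping transcripts along a chromosome, each with a
#' 5'-UTR, a multi-exon CDS (length divisible by 3) and a 3'-UTR. Intron
#' lengths are drawn from a log-normal distribution with median 70 bp (the
#' genome-wide median this pipeline's short-intron class is defined
#' against), truncated below at 31 bp, so a sizeable fraction falls under
#' the 70-bp short-intron cutoff.
#'
#' @param L Chromosome length (bp).
#' @param n_genes Number of genes to place.
#' @param chrom Chromosome name.
#' @param seed Integer seed.
#' @return A [transcript_models()] data.frame.
#' @export
simulate_annotation <- function(L, n_genes = 10L, chrom = "chr", seed = 1L) {
  .with_seed(seed, {
    models <- list()
    cursor <- 200L
    for (g in seq_len(n_genes)) {
      strand <- sample(c("+", "-"), 1L)
      n_introns <- sample(1:3, 1L)
      intron_len <- pmax(31L, as.integer(stats::rlnorm(n_introns,
                                                       log(70), 0.6)))
      n_cds_exon <- n_introns + 1L
      cds_len <- 3L * sample(40:120, n_cds_exon, replace = TRUE)
      utr5 <- sample(30:80, 1L); utr3 <- sample(50:150, 1L)
      total <- utr5 + sum(cds_len) + sum(intron_len) + utr3
      if (cursor + total + 200L > L) break
      gid <- sprintf("gene%03d", g); tid <- sprintf("tx%03d.1", g)
      # build on the + strand geometrically; strand only affects phase use
      p <- cursor
      feats <- list()
      add <- function(type, s, e)
        feats[[length(feats) + 1L]] <<- data.frame(
          gene_id = gid, transcript_id = tid, chrom = chrom,
          strand = strand, type = type, start = s, end = e)
      exon_start <- p
      add("five_prime_UTR", p, p + utr5); p <- p + utr5
      for (i in seq_len(n_cds_exon)) {
        add("CDS", p, p + cds_len[i]); p <- p + cds_len[i]
        if (i <= n_introns) {
          add("exon", exon_start, p)
          p <- p + intron_len[i]
          exon_start <- p
        }
      }
      add("three_prime_UTR", p, p + utr3); p <- p + utr3
      add("exon", exon_start, p)
      models[[length(models) + 1L]] <- do.call(rbind, feats)
      cursor <- p + sample(300:800, 1L)
    }
    transcript_models(do.call(rbind, models))
  })
}

# expand a variant-only alignment into full-length sequences on a common
# random reference background (ancestral alleles at variant sites)
.full_sequences <- function(aln, seed = 1L) {
  ref <- .with_seed(seed,
    sample(c("A", "C", "G", "T"), aln$L, replace = TRUE))
  anc <- aln$ancestral
  if (!is.null(anc)) ref[aln$positions + 1L] <- anc
  seqs <- lapply(seq_len(nrow(aln$alleles)), function(i) {
    s <- ref
    al <- aln$alleles[i, ]
    s[aln$positions + 1L] <- ifelse(is.na(al), "N", al)
    paste(s, collapse = "")
  })
  names(seqs) <- rownames(aln$alleles)
  seqs
}

#' Write a synthetic-data fixture bundle
#'
#' Materializes one simulated chromosome as the standard file formats the
#' pipeline's readers consume: an aligned multi-FASTA (one record per
#' haplotype), a VCF 4.2 of the variable sites with haploid genotypes, a
#' GFF3 of the gene models, a BED of planted repeat blocks, a TSV genetic
#' map (constant rate derived from `cfg$rho`), and a JSON truth sidecar
#' recording the generator parameters (including the population
#' rescaling and any sweep truth).
#'
#' @param outdir Output directory (created if needed).
#' @param cfg A [sim_config()]; a sweep config triggers [simulate_sweep()].
#' @param models Optional [transcript_models()]; default
#'   [simulate_annotation()] on the same chromosome.
#' @param mechanism Generator mechanism for neutral configs.
#' @return Invisibly, a named list of file paths plus the alignment.
#' @export
write_fixture_bundle <- function(outdir, cfg, models = NULL,
                                 mechanism = "sfs") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) .stopf("cannot create output directory %s", outdir)
  aln <- if (is.null(cfg$sweep)) simulate_neutral(cfg, mechanism)
         else simulate_sweep(cfg)
  if (is.null(models))
    models <- simulate_annotation(cfg$L, chrom = cfg$chrom,
                                  seed = cfg$seed + 1L)
  paths <- list()
  # FASTA
  paths$fasta <- file.path(outdir, paste0(cfg$chrom, ".fa"))
  seqs <- .full_sequences(aln, seed = cfg$seed + 2L)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(seqs)), paths$fasta)
  # VCF
  paths$vcf <- file.path(outdir, paste0(cfg$chrom, ".vcf"))
  .write_haploid_vcf(aln, paths$vcf)
  # GFF3
  paths$gff <- file.path(outdir, paste0(cfg$chrom, ".gff3"))
  write_gff_models(models, paths$gff)
  # repeat BED: planted blocks, one per repeat class
  paths$bed <- file.path(outdir, "repeats.bed")
  rep_classes <- c("LTR", "non-LTR", "DNA_transposon", "satellite",
                   "microsatellite", "low_complexity")
  bed <- .with_seed(cfg$seed + 3L, {
    st <- sort(sample.int(max(1L, cfg$L - 2000L), length(rep_classes)))
    data.frame(chrom = cfg$chrom, start = st,
               end = st + sample(200:1500, length(rep_classes),
                                 replace = TRUE),
               class = rep_classes)
  })
  bed$end <- pmin(bed$end, cfg$L)
  utils::write.table(bed, paths$bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  # genetic map: constant rate, r per bp per generation = rho / (2 n_pop)
  paths$map <- file.path(outdir, "genetic_map.tsv")
  bp <- seq(0L, cfg$L, length.out = 11L)
  rate <- 100 * cfg$rho / (2 * cfg$n_pop)  # cM per bp
  map <- data.frame(chrom = cfg$chrom, bp = round(bp), cM = rate * bp)
  utils::write.table(map, paths$map, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  # truth sidecar
  paths$truth <- file.path(outdir, "truth.json")
  truth <- list(seed = cfg$seed, n_ingroup = cfg$n_ingroup,
                n_outgroups = cfg$n_outgroups, L = cfg$L,
                theta = cfg$theta, rho = cfg$rho,
                outgroup_divergence = cfg$outgroup_divergence,
                n_pop = cfg$n_pop, mechanism = mechanism,
                rescaling = paste("population rescaled to n_pop haploids;",
                                  "per-generation mu and r are",
                                  "theta/(2 n_pop) and rho/(2 n_pop)"),
                sweep = if (!is.null(cfg$sweep))
                  attr(aln, "sweep_truth") else NULL,
                repeat_bed_classes = rep_classes)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(paths, list(alignment = aln, models = models)))
}

# minimal VCF 4.2 writer for haploid variant-only alignments; REF is the
# ancestral allele when known, else the first ingroup allele
.write_haploid_vcf <- function(aln, path) {
  n_s <- nrow(aln$alleles)
  ref <- if (!is.null(aln$ancestral)) aln$ancestral
         else apply(aln$alleles, 2L, function(x) x[!is.na(x)][1])
  alt <- vapply(seq_along(aln$positions), function(j) {
    a <- setdiff(unique(aln$alleles[, j]), c(ref[j], NA))
    if (!length(a)) "." else paste(sort(a), collapse = ",")
  }, "")
  gt <- vapply(seq_along(aln$positions), function(j) {
    alleles_j <- c(ref[j], strsplit(alt[j], ",")[[1]])
    idx <- match(aln$alleles[, j], alleles_j) - 1L
    out <- ifelse(is.na(aln$alleles[, j]), ".", as.character(idx))
    paste(out, collapse = "\t")
  }, "")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", aln$chrom, aln$L),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(aln$alleles)), collapse = "\t"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s",
                  aln$chrom, aln$positions + 1L, ref, alt, gt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a haplotype alignment from an aligned FASTA
#'
#' Reduces an aligned multi-FASTA (equal-length records, one per
#' haplotype) to its variable sites. Sample roles are taken from the
#' `roles` argument or guessed from record names (`*near*` ->
#' near outgroup, `*far*`/`mel*` -> far outgroup, rest ingroup).
#'
#' @param path FASTA file.
#' @param chrom Chromosome name (default: file base name).
#' @param roles Optional role vector matching the records.
#' @return A [haplotype_alignment()].
#' @export
read_haplotype_fasta <- function(path, chrom = NULL, roles = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(unique(Biostrings::width(ss))) != 1L)
    .stopf("records are not aligned (unequal lengths)")
  L <- Biostrings::width(ss)[1]
  M <- t(vapply(seq_along(ss), function(i)
    strsplit(as.character(ss[[i]]), "")[[1]], character(L)))
  rownames(M) <- names(ss)
  M[M == "N"] <- NA
  var <- which(vapply(seq_len(ncol(M)), function(j)
    length(unique(M[!is.na(M[, j]), j])) > 1L, logical(1)))
  if (is.null(roles)) {
    nm <- tolower(rownames(M))
    roles <- ifelse(grepl("near|sim", nm), "outgroup_near",
                    ifelse(grepl("far|mel", nm), "outgroup_far", "ingroup"))
  }
  if (is.null(chrom)) chrom <- sub("\\.[^.]*$", "", basename(path))
  haplotype_alignment(chrom = chrom, L = L, positions = var - 1L,
                      alleles = M[, var, drop = FALSE], roles = roles)
}

#' Read a haplotype alignment from a haploid VCF
#'
#' Parses a VCF (via \pkg{vcfR}) with haploid genotypes into a
#' [haplotype_alignment()]. Chromosome length is taken from the contig
#' header or the `L` argument.
#'
#' @param path VCF file.
#' @param L Optional chromosome length override.
#' @param roles Optional role vector matching the sample columns.
#' @return A [haplotype_alignment()].
#' @export
read_haplotype_vcf <- function(path, L = NULL, roles = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v)
  chrom <- fix[1, "CHROM"]
  if (is.null(L)) {
    m <- regmatches(v@meta, regexpr("length=[0-9]+", v@meta))
    if (!length(m)) .stopf("no contig length in header; supply L")
    L <- as.integer(sub("length=", "", m[1]))
  }
  pos <- as.integer(fix[, "POS"]) - 1L
  alleles_list <- lapply(seq_len(nrow(fix)), function(j)
    c(fix[j, "REF"], strsplit(fix[j, "ALT"], ",")[[1]]))
  M <- vapply(seq_len(nrow(gt)), function(j) {
    idx <- suppressWarnings(as.integer(gt[j, ])) + 1L
    alleles_list[[j]][idx]
  }, character(ncol(gt)))
  M <- matrix(M, nrow = ncol(gt),
              dimnames = list(colnames(gt), NULL))
  if (is.null(roles)) {
    nm <- tolower(rownames(M))
    roles <- ifelse(grepl("near|sim", nm), "outgroup_near",
                    ifelse(grepl("far|mel", nm), "outgroup_far", "ingroup"))
  }
  haplotype_alignment(chrom = chrom, L = L, positions = pos,
                      alleles = M, roles = roles)
}

#' Read a genetic map TSV
#'
#' @param path TSV with header columns `chrom`, `bp`, `cM`.
#' @return data.frame.
#' @export
read_genetic_map <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("chrom", "bp", "cM") %in% names(m)))
    .stopf("genetic map needs columns chrom, bp, cM")
  m
}

#' Read a repeat BED
#'
#' @param path BED file (`chrom`, `start`, `end`, `class`; 0-based
#'   half-open).
#' @return data.frame.
#' @export
read_repeat_bed <- function(path) {
  b <- utils::read.table(path, header = FALSE, sep = "\t",
                         stringsAsFactors = FALSE)
  names(b)[1:4] <- c("chrom", "start", "end", "class")
  b
}
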