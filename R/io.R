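# Readers and writers for the tab-separated interchange formats, and
# sequence extraction helpers built on the Bioconductor stack
# (Biostrings / rtracklayer) and vcfR.

#' Read an exon table
#'
#' Tab-separated with header; required columns `exon_id`, `gene_id`,
#' `splice_class`, `exon_seq`, `up_flank`, `down_flank`; optional
#' `acceptor_window`, `donor_window`, `acceptor_pos`, `donor_pos`.
#' Malformed rows (bad splice class or non-ACGTN characters) are
#' rejected with their line numbers.
#'
#' @param path file path.
#' @return an [exon_corpus()]; rejected rows in the `rejected_rows`
#'   attribute.
#' @export
read_exon_table <- function(path) {
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = TRUE)
  req <- c("exon_id", "gene_id", "splice_class", "exon_seq",
           "up_flank", "down_flank")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("empty exon table: ", path)
    return(exon_corpus(df))
  }
  ok_class <- c("constitutive", "alt_cassette", "alt_3ss", "alt_5ss",
                "pseudo")
  bad <- !df$splice_class %in% ok_class
  for (col in c("exon_seq", "up_flank", "down_flank"))
    bad <- bad | grepl("[^ACGTN]", toupper(df[[col]]))
  if (any(bad)) {
    warning("rejected ", sum(bad), " malformed row(s) at line(s): ",
            paste(utils::head(which(bad) + 1L, 10), collapse = ", "))
    rejected <- df[bad, , drop = FALSE]
    df <- df[!bad, , drop = FALSE]
    out <- exon_corpus(df)
    attr(out, "rejected_rows") <- rejected
    return(out)
  }
  for (col in c("acceptor_pos", "donor_pos"))
    if (!is.null(df[[col]])) df[[col]] <- as.numeric(df[[col]])
  exon_corpus(df)
}

#' Write an exon table
#'
#' @param corpus an [exon_corpus()].
#' @param path output path (tab-separated, header).
#' @export
write_exon_table <- function(corpus, path) {
  utils::write.table(as.data.frame(unclass(corpus)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write scan results as a tab-separated table
#'
#' @param fit a `bbcooc` fit.
#' @param path output path.
#' @param all write all `4^(2k)` pairs instead of the significant
#'   ones only.
#' @export
write_scan_table <- function(fit, path, all = FALSE) {
  utils::write.table(as.data.frame(fit, all = all), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a scan result table written by [write_scan_table()]
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_scan_table <- function(path) {
  utils::read.delim(path, colClasses = c(motif_u = "character",
                                         motif_d = "character"))
}

#' Read a hexamer set file (one 6-mer per line)
#'
#' @param path file path.
#' @param label set label.
#' @return a [hexamer_set()].
#' @export
read_hexamers <- function(path, label = "custom") {
  hexamer_set(readLines(path), label)
}

#' Read an ortholog flank table
#'
#' Tab-separated `exon_id`, `up_flank`, `down_flank`.
#' @param path file path.
#' @return data.frame.
#' @export
read_orthologs <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  stopifnot(all(c("exon_id", "up_flank", "down_flank") %in% names(df)))
  df
}

#' Read a SNP position table
#'
#' Tab-separated `exon_id`, `side` (`up`/`down`), `pos` (1-based
#' flank position).
#' @param path file path.
#' @return data.frame.
#' @export
read_snp_table <- function(path) {
  df <- utils::read.delim(path)
  stopifnot(all(c("exon_id", "side", "pos") %in% names(df)))
  df
}

#' Read a genes x tissues expression matrix
#'
#' Tab-separated, genes as rows (first column = gene id), tissues as
#' columns.  Rows with missing values are dropped and logged.
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  bad <- apply(m, 1L, anyNA)
  if (any(bad)) {
    warning(sum(bad), " gene(s) with missing values dropped")
    m <- m[!bad, , drop = FALSE]
  }
  m
}

#' Read a reporter measurement table
#'
#' Tab-separated `construct`, `replicate`, `included_molar`,
#' `skipped_molar`; see [synergy_from_measurements()].
#' @param path file path.
#' @return data.frame.
#' @export
read_reporter <- function(path) {
  df <- utils::read.delim(path)
  stopifnot(all(c("construct", "replicate", "included_molar",
                  "skipped_molar") %in% names(df)))
  df
}

#' Extract exon and flank sequences from a genome FASTA and BED
#' intervals
#'
#' BED6 intervals (0-based half-open, strand-aware) name the exons;
#' the exon sequence plus `flank_length` nt on each side are
#' extracted and minus-strand features are reverse-complemented, so
#' all output is in transcript orientation (`up_flank` ends at intron
#' position -1).
#'
#' @param genome_fasta FASTA file of the genome/contigs.
#' @param intervals_bed BED6 file (name column = exon_id; a
#'   `gene:exon` name is split on `:` into gene_id and exon_id).
#' @param flank_length nt of intron to extract per side.
#' @param splice_class class label to assign.
#' @return an [exon_corpus()].
#' @export
extract_flanks <- function(genome_fasta, intervals_bed,
                           flank_length = 100L,
                           splice_class = "constitutive") {
  for (pkg in c("Biostrings", "rtracklayer"))
    if (!requireNamespace(pkg, quietly = TRUE))
      stop("extract_flanks() needs the ", pkg, " package")
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- rtracklayer::import(intervals_bed, format = "BED")
  chr <- as.character(GenomicRanges::seqnames(gr))
  start <- GenomicRanges::start(gr)   # 1-based inclusive after import
  end <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!chr %in% names(genome)))
    stop("interval on unknown contig: ",
         paste(unique(setdiff(chr, names(genome))), collapse = ", "))
  clen <- Biostrings::width(genome)[match(chr, names(genome))]
  if (any(start - flank_length < 1L | end + flank_length > clen))
    stop("interval with flank extends beyond contig end")
  getseq <- function(from, to)
    as.character(Biostrings::subseq(genome[chr], from, to))
  exon <- getseq(start, end)
  left <- getseq(start - flank_length, start - 1L)
  right <- getseq(end + 1L, end + flank_length)
  minus <- strand == "-"
  up <- ifelse(minus, revcomp(right), left)
  dn <- ifelse(minus, revcomp(left), right)
  exon[minus] <- revcomp(exon[minus])
  nm <- gr$name
  if (is.null(nm)) nm <- sprintf("exon%05d", seq_along(exon))
  has_gene <- grepl(":", nm, fixed = TRUE)
  gene <- ifelse(has_gene, sub(":.*$", "", nm), nm)
  exid <- ifelse(has_gene, sub("^[^:]*:", "", nm), nm)
  exon_corpus(data.frame(exon_id = exid, gene_id = gene,
                         splice_class = splice_class, exon_seq = exon,
                         up_flank = up, down_flank = dn))
}

#' Map VCF SNP positions into flank coordinates
#'
#' Reads CHROM/POS from a VCF (everything else is ignored) and
#' intersects the positions with a flank interval table, producing
#' the `exon_id` / `side` / `pos` format [snp_motif_density()]
#' consumes.  `pos` is the 1-based position within the stored flank
#' string (transcript orientation; minus-strand flanks are counted
#' from their far end accordingly).
#'
#' @param vcf_path VCF file.
#' @param flank_intervals data.frame with `exon_id`, `side`
#'   (`up`/`down`), `chrom`, `start`, `end` (1-based inclusive
#'   genomic span of the stored flank), `strand` (`+`/`-`).
#' @return data.frame `exon_id`, `side`, `pos`.
#' @export
snps_from_vcf <- function(vcf_path, flank_intervals) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("snps_from_vcf() needs the vcfR package")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  chrom <- vcfR::getCHROM(v)
  pos <- vcfR::getPOS(v)
  out <- list()
  for (i in seq_len(nrow(flank_intervals))) {
    fi <- flank_intervals[i, ]
    hit <- which(chrom == fi$chrom & pos >= fi$start & pos <= fi$end)
    if (!length(hit)) next
    p <- if (fi$strand == "+") pos[hit] - fi$start + 1L else
      fi$end - pos[hit] + 1L
    out[[length(out) + 1L]] <- data.frame(exon_id = fi$exon_id,
                                          side = fi$side, pos = p)
  }
  if (!length(out))
    return(data.frame(exon_id = character(), side = character(),
                      pos = integer()))
  do.call(rbind, out)
}

#' Read a published motif pair list
#'
#' Tab-separated with columns `motif_u`, `motif_d` and optionally
#' `region_pair` and `splice_set` — the format of a supplementary
#' pair catalogue accompanying a genome-scale scan.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_pair_list <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  stopifnot(all(c("motif_u", "motif_d") %in% names(df)))
  df
}

#' Summary statistics of a motif pair list
#'
#' Counts pairs per region class, perfectly reverse-complementary
#' pairs (`motif_d == revcomp(motif_u)`), and the fraction of
#' distinct motifs containing a CpG dinucleotide.
#'
#' @param pairs data.frame from [read_pair_list()].
#' @return list with `n_pairs`, `by_region` (named vector),
#'   `n_revcomp`, `cpg_motif_fraction`.
#' @export
pair_list_stats <- function(pairs) {
  by_region <- if (!is.null(pairs$region_pair))
    table(pairs$region_pair) else table(character())
  motifs <- unique(c(pairs$motif_u, pairs$motif_d))
  list(n_pairs = nrow(pairs),
       by_region = c(by_region),
       n_revcomp = sum(pairs$motif_d == revcomp(pairs$motif_u)),
       cpg_motif_fraction = mean(grepl("CG", motifs, fixed = TRUE)))
}

#' Expected co-hit count per motif pairing
#'
#' Back-of-envelope power arithmetic for choosing the motif length:
#' with `n_exons` exons and `positions` possible start positions per
#' window, a random ordered pair of k-mers co-hits an exon
#' `n_exons * positions^2 / 4^(2k)` times in expectation (one
#' position pair each side, all `4^(2k)` pairs equally likely).
#' For 80,000 exons and 46 positions this gives about 10 for
#' hexamers and about 161 for pentamers — the basis for scanning
#' pentamer pairs.
#'
#' @param n_exons number of exons.
#' @param positions start positions per window (46 for a 50-nt window
#'   and pentamers).
#' @param k motif length.
#' @return expected co-hit count.
#' @export
expected_pair_hits <- function(n_exons, positions, k) {
  n_exons * positions^2 / 4^(2 * k)
}
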