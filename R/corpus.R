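#' Exon corpus construction and validation
#'
#' An exon corpus is a `data.frame` (class `exon_corpus`) with one row
#' per internal exon.  Required columns:
#' \describe{
#'   \item{exon_id}{unique identifier.}
#'   \item{gene_id}{identifier of the host gene.}
#'   \item{splice_class}{one of `"constitutive"`, `"alt_cassette"`,
#'     `"alt_3ss"`, `"alt_5ss"`, `"pseudo"`.}
#'   \item{exon_seq}{exon sequence, 5'->3' in transcript orientation.}
#'   \item{up_flank}{intron sequence immediately upstream of the 3'
#'     splice site; its last character is intron position -1.}
#'   \item{down_flank}{intron sequence immediately downstream of the 5'
#'     splice site; its first character is intron position +1.}
#' }
#' Optional columns: `acceptor_window` and `donor_window` (splice-site
#' windows used for consensus scoring), and `acceptor_pos` /
#' `donor_pos` (genomic splice-site coordinates enabling alternative
#' splice-site deduplication in [filter_corpus()]).
#'
#' All sequences are stored in transcript orientation; minus-strand
#' features must be reverse-complemented before they enter a corpus
#' (see [extract_flanks()]).  Pseudo exons must never be mixed with
#' real exons in a scan corpus.
#'
#' @param x data.frame with the columns above.
#' @return `x` with class `c("exon_corpus", "data.frame")`.
#' @examples
#' sim <- simulate_corpus(n_exons = 20, seed = 1)
#' corp <- sim$corpus
#' nrow(corp)
#' @export
exon_corpus <- function(x) {
  req <- c("exon_id", "gene_id", "splice_class", "exon_seq",
           "up_flank", "down_flank")
  miss <- setdiff(req, names(x))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$exon_id))
    stop("exon_id values must be unique")
  ok_class <- c("constitutive", "alt_cassette", "alt_3ss", "alt_5ss", "pseudo")
  bad <- !x$splice_class %in% ok_class
  if (any(bad))
    stop("invalid splice_class at row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  for (col in c("exon_seq", "up_flank", "down_flank")) {
    bad <- grepl("[^ACGTN]", toupper(x[[col]]))
    if (any(bad))
      stop("non-ACGTN character in ", col, " at row(s): ",
           paste(utils::head(which(bad), 5), collapse = ", "))
  }
  if ("pseudo" %in% x$splice_class && !all(x$splice_class == "pseudo"))
    stop("pseudo records must not be mixed with real exons in one corpus")
  class(x) <- unique(c("exon_corpus", class(x)))
  x
}

#' Define a scanning window relative to a splice site
#'
#' Coordinates are splice-site relative, both endpoints inclusive.
#' On the upstream side position -1 is the intron base immediately
#' adjacent to the exon (the G of the acceptor AG); on the downstream
#' side +1 is the first intron base after the exon (the G of the donor
#' GT).  The default windows keep clear of the splice-site consensus:
#' upstream windows end at or before -15 (beyond the polypyrimidine
#' tract) and downstream windows start at or after +7.
#'
#' @param name label for the window (e.g. `"Up"`).
#' @param side `"upstream"` or `"downstream"`.
#' @param start_offset,end_offset signed inclusive offsets
#'   (`start_offset < end_offset`; both negative upstream, both
#'   positive downstream).
#' @return object of class `region_spec`.
#' @seealso [region_presets()], [region_pairing()]
#' @export
region_spec <- function(name, side = c("upstream", "downstream"),
                        start_offset, end_offset) {
  side <- match.arg(side)
  stopifnot(is.numeric(start_offset), is.numeric(end_offset),
            start_offset <= end_offset)
  if (side == "upstream" && !(start_offset < 0 && end_offset < 0))
    stop("upstream offsets must be negative")
  if (side == "downstream" && !(start_offset > 0 && end_offset > 0))
    stop("downstream offsets must be positive")
  structure(list(name = name, side = side,
                 start_offset = as.integer(start_offset),
                 end_offset = as.integer(end_offset)),
            class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("<region_spec> %s: %s [%+d, %+d] (%d nt)\n", x$name, x$side,
              x$start_offset, x$end_offset,
              x$end_offset - x$start_offset + 1L))
  invisible(x)
}

#' Default 50-nt scanning windows
#'
#' The four canonical windows: upstream distal Ud = \[-100, -51\],
#' upstream proximal Up = \[-64, -15\] (ending just upstream of the
#' polypyrimidine tract), downstream proximal Dp = \[+7, +56\]
#' (starting just past the donor consensus), downstream distal
#' Dd = \[+51, +100\].
#'
#' @return named list of [region_spec()] objects.
#' @export
region_presets <- function() {
  list(Ud = region_spec("Ud", "upstream",  -100L, -51L),
       Up = region_spec("Up", "upstream",   -64L, -15L),
       Dp = region_spec("Dp", "downstream",  +7L, +56L),
       Dd = region_spec("Dd", "downstream", +51L, +100L))
}

#' Pair one upstream with one downstream window
#'
#' @param upstream upstream [region_spec()], or one of the preset
#'   labels `"UpDp"`, `"UpDd"`, `"UdDp"`, `"UdDd"` (then `downstream`
#'   is ignored).
#' @param downstream downstream [region_spec()].
#' @param label optional label; defaults to the concatenated names.
#' @return object of class `region_pairing`.
#' @export
region_pairing <- function(upstream, downstream = NULL, label = NULL) {
  if (is.character(upstream) && length(upstream) == 1L) {
    presets <- region_presets()
    u <- substr(upstream, 1, 2); d <- substr(upstream, 3, 4)
    if (!u %in% c("Up", "Ud") || !d %in% c("Dp", "Dd"))
      stop("unknown pairing label: ", upstream)
    return(region_pairing(presets[[u]], presets[[d]], upstream))
  }
  stopifnot(inherits(upstream, "region_spec"),
            inherits(downstream, "region_spec"))
  if (upstream$side != "upstream" || downstream$side != "downstream")
    stop("a pairing needs one upstream and one downstream window")
  if (is.null(label)) label <- paste0(upstream$name, downstream$name)
  structure(list(upstream = upstream, downstream = downstream,
                 label = label),
            class = "region_pairing")
}

#' @export
print.region_pairing <- function(x, ...) {
  cat(sprintf("<region_pairing> %s: %s [%+d,%+d] x %s [%+d,%+d]\n",
              x$label,
              x$upstream$name, x$upstream$start_offset, x$upstream$end_offset,
              x$downstream$name, x$downstream$start_offset,
              x$downstream$end_offset))
  invisible(x)
}

#' Extract a scanning window from each exon's flank
#'
#' Maps splice-site-relative offsets onto the stored flank strings.
#' For an upstream flank of length L, position p (negative) is
#' character `L + p + 1`; for a downstream flank, position p is
#' character `p`.
#'
#' @param corpus an [exon_corpus()] (or any data.frame with the flank
#'   columns).
#' @param spec a [region_spec()].
#' @return character vector of window sequences, one per exon, length
#'   `end_offset - start_offset + 1` each.
#' @export
extract_region <- function(corpus, spec) {
  stopifnot(inherits(spec, "region_spec"))
  if (spec$side == "upstream") {
    flank <- corpus$up_flank
    L <- nchar(flank)
    from <- L + spec$start_offset + 1L
    to   <- L + spec$end_offset + 1L
    short <- from < 1L
  } else {
    flank <- corpus$down_flank
    from <- rep(spec$start_offset, length(flank))
    to   <- rep(spec$end_offset, length(flank))
    short <- nchar(flank) < spec$end_offset
  }
  if (any(short))
    stop(sprintf("insufficient flank for region %s [%+d,%+d]: exon(s) %s",
                 spec$name, spec$start_offset, spec$end_offset,
                 paste(utils::head(corpus$exon_id[short], 5),
                       collapse = ", ")))
  substr(flank, from, to)
}

#' GC content of nucleotide sequences
#'
#' `(#G + #C) / (#A + #C + #G + #T)`: ambiguous characters (N) are
#' excluded from both numerator and denominator.  Windows used for
#' scanning are expected to be N-free; an all-N sequence yields `NaN`.
#'
#' @param seq character vector of sequences.
#' @return numeric vector of fractions in \[0, 1\].
#' @export
gc_content <- function(seq) {
  if (length(seq) == 0L || any(!nzchar(seq)))
    stop("empty sequence")
  up <- toupper(seq)
  gc <- nchar(gsub("[^GC]", "", up))
  acgt <- nchar(gsub("[^ACGT]", "", up))
  gc / acgt
}
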