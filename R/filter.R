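#' Filter an exon corpus before co-occurrence scanning
#'
#' Applies, in order:
#' \enumerate{
#'   \item \strong{Alternative splice-site deduplication}: among
#'     alternative 3' (resp. 5') splice-site exons of the same gene
#'     that share the opposite splice site and whose alternative sites
#'     lie within 50 nt of each other, one exon is kept, chosen by
#'     seeded RNG.  Requires the optional `acceptor_pos` / `donor_pos`
#'     columns; skipped (and noted) when absent.
#'   \item \strong{Similarity purge}: for the configured region
#'     pairing, any two exons whose upstream windows and downstream
#'     windows are each similar are \emph{both} removed.  Two windows
#'     are similar when the Jaccard index of their k-mer sets
#'     (`sim_k`-mers, default 11) is at least `sim_threshold`
#'     (default 0.8).  An inverted k-mer index restricts the
#'     quadratic comparison to window pairs sharing at least one
#'     k-mer on both sides.
#'   \item \strong{GC extremes}: exons whose upstream or downstream
#'     window GC is below `gc_min` (default 0.20) or above `gc_max`
#'     (default 0.80) are removed; windows containing ambiguous bases
#'     are removed too (`rule = "ambiguous"`).
#' }
#' Filtering is idempotent: running it on its own output changes
#' nothing.
#'
#' @param corpus an [exon_corpus()].
#' @param pairing the [region_pairing()] whose windows the similarity
#'   and GC rules inspect (default UpDp).
#' @param seed RNG seed for the random choice among duplicated
#'   alternative sites.
#' @param sim_k,sim_threshold k-mer length and Jaccard threshold of
#'   the similarity contract.
#' @param gc_min,gc_max admissible GC range (exclusive bounds are
#'   rejected: GC < `gc_min` or GC > `gc_max` fails).
#' @return the filtered corpus, with a `rejection_log` attribute: a
#'   data.frame of (`exon_id`, `rule`) for every removed exon.
#' @export
filter_corpus <- function(corpus, pairing = region_pairing("UpDp"),
                          seed = 1L, sim_k = 11L, sim_threshold = 0.8,
                          gc_min = 0.20, gc_max = 0.80) {
  log <- data.frame(exon_id = character(), rule = character())
  note <- character()

  ## (1) alternative splice-site dedup
  if (!is.null(corpus$acceptor_pos) && !is.null(corpus$donor_pos)) {
    rng <- .substream(seed, "altsite_dedup")
    drop <- c(.dedup_alt(corpus, "alt_3ss", rng),
              .dedup_alt(corpus, "alt_5ss", rng))
    if (length(drop)) {
      log <- rbind(log, data.frame(exon_id = corpus$exon_id[drop],
                                   rule = "alt_site_dedup"))
      corpus <- corpus[-drop, , drop = FALSE]
    }
  } else {
    note <- "alt-site dedup skipped: no acceptor_pos/donor_pos columns"
  }

  ## (2) similarity purge on both windows of the pairing: candidate
  ## pairs must share >= 1 k-mer on each side before Jaccard is scored
  up <- extract_region(corpus, pairing$upstream)
  dn <- extract_region(corpus, pairing$downstream)
  sets_u <- .kmer_sets(up, sim_k)
  sets_d <- .kmer_sets(dn, sim_k)
  cand <- merge(.shared_kmer_pairs(sets_u), .shared_kmer_pairs(sets_d))
  both <- if (nrow(cand)) {
    ju <- .jaccard_rows(sets_u, cand)
    jd <- .jaccard_rows(sets_d, cand)
    cand[ju >= sim_threshold & jd >= sim_threshold, , drop = FALSE]
  } else cand
  if (nrow(both)) {
    drop <- sort(unique(c(both$i, both$j)))
    log <- rbind(log, data.frame(exon_id = corpus$exon_id[drop],
                                 rule = "similarity"))
    corpus <- corpus[-drop, , drop = FALSE]
    up <- up[-drop]; dn <- dn[-drop]
  }

  ## (3) GC extremes (and ambiguous windows)
  gcu <- suppressWarnings(.gc_frac_or_na(up))
  gcd <- suppressWarnings(.gc_frac_or_na(dn))
  amb <- is.na(gcu) | is.na(gcd)
  extreme <- !amb & (gcu < gc_min | gcu > gc_max |
                     gcd < gc_min | gcd > gc_max)
  if (any(amb))
    log <- rbind(log, data.frame(exon_id = corpus$exon_id[amb],
                                 rule = "ambiguous"))
  if (any(extreme))
    log <- rbind(log, data.frame(exon_id = corpus$exon_id[extreme],
                                 rule = "gc_extreme"))
  corpus <- corpus[!(amb | extreme), , drop = FALSE]

  attr(corpus, "rejection_log") <- log
  attr(corpus, "filter_notes") <- note
  corpus
}

.gc_frac_or_na <- function(seqs) {
  up <- toupper(seqs)
  acgt <- nchar(gsub("[^ACGT]", "", up))
  out <- nchar(gsub("[^GC]", "", up)) / acgt
  out[acgt < nchar(up)] <- NA_real_
  out
}

# Row indices to drop for one alternative splice-site class.
.dedup_alt <- function(corpus, cls, rng) {
  idx <- which(corpus$splice_class == cls)
  if (!length(idx)) return(integer())
  if (cls == "alt_3ss") {
    anchor <- corpus$donor_pos[idx]; site <- corpus$acceptor_pos[idx]
  } else {
    anchor <- corpus$acceptor_pos[idx]; site <- corpus$donor_pos[idx]
  }
  grp <- paste(corpus$gene_id[idx], anchor)
  drop <- integer()
  for (g in split(seq_along(idx), grp)) {
    if (length(g) < 2L) next
    o <- g[order(site[g])]
    pos <- site[o]
    # chain sites within 50 nt of the previous into one cluster
    cl <- cumsum(c(1L, as.integer(diff(pos) > 50)))
    for (members in split(o, cl)) {
      if (length(members) < 2L) next
      keep <- members[floor(rng$runif(1) * length(members)) + 1L]
      drop <- c(drop, setdiff(members, keep))
    }
  }
  idx[drop]
}

# Per-window unique k-mer code sets.
.kmer_sets <- function(seqs, k) {
  if (!length(seqs) || nchar(seqs[[1L]]) < k)
    return(vector("list", length(seqs)))
  W <- .kmer_codes(seqs, k)
  apply(W, 2L, function(v) unique(v[!is.na(v)]), simplify = FALSE)
}

# Pairs (i < j) of windows sharing at least one k-mer, via an
# inverted index over code values.
.shared_kmer_pairs <- function(sets) {
  empty <- data.frame(i = integer(), j = integer())
  code <- unlist(sets, use.names = FALSE)
  if (!length(code)) return(empty)
  exon <- rep.int(seq_along(sets), lengths(sets))
  o <- order(code, exon)
  code <- code[o]; exon <- exon[o]
  runs <- rle(code)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  multi <- which(runs$lengths >= 2L)
  if (!length(multi)) return(empty)
  cand <- do.call(rbind, lapply(multi, function(r) {
    e <- unique(exon[starts[r]:ends[r]])
    if (length(e) < 2L) return(NULL)
    t(utils::combn(e, 2L))
  }))
  if (is.null(cand) || !nrow(cand)) return(empty)
  unique(data.frame(i = cand[, 1L], j = cand[, 2L]))
}

.jaccard_rows <- function(sets, cand) {
  vapply(seq_len(nrow(cand)), function(r) {
    a <- sets[[cand$i[r]]]; b <- sets[[cand$j[r]]]
    if (!length(a) || !length(b)) return(0)
    inter <- length(intersect(a, b))
    inter / (length(a) + length(b) - inter)
  }, numeric(1))
}
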