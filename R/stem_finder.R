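## stem_finder: discover imperfect complementary "genomic stems" between
## the sense strands of two genes' introns.  A stem is a local alignment
## of an A-intron sense sequence against the reverse complement of a
## B-intron sense sequence: every match column pairs a base of A with
## the complement of a base of B, exactly the geometry of a sense-sense
## DNA stem.

#' Stem search parameters
#'
#' Default scoring mirrors common nucleotide-BLAST defaults (match +2,
#' mismatch -3, gap open 5, gap extend 2); a gap of length L costs
#' `gap_open + L * gap_extend`.  The source protocol names BLAST but no
#' parameter set, so everything here is overridable.
#'
#' @param match_score per-column match score (> 0).
#' @param mismatch_penalty per-column mismatch cost (>= 0, applied
#'   negatively).
#' @param gap_open,gap_extend affine gap costs (>= 0, applied
#'   negatively).
#' @param min_length minimum aligned length in columns (>= 8).
#' @param min_identity minimum fraction of match columns, in (0, 1].
#' @param max_results cap on returned stems.
#' @return an object of class `stem_params`.
#' @export
stem_params <- function(match_score = 2, mismatch_penalty = 3,
                        gap_open = 5, gap_extend = 2,
                        min_length = 20, min_identity = 0.7,
                        max_results = 20) {
  if (min_length < 8) stop("min_length must be >= 8", call. = FALSE)
  if (min_identity <= 0 || min_identity > 1)
    stop("min_identity must be in (0, 1]", call. = FALSE)
  structure(list(match_score = match_score,
                 mismatch_penalty = mismatch_penalty,
                 gap_open = gap_open, gap_extend = gap_extend,
                 min_length = as.integer(min_length),
                 min_identity = min_identity,
                 max_results = as.integer(max_results)),
            class = "stem_params")
}

## map a [s, e) range in sense-space of an intron back to genomic coords
sense_range_to_genomic <- function(intv, s, e) {
  if (intv$strand == "+") {
    interval(intv$contig_id, intv$start + s, intv$start + e, "+")
  } else {
    interval(intv$contig_id, intv$end - e, intv$end - s, "-")
  }
}

#' Find genomic stems between the introns of two genes
#'
#' Runs affine-gap local alignment of each A-intron sense sequence
#' against the reverse complement of each B-intron sense sequence (one
#' best alignment per intron pair), keeps alignments passing the length
#' and identity thresholds, ranks by score (ties: leftmost A window,
#' then leftmost B window), and greedily suppresses stems whose A- or
#' B-window overlaps a higher-scoring stem's window by more than half.
#'
#' @param gene_a,gene_b [gene_model()] objects with at least one intron
#'   each (a gene without introns yields an empty result with a
#'   warning).
#' @param genome named character vector from [read_fasta()].
#' @param params a [stem_params()] object.
#' @return list of `genomic_stem` objects, ranked; each has fields
#'   `window_a`, `window_b` (genomic [interval()]s on the genes' sense
#'   strands), `aligned_length`, `identity`, `score`, `intron_a`,
#'   `intron_b` and a `pairing` data.frame (`base_a`, `base_b`,
#'   `match`) giving for every aligned column the A sense base and the
#'   B sense base it pairs with.
#' @export
find_stems <- function(gene_a, gene_b, genome, params = stem_params()) {
  ia <- introns_of(gene_a); ib <- introns_of(gene_b)
  if (nrow(ia) == 0L || nrow(ib) == 0L) {
    warning("no introns in ", if (nrow(ia) == 0L) gene_a$gene_id else gene_b$gene_id,
            "; no stems searched")
    return(list())
  }
  stems <- list()
  for (i in seq_len(nrow(ia))) {
    iva <- interval(ia$contig_id[i], ia$start[i], ia$end[i], ia$strand[i])
    sa <- sense_sequence(iva, genome)
    for (j in seq_len(nrow(ib))) {
      ivb <- interval(ib$contig_id[j], ib$start[j], ib$end[j], ib$strand[j])
      sb <- sense_sequence(ivb, genome)
      aln <- sw_align_cpp(sa, revcomp(sb),
                          params$match_score, -params$mismatch_penalty,
                          params$gap_open, params$gap_extend)
      if (aln$columns == 0L) next
      identity <- aln$matches / aln$columns
      if (aln$columns < params$min_length || identity < params$min_identity)
        next
      ## the aligned B region is in revcomp(sb) space: map back to sb
      lb <- nchar(sb)
      b_s <- lb - aln$b_end; b_e <- lb - aln$b_start
      win_a <- sense_range_to_genomic(iva, aln$a_start, aln$a_end)
      win_b <- sense_range_to_genomic(ivb, b_s, b_e)
      ca <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
      cb <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
      pairing <- data.frame(
        base_a = ca,
        base_b = ifelse(cb == "-", "-", complement_base(cb)),
        match = ca == cb & ca != "-" & ca != "N")
      stems[[length(stems) + 1L]] <- structure(
        list(window_a = win_a, window_b = win_b,
             intron_a = ia$intron_number[i], intron_b = ib$intron_number[j],
             aligned_length = aln$columns, identity = identity,
             score = aln$score, pairing = pairing,
             aligned_a = aln$aligned_a, aligned_b = aln$aligned_b),
        class = "genomic_stem")
    }
  }
  if (length(stems) == 0L) return(stems)
  ord <- order(-vapply(stems, `[[`, numeric(1), "score"),
               vapply(stems, function(s) s$window_a$start, integer(1)),
               vapply(stems, function(s) s$window_b$start, integer(1)))
  stems <- stems[ord]
  ## greedy suppression of heavily overlapping lower-ranked stems
  ov_frac <- function(x, y) {
    if (x$contig_id != y$contig_id) return(0)
    ov <- min(x$end, y$end) - max(x$start, y$start)
    if (ov <= 0) return(0)
    ov / iv_width(x)
  }
  keep <- list()
  for (s in stems) {
    clash <- any(vapply(keep, function(k)
      ov_frac(s$window_a, k$window_a) > 0.5 ||
        ov_frac(s$window_b, k$window_b) > 0.5, logical(1)))
    if (!clash) keep[[length(keep) + 1L]] <- s
  }
  head(keep, params$max_results)
}

#' @export
print.genomic_stem <- function(x, ...) {
  cat(sprintf("<genomic_stem> score %g, %d cols, identity %.3f\n",
              x$score, x$aligned_length, x$identity))
  cat(sprintf("  A intron %d  %s:%d-%d (%s)\n", x$intron_a,
              x$window_a$contig_id, pos1(x$window_a$start), x$window_a$end,
              x$window_a$strand))
  cat(sprintf("  B intron %d  %s:%d-%d (%s)\n", x$intron_b,
              x$window_b$contig_id, pos1(x$window_b$start), x$window_b$end,
              x$window_b$strand))
  invisible(x)
}

#' Render one stem alignment as text
#'
#' Shows the A sense strand over the reverse complement of the B sense
#' strand with `|` marks at paired (complementary) columns.
#'
#' @param stem a `genomic_stem`.
#' @return character vector of three lines.
#' @export
stem_alignment_text <- function(stem) {
  marks <- paste(ifelse(stem$pairing$match, "|", " "), collapse = "")
  c(paste0("A sense  5'-", stem$aligned_a, "-3'"),
    paste0("            ", marks),
    paste0("B rc     3'-", stem$aligned_b, "-5'"))
}

#' Tabulate or serialise a stem list
#'
#' @param stems list from [find_stems()].
#' @param format `"tsv"` (a data.frame with 1-based inclusive
#'   coordinates) or `"json"` (a JSON string, same fields).
#' @return data.frame or JSON string; zero stems yield a zero-row table
#'   (header only).
#' @export
stem_report <- function(stems, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- data.frame(
    rank = seq_along(stems),
    contig_a = vapply(stems, function(s) s$window_a$contig_id, character(1)),
    start_a = vapply(stems, function(s) pos1(s$window_a$start), integer(1)),
    end_a = vapply(stems, function(s) s$window_a$end, integer(1)),
    intron_a = vapply(stems, `[[`, integer(1), "intron_a"),
    contig_b = vapply(stems, function(s) s$window_b$contig_id, character(1)),
    start_b = vapply(stems, function(s) pos1(s$window_b$start), integer(1)),
    end_b = vapply(stems, function(s) s$window_b$end, integer(1)),
    intron_b = vapply(stems, `[[`, integer(1), "intron_b"),
    aligned_length = vapply(stems, `[[`, integer(1), "aligned_length"),
    identity = vapply(stems, `[[`, numeric(1), "identity"),
    score = vapply(stems, `[[`, numeric(1), "score"))
  if (format == "tsv") df else jsonlite::toJSON(df, digits = NA)
}

#' Export stem windows to BED
#'
#' @param stems list from [find_stems()].
#' @param path output BED file (0-based half-open per the BED standard).
#' @return `path`, invisibly.
#' @export
stems_to_bed <- function(stems, path) {
  rows <- lapply(seq_along(stems), function(k) {
    s <- stems[[k]]
    data.frame(contig_id = c(s$window_a$contig_id, s$window_b$contig_id),
               start = c(s$window_a$start, s$window_b$start),
               end = c(s$window_a$end, s$window_b$end),
               name = sprintf("stem%d_%s", k, c("A", "B")),
               strand = c(s$window_a$strand, s$window_b$strand))
  })
  write_bed(do.call(rbind, rows), path)
}
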