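## chimera_design: two-arm antisense/sense chimeric RNAs whose arms
## hybridise to intronic windows adjacent to a genomic stem, forming a
## three-way junction (stem + two RNA/DNA hybrids); plus pol-III
## expression-cassette inserts.

## sense-space range of a genomic window inside an intron interval
window_in_sense_space <- function(win, intron) {
  if (intron$strand == "+") c(win$start - intron$start, win$end - intron$start)
  else c(intron$end - win$end, intron$end - win$start)
}

## place an arm window adjacent to [s, e) within an intron of length L
place_arm <- function(s, e, L, arm_length, offset, side) {
  if (side == "upstream") c(s - offset - arm_length, s - offset)
  else c(e + offset, e + offset + arm_length)
}

#' Design an antisense chimeric RNA for one genomic stem
#'
#' Each arm targets an intronic window of `arm_length` bases placed at
#' distance `offset` from the stem window, on the configured flank of
#' each gene (in gene-sense orientation).  The sense-orientation
#' precursor is the concatenation of the two target windows' sense
#' sequences (in `arm_order`), and the antisense chimera is its reverse
#' complement, so the chimera restricted to each arm is the exact
#' reverse complement of that arm's target window.
#'
#' Windows must stay inside the stem's intron, contain no `N`, and --
#' as a desk-scale specificity proxy -- each target `arm_length`-mer
#' must occur exactly once in the union of the two contigs (both
#' strands); violations raise a design error naming the gene.
#'
#' @param stem a `genomic_stem` from [find_stems()].
#' @param gene_a,gene_b the [gene_model()]s the stem was found in.
#' @param genome named character vector from [read_fasta()].
#' @param arm_length arm length in nt (default 50).
#' @param offset gap in nt between stem window and arm window
#'   (default 0: arms abut the stem).
#' @param arm_order `"ab"` (gene A arm 5' in the sense precursor,
#'   default) or `"ba"`.
#' @param side_a,side_b flank choice per gene, `"upstream"` (5' of the
#'   stem window in gene orientation) or `"downstream"`.  Defaults put
#'   the arms on opposite flanks (A upstream, B downstream), the
#'   three-way-junction geometry.
#' @param chimera_id identifier for the design.
#' @return an object of class `chimeric_rna` with `orientation =
#'   "antisense"`.
#' @export
design_chimera <- function(stem, gene_a, gene_b, genome,
                           arm_length = 50, offset = 0,
                           arm_order = c("ab", "ba"),
                           side_a = "upstream", side_b = "downstream",
                           chimera_id = "chimera-1") {
  arm_order <- match.arg(arm_order)
  stopifnot(inherits(stem, "genomic_stem"))
  arm_length <- as.integer(arm_length); offset <- as.integer(offset)
  if (arm_length < 1L) stop("arm_length must be positive", call. = FALSE)

  one_arm <- function(gene, win, intron_no, side) {
    intron <- intron_interval(gene, intron_no)
    L <- iv_width(intron)
    se <- window_in_sense_space(win, intron)
    arm <- place_arm(se[1], se[2], L, arm_length, offset, side)
    if (arm[1] < 0L || arm[2] > L) {
      short <- if (arm[1] < 0L) -arm[1] else arm[2] - L
      stop("design error: ", gene$gene_id, " intron ", intron_no,
           " lacks ", short, " nt of intronic flank for a ", arm_length,
           "-nt arm (side ", side, ")", call. = FALSE)
    }
    target <- sense_range_to_genomic(intron, arm[1], arm[2])
    seq <- sense_sequence(target, genome)
    if (grepl("N", seq, fixed = TRUE))
      stop("design error: ", gene$gene_id, " arm window contains N",
           call. = FALSE)
    n_occ <- count_occurrences(seq, genome[c(gene_a$contig_id, gene_b$contig_id)])
    if (n_occ != 1L)
      stop("design error: ", gene$gene_id, " arm ", arm_length,
           "-mer occurs ", n_occ, " times in the two loci (need 1)",
           call. = FALSE)
    list(target = target, seq = seq)
  }

  a <- one_arm(gene_a, stem$window_a, stem$intron_a, side_a)
  b <- one_arm(gene_b, stem$window_b, stem$intron_b, side_b)
  precursor <- if (arm_order == "ab") paste0(a$seq, b$seq) else paste0(b$seq, a$seq)
  structure(list(chimera_id = chimera_id, orientation = "antisense",
                 arm_a_target = a$target, arm_b_target = b$target,
                 arm_length = arm_length, arm_order = arm_order,
                 sequence = revcomp(precursor)),
            class = "chimeric_rna")
}

#' @export
print.chimeric_rna <- function(x, ...) {
  cat(sprintf("<chimeric_rna> %s (%s), 2 x %d nt arms, order '%s'\n",
              x$chimera_id, x$orientation, x$arm_length, x$arm_order))
  cat(sprintf("  arm A -> %s:%d-%d (%s)\n", x$arm_a_target$contig_id,
              pos1(x$arm_a_target$start), x$arm_a_target$end,
              x$arm_a_target$strand))
  cat(sprintf("  arm B -> %s:%d-%d (%s)\n", x$arm_b_target$contig_id,
              pos1(x$arm_b_target$start), x$arm_b_target$end,
              x$arm_b_target$strand))
  cat(sprintf("  5'-%s-3'\n", x$sequence))
  invisible(x)
}

#' Flip a chimera between antisense and sense orientation
#'
#' The two orientations of one design are mutual reverse complements
#' (the single-insert, flipped-promoter construction); target windows
#' are unchanged.
#'
#' @param chimera a `chimeric_rna`.
#' @return the counterpart `chimeric_rna`.
#' @export
sense_counterpart <- function(chimera) {
  stopifnot(inherits(chimera, "chimeric_rna"))
  chimera$orientation <- if (chimera$orientation == "antisense") "sense" else "antisense"
  chimera$sequence <- revcomp(chimera$sequence)
  chimera
}

#' Build a pol-III expression cassette for a chimera
#'
#' Cassette = promoter label + insert + `"TTTTTT"` terminator.  The
#' insert must not contain an internal run of six or more `T` on the
#' transcribed strand (it would truncate the transcript); a first base
#' other than `G`/`A` triggers a warning (weak pol-III initiation), not
#' an error.
#'
#' @param chimera a `chimeric_rna`.
#' @param promoter_label promoter name (default `"U6"`).
#' @return an object of class `expression_cassette` with fields
#'   `promoter_label`, `insert`, `terminator`, `orientation`.
#' @export
build_cassette <- function(chimera, promoter_label = "U6") {
  stopifnot(inherits(chimera, "chimeric_rna"))
  insert <- chimera$sequence
  if (grepl("TTTTTT", insert, fixed = TRUE))
    stop("cassette error: insert contains an internal >=6-T run ",
         "(premature pol-III termination)", call. = FALSE)
  if (!substr(insert, 1, 1) %in% c("G", "A"))
    warning("insert starts with ", substr(insert, 1, 1),
            ": weak pol-III initiation")
  structure(list(promoter_label = promoter_label, insert = insert,
                 terminator = "TTTTTT", orientation = chimera$orientation),
            class = "expression_cassette")
}

#' Transcribed-cassette sequence (insert + terminator)
#'
#' @param cassette an `expression_cassette`.
#' @return nucleotide string.
#' @export
cassette_sequence <- function(cassette) {
  paste0(cassette$insert, cassette$terminator)
}

#' Three-way-junction layout report for a design
#'
#' Verifies that the two RNA/DNA hybrid windows and the stem windows
#' share no genomic bases, and renders a text layout.
#'
#' @param stem a `genomic_stem`.
#' @param chimera the `chimeric_rna` designed on it.
#' @return list with `stem`, `hybrid_a`, `hybrid_b` and a `layout`
#'   character vector.
#' @export
three_way_junction_report <- function(stem, chimera) {
  overlaps <- function(x, y) {
    x$contig_id == y$contig_id && min(x$end, y$end) > max(x$start, y$start)
  }
  parts <- list(stem_a = stem$window_a, stem_b = stem$window_b,
                hybrid_a = chimera$arm_a_target, hybrid_b = chimera$arm_b_target)
  nm <- names(parts)
  for (i in seq_along(parts)) for (j in seq_along(parts)) {
    if (i < j && overlaps(parts[[i]], parts[[j]]))
      stop("three-way junction error: ", nm[i], " overlaps ", nm[j],
           call. = FALSE)
  }
  fmt <- function(iv) sprintf("%s:%d-%d(%s)", iv$contig_id, pos1(iv$start),
                              iv$end, iv$strand)
  layout <- c(
    sprintf("hybrid A  %s  ===[arm %d nt]===", fmt(chimera$arm_a_target),
            chimera$arm_length),
    sprintf("stem      %s  x  %s  (%d cols, id %.2f)", fmt(stem$window_a),
            fmt(stem$window_b), stem$aligned_length, stem$identity),
    stem_alignment_text(stem),
    sprintf("hybrid B  %s  ===[arm %d nt]===", fmt(chimera$arm_b_target),
            chimera$arm_length))
  list(stem = stem, hybrid_a = chimera$arm_a_target,
       hybrid_b = chimera$arm_b_target, layout = layout)
}

#' Batch design over all candidate stems
#'
#' Runs [find_stems()] and designs one antisense/sense pair per
#' surviving stem, in stem rank order.  Per-candidate design errors are
#' logged as warnings and skipped without aborting the batch.
#'
#' @param gene_a,gene_b [gene_model()] objects.
#' @param genome named character vector.
#' @param params a [stem_params()].
#' @param ... design parameters passed to [design_chimera()]
#'   (`arm_length`, `offset`, `arm_order`, `side_a`, `side_b`).
#' @param id_prefix prefix for generated chimera ids.
#' @return list of candidates, each a list with `stem`, `antisense`,
#'   `sense`, `junction` (the [three_way_junction_report()]).
#' @export
design_candidates <- function(gene_a, gene_b, genome,
                              params = stem_params(), ...,
                              id_prefix = "as") {
  stems <- find_stems(gene_a, gene_b, genome, params)
  out <- list()
  for (k in seq_along(stems)) {
    cand <- tryCatch({
      anti <- design_chimera(stems[[k]], gene_a, gene_b, genome, ...,
                             chimera_id = sprintf("%s-%d", id_prefix, k))
      list(stem = stems[[k]], antisense = anti,
           sense = sense_counterpart(anti),
           junction = three_way_junction_report(stems[[k]], anti))
    }, error = function(e) {
      warning("candidate ", k, " skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(cand)) out[[length(out) + 1L]] <- cand
  }
  out
}

#' Tabulate a design batch
#'
#' @param candidates list from [design_candidates()].
#' @return data.frame design sheet (1-based inclusive coordinates).
#' @export
design_sheet <- function(candidates) {
  rows <- lapply(candidates, function(cd) {
    ch <- cd$antisense
    data.frame(chimera_id = ch$chimera_id,
               score = cd$stem$score,
               identity = cd$stem$identity,
               arm_a_contig = ch$arm_a_target$contig_id,
               arm_a_start = pos1(ch$arm_a_target$start),
               arm_a_end = ch$arm_a_target$end,
               arm_b_contig = ch$arm_b_target$contig_id,
               arm_b_start = pos1(ch$arm_b_target$start),
               arm_b_end = ch$arm_b_target$end,
               antisense = ch$sequence,
               sense = cd$sense$sequence)
  })
  if (length(rows) == 0L)
    return(data.frame(chimera_id = character(0), score = numeric(0),
                      identity = numeric(0), arm_a_contig = character(0),
                      arm_a_start = integer(0), arm_a_end = integer(0),
                      arm_b_contig = character(0), arm_b_start = integer(0),
                      arm_b_end = integer(0), antisense = character(0),
                      sense = character(0)))
  do.call(rbind, rows)
}
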