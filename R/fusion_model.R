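## fusion_model: the rearranged fusion allele, its spliced fusion
## transcript, and the inverse problem -- inferring breakpoints,
## microhomology and untemplated insertions from junction-spanning
## sequence.
##
## Breakpoints live in "sense space": 0-based positions along the
## contig read 5'->3' on the gene's sense strand (identical to contig
## coordinates for plus-strand genes).  breakpoint_a is the LAST
## retained base of gene A, breakpoint_b the FIRST retained base of
## gene B.

#' Construct a fusion event
#'
#' Insertion and microhomology are mutually exclusive junction features
#' by convention: a non-empty insertion forces
#' `microhomology_length = 0`.
#'
#' @param event_id short label (the classic examples are "x" and "y").
#' @param gene_a_id,gene_b_id parental gene ids (A upstream, B
#'   downstream).
#' @param breakpoint_a 0-based sense-space position of the last
#'   retained base of gene A.
#' @param breakpoint_b 0-based sense-space position of the first
#'   retained base of gene B.
#' @param insertion untemplated bases at the junction (possibly "").
#' @param microhomology_length nt of junction sequence shared by both
#'   parental loci (placement ambiguity span).
#' @return an object of class `fusion_event`.
#' @export
fusion_event <- function(event_id, gene_a_id, gene_b_id,
                         breakpoint_a, breakpoint_b,
                         insertion = "", microhomology_length = 0L) {
  assert_dna(insertion, "insertion")
  if (nzchar(insertion) && microhomology_length != 0L)
    stop("insertion and microhomology are mutually exclusive", call. = FALSE)
  structure(list(event_id = event_id,
                 gene_a_id = gene_a_id, gene_b_id = gene_b_id,
                 breakpoint_a = as.integer(breakpoint_a),
                 breakpoint_b = as.integer(breakpoint_b),
                 insertion = insertion,
                 microhomology_length = as.integer(microhomology_length)),
            class = "fusion_event")
}

#' @export
print.fusion_event <- function(x, ...) {
  cat(sprintf("<fusion_event> '%s'  %s|%s  bpA=%d bpB=%d (1-based %d/%d)",
              x$event_id, x$gene_a_id, x$gene_b_id,
              x$breakpoint_a, x$breakpoint_b,
              pos1(x$breakpoint_a), pos1(x$breakpoint_b)))
  if (nzchar(x$insertion)) cat(sprintf("  ins '%s'", x$insertion))
  if (x$microhomology_length > 0)
    cat(sprintf("  microhomology %d nt", x$microhomology_length))
  cat("\n")
  invisible(x)
}

## which intron (if any) contains sense-space position p?  Returns the
## intron number or NA.  `exons` are sense-space exon coordinates.
intron_containing <- function(p, exons) {
  n <- nrow(exons)
  if (n < 2L) return(NA_integer_)
  for (k in seq_len(n - 1L)) {
    if (p >= exons$end[k] && p < exons$start[k + 1L]) return(k)
  }
  NA_integer_
}

#' Build the rearranged fusion allele
#'
#' The allele sequence is `senseA[0..breakpoint_a] + insertion +
#' senseB[breakpoint_b..]`.  Both breakpoints must be intronic (the
#' modeled class): an exonic breakpoint is an error, so exons are never
#' partially retained.  The lifted annotation keeps the upstream exons
#' of gene A and the downstream exons of gene B, and records the new
#' intron spanning from the end of the last retained A exon to the
#' start of the first retained B exon.
#'
#' @param genome named character vector.
#' @param gene_a,gene_b [gene_model()] objects.
#' @param event a [fusion_event()].
#' @return an object of class `fusion_allele` with fields `sequence`,
#'   `exons` (allele-coordinate data.frame with `gene`, `exon_number`,
#'   `start`, `end`), `new_intron` (allele-coordinate [interval()]),
#'   `junction_start` (allele position where parental A sequence ends),
#'   and `event`.
#' @export
make_fusion_allele <- function(genome, gene_a, gene_b, event) {
  stopifnot(inherits(event, "fusion_event"))
  ssa <- gene_sense_space(gene_a, genome)
  ssb <- gene_sense_space(gene_b, genome)
  bpA <- event$breakpoint_a; bpB <- event$breakpoint_b
  if (bpA < 0L || bpA >= ssa$length || bpB < 0L || bpB >= ssb$length)
    stop("breakpoint outside contig bounds", call. = FALSE)
  ka <- intron_containing(bpA, ssa$exons)
  kb <- intron_containing(bpB, ssb$exons)
  if (is.na(ka))
    stop("breakpoint_a (", bpA, ") is not intronic in ", gene_a$gene_id,
         call. = FALSE)
  if (is.na(kb))
    stop("breakpoint_b (", bpB, ") is not intronic in ", gene_b$gene_id,
         call. = FALSE)
  seq_a <- subseq0(ssa$seq, 0L, bpA + 1L)
  seq_b <- subseq0(ssb$seq, bpB, ssb$length)
  allele_seq <- paste0(seq_a, event$insertion, seq_b)
  shift_b <- (bpA + 1L) + nchar(event$insertion) - bpB
  ea <- ssa$exons[ssa$exons$end <= bpA + 1L, , drop = FALSE]
  eb <- ssb$exons[ssb$exons$start >= bpB, , drop = FALSE]
  exons <- rbind(
    data.frame(gene = gene_a$gene_id, exon_number = ea$exon_number,
               start = ea$start, end = ea$end),
    data.frame(gene = gene_b$gene_id, exon_number = eb$exon_number,
               start = eb$start + shift_b, end = eb$end + shift_b))
  rownames(exons) <- NULL
  new_intron <- NULL
  if (nrow(ea) > 0L && nrow(eb) > 0L) {
    new_intron <- interval("fusion", max(ea$end),
                           min(eb$start) + shift_b, "+")
  }
  structure(list(sequence = allele_seq, exons = exons,
                 new_intron = new_intron,
                 junction_start = bpA + 1L,
                 gene_a_id = gene_a$gene_id, gene_b_id = gene_b$gene_id,
                 event = event),
            class = "fusion_allele")
}

#' @export
print.fusion_allele <- function(x, ...) {
  na <- sum(x$exons$gene == x$gene_a_id)
  nb <- sum(x$exons$gene == x$gene_b_id)
  cat(sprintf("<fusion_allele> '%s'  %d nt, %d + %d retained exons\n",
              x$event$event_id, nchar(x$sequence), na, nb))
  invisible(x)
}

#' Splice the fusion allele into its mature fusion transcript
#'
#' Removes all native introns and the new intron; the fusion junction
#' joins the last retained exon of gene A to the first retained exon of
#' gene B at their annotated boundaries.
#'
#' @param allele a [make_fusion_allele()] result.
#' @return an object of class `fusion_transcript` with fields
#'   `exon_list` (data.frame: `gene`, `exon_number`, `start`, `end` on
#'   the mature sequence), `junction` (named vector: last A exon
#'   number, first B exon number), `junction_pos` (0-based mature
#'   position where gene B sequence starts) and `mature_sequence`.
#' @export
splice_fusion_transcript <- function(allele) {
  stopifnot(inherits(allele, "fusion_allele"))
  ea <- allele$exons[allele$exons$gene == allele$gene_a_id, , drop = FALSE]
  eb <- allele$exons[allele$exons$gene == allele$gene_b_id, , drop = FALSE]
  if (nrow(ea) == 0L || nrow(eb) == 0L)
    stop("no retained exon on ", if (nrow(ea) == 0L) "the upstream" else
         "the downstream", " side; cannot splice", call. = FALSE)
  exs <- allele$exons
  pieces <- vapply(seq_len(nrow(exs)), function(k)
    subseq0(allele$sequence, exs$start[k], exs$end[k]), character(1))
  w <- exs$end - exs$start
  ends <- cumsum(w)
  exon_list <- data.frame(gene = exs$gene, exon_number = exs$exon_number,
                          start = ends - w, end = ends)
  structure(list(exon_list = exon_list,
                 junction = c(a = max(ea$exon_number), b = min(eb$exon_number)),
                 junction_pos = sum(w[exs$gene == allele$gene_a_id]),
                 mature_sequence = paste(pieces, collapse = "")),
            class = "fusion_transcript")
}

#' @export
print.fusion_transcript <- function(x, ...) {
  cat(sprintf("<fusion_transcript> %d nt, junction exon %d -> exon %d\n",
              nchar(x$mature_sequence), x$junction["a"], x$junction["b"]))
  invisible(x)
}

#' Mature mRNA of a wild-type gene
#'
#' Concatenation of the exon sense sequences in gene order; useful as
#' the non-fusion control template for in-silico RT-PCR.
#'
#' @param gene a [gene_model()].
#' @param genome named character vector.
#' @return nucleotide string.
#' @export
mature_mrna <- function(gene, genome) {
  pieces <- vapply(seq_len(nrow(gene$exons)), function(k) {
    sense_sequence(interval(gene$contig_id, gene$exons$start[k],
                            gene$exons$end[k], gene$strand), genome)
  }, character(1))
  paste(pieces, collapse = "")
}

## Anchor the read's first `anchor` bases in `ref` (exact match) and
## return the diagonal: the 0-based ref position of read character 1.
## Multiple anchor hits are resolved by maximal exact extension
## (tie: leftmost).  NULL when the anchor is absent.
anchor_prefix <- function(read, ref, anchor) {
  L <- nchar(read)
  if (L < anchor) return(NULL)
  occ <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(substr(read, 1L, anchor)),
    Biostrings::DNAString(ref))) - 1L
  if (length(occ) == 0L) return(NULL)
  if (length(occ) == 1L) return(occ[1])
  nref <- nchar(ref)
  ext <- vapply(occ, function(p) {
    i <- anchor
    while (i < L && p + i < nref &&
           substr(read, i + 1L, i + 1L) == substr(ref, p + i + 1L, p + i + 1L))
      i <- i + 1L
    i
  }, numeric(1))
  occ[which.max(ext)]
}

## per-position mismatch indicator of the read against `ref` along a
## fixed diagonal (`diag` = ref pos of read char 1); positions falling
## outside the reference are NA
diag_mismatch <- function(rv, ref_v, diag) {
  L <- length(rv)
  idx <- diag + seq_len(L)             # 1-based ref indices
  ok <- idx >= 1L & idx <= length(ref_v)
  mm <- rep(NA, L)
  mm[ok] <- as.integer(rv[ok] != ref_v[idx[ok]] |
                         rv[ok] == "N" | ref_v[idx[ok]] == "N")
  mm
}

#' Infer a fusion event from a junction-spanning read
#'
#' Anchors the read's first `anchor` bases in `sense_a` and its last
#' `anchor` bases in `sense_b` (exact match; multiple hits resolved by
#' maximal extension), which fixes one alignment diagonal per side.
#' Every split of the read into an A-prefix, an optional unaligned
#' middle (untemplated insertion, up to `max_insertion` nt) and a
#' B-suffix is then scored by its total mismatch count along those
#' diagonals, and the split maximizing the matched bases (minimizing
#' mismatches; ties prefer no/shorter insertion) is chosen -- exactly
#' the exhaustive split criterion, but tolerant of sequencing errors at
#' roughly `mismatch_rate` (Sanger-quality default 1 per 100 bases,
#' used to flag low-confidence calls).  When the junction placement is
#' ambiguous (a plateau of equally good splits), the shared bases are
#' canonically assigned to gene A, the plateau width is reported as
#' microhomology, and the ambiguity window is returned alongside.
#'
#' @param junction_read nucleotide string spanning the junction.
#' @param sense_a,sense_b parental sense-space sequences.
#' @param anchor minimum anchored bases per side (default 20); reads
#'   failing to anchor on either side yield an `"unmappable"` result,
#'   not an exception.
#' @param mismatch_rate tolerated mismatches per base; a best split
#'   with more mismatches than `ceiling(mismatch_rate * nchar(read))`
#'   is flagged `low_confidence = TRUE` rather than rejected.
#' @param max_insertion longest untemplated insertion considered.
#' @return an object of class `fusion_inference`: list with `status`
#'   (`"ok"` or `"unmappable"`), `event` (a [fusion_event()] or
#'   `NULL`), `ambiguity` (0-based inclusive range of equally valid
#'   `breakpoint_a` placements), `mismatches`, `low_confidence`.
#' @export
infer_breakpoint <- function(junction_read, sense_a, sense_b,
                             anchor = 20L, mismatch_rate = 0.01,
                             max_insertion = 30L) {
  assert_dna(junction_read, "junction_read")
  L <- nchar(junction_read)
  unmappable <- structure(list(status = "unmappable", event = NULL,
                               ambiguity = NULL, mismatches = NA_integer_,
                               low_confidence = NA),
                          class = "fusion_inference")
  if (L < 2L * anchor) return(unmappable)
  dA <- anchor_prefix(junction_read, sense_a, anchor)
  rcL <- anchor_prefix(revcomp(junction_read), revcomp(sense_b), anchor)
  if (is.null(dA) || is.null(rcL)) return(unmappable)
  ## diagonal offset for B: B position of read char r is qoff + r (0-based)
  qend <- nchar(sense_b) - 1L - rcL     # B pos of read char L
  qoff <- qend - L
  rv <- strsplit(junction_read, "", fixed = TRUE)[[1]]
  av <- strsplit(sense_a, "", fixed = TRUE)[[1]]
  bv <- strsplit(sense_b, "", fixed = TRUE)[[1]]
  mmA <- diag_mismatch(rv, av, dA)
  mmB <- diag_mismatch(rv, bv, qoff + 1L)
  cumA <- cumsum(ifelse(is.na(mmA), 1e6, mmA))     # mismatches in read[1..i]
  sufB <- rev(cumsum(rev(ifelse(is.na(mmB), 1e6, mmB)))) # in read[j..L]
  sufB <- c(sufB, 0)                                # j = L + 1 -> empty suffix
  best <- NULL
  for (g in 0:max_insertion) {
    i <- seq.int(anchor, L - anchor - g)            # split: A ends at read i
    if (length(i) == 0L || i[1] > i[length(i)]) break
    cost <- cumA[i] + sufB[i + g + 1L]
    m <- min(cost)
    if (is.null(best) || m < best$cost) {
      cand <- i[cost == m]
      best <- list(cost = m, g = g, i = max(cand),
                   plateau = if (g == 0L) cand else integer(0))
    }
  }
  if (is.null(best) || best$cost >= 1e6) return(unmappable)
  i <- best$i; g <- best$g
  bpA <- dA + i - 1L
  bpB <- qoff + i + g + 1L
  if (g == 0L) {
    ## contiguous equal-cost plateau containing i = microhomology window
    run <- best$plateau
    lo <- i
    while ((lo - 1L) %in% run) lo <- lo - 1L
    h <- i - lo
    ev <- fusion_event("inferred", "gene_a", "gene_b", bpA, bpB,
                       insertion = "", microhomology_length = h)
    amb <- c(bpA - h, bpA)
  } else {
    ev <- fusion_event("inferred", "gene_a", "gene_b", bpA, bpB,
                       insertion = substr(junction_read, i + 1L, i + g),
                       microhomology_length = 0L)
    amb <- c(bpA, bpA)
  }
  structure(list(status = "ok", event = ev, ambiguity = amb,
                 mismatches = as.integer(best$cost),
                 low_confidence = best$cost > ceiling(mismatch_rate * L)),
            class = "fusion_inference")
}

#' @export
print.fusion_inference <- function(x, ...) {
  if (x$status != "ok") {
    cat("<fusion_inference> unmappable junction\n")
  } else {
    cat(sprintf(
      "<fusion_inference> bpA=%d bpB=%d ins='%s' microhomology=%d (A window %d-%d, %d mismatch%s)%s\n",
      x$event$breakpoint_a, x$event$breakpoint_b, x$event$insertion,
      x$event$microhomology_length, x$ambiguity[1], x$ambiguity[2],
      x$mismatches, if (x$mismatches == 1L) "" else "es",
      if (isTRUE(x$low_confidence)) "  [low confidence]" else ""))
  }
  invisible(x)
}

#' Microhomology at a fusion junction
#'
#' Longest run of bases immediately flanking the junction that is
#' identical in both parental sequences: the maximal `k` such that the
#' junction placement is ambiguous over `k + 1` positions (left-shift
#' plus right-shift extents combined).
#'
#' @param event a [fusion_event()].
#' @param sense_a,sense_b parental sense-space sequences.
#' @return integer nt count (0 when the flanks share nothing).
#' @export
microhomology_at <- function(event, sense_a, sense_b) {
  bpA <- event$breakpoint_a; bpB <- event$breakpoint_b
  LA <- nchar(sense_a); LB <- nchar(sense_b)
  ch <- function(s, p) substr(s, p + 1L, p + 1L)  # 0-based accessor
  r <- 0L
  while (bpA + 1L + r < LA && bpB + r < LB) {
    x <- ch(sense_a, bpA + 1L + r)
    if (x == "N" || x != ch(sense_b, bpB + r)) break
    r <- r + 1L
  }
  l <- 0L
  while (bpA - l >= 0L && bpB - 1L - l >= 0L) {
    x <- ch(sense_a, bpA - l)
    if (x == "N" || x != ch(sense_b, bpB - 1L - l)) break
    l <- l + 1L
  }
  l + r
}

#' Report fusion events as a table
#'
#' Coordinates are converted to 1-based single positions.  Because the
#' literature does not fix whether a printed breakpoint means the last
#' retained or the first lost base, the conversion is parameterised.
#'
#' @param events list of [fusion_event()] objects.
#' @param gene_a,gene_b [gene_model()]s supplying contig names.
#' @param convention `"last_retained"` (default) or `"first_lost"`.
#' @return data.frame, BEDPE-style (two loci plus insertion /
#'   microhomology columns).
#' @export
fusion_event_table <- function(events, gene_a, gene_b,
                               convention = c("last_retained", "first_lost")) {
  convention <- match.arg(convention)
  off_a <- if (convention == "last_retained") 1L else 2L
  off_b <- if (convention == "last_retained") 1L else 0L
  do.call(rbind, lapply(events, function(ev) {
    data.frame(event_id = ev$event_id,
               contig_a = gene_a$contig_id,
               pos_a = ev$breakpoint_a + off_a,
               contig_b = gene_b$contig_id,
               pos_b = ev$breakpoint_b + off_b,
               insertion = ev$insertion,
               microhomology = ev$microhomology_length)
  }))
}

#' Serialise fusion events to JSON
#'
#' @param events list of [fusion_event()] objects.
#' @param path optional output file; if `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
fusion_events_to_json <- function(events, path = NULL) {
  x <- lapply(events, unclass)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
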