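## synthetic_data: deterministic generator of two-gene fixture genomes
## with planted stems, fusion events and junction reads.  Identical
## spec + seed gives byte-identical output, so every pipeline stage can
## be tested against a known truth record with no external downloads.

#' Construct a synthetic two-gene genome specification
#'
#' Describes two genes on separate contigs (emulating an
#' inter-chromosomal pair), a planted imperfect complementary stem
#' between one intron of each gene, and planted fusion events with
#' configurable junction micro-features.
#'
#' @param seed integer RNG seed; the whole generation is a pure
#'   function of (spec, seed).
#' @param gene_a,gene_b lists with `id`, `exon_lengths` (nt) and
#'   `intron_lengths` (nt, one fewer than exons).
#' @param gc_content background GC fraction (default 0.42, human-like).
#' @param flank nt of intergenic sequence on each side of each gene.
#' @param stem list `(intron_a, intron_b, length, mismatches,
#'   offset_a, offset_b)`: the reverse complement of the A-intron
#'   window is copied into the B intron with `mismatches` substitutions.
#' @param events list of event descriptions: `(id, intron_a, offset_a,
#'   intron_b, offset_b, insertion, microhomology)`; offsets are
#'   0-based within the intron (`offset_a` = last retained base of A,
#'   `offset_b` = first retained base of B).
#' @param read_length junction-read length (default 600, Sanger-like).
#' @param read_error per-base substitution error rate for reads.
#' @param n_reads junction reads per event.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           gene_a = list(id = "geneA",
                                         exon_lengths = c(150, 150, 150),
                                         intron_lengths = c(500, 500)),
                           gene_b = list(id = "geneB",
                                         exon_lengths = c(150, 150, 150),
                                         intron_lengths = c(500, 500)),
                           gc_content = 0.42, flank = 400L,
                           stem = list(intron_a = 1L, intron_b = 1L,
                                       length = 40L, mismatches = 4L,
                                       offset_a = 50L, offset_b = 50L),
                           events = list(), read_length = 600L,
                           read_error = 0, n_reads = 3L) {
  spec <- structure(list(seed = as.integer(seed), gene_a = gene_a,
                         gene_b = gene_b, gc_content = gc_content,
                         flank = as.integer(flank), stem = stem,
                         events = events,
                         read_length = as.integer(read_length),
                         read_error = read_error,
                         n_reads = as.integer(n_reads)),
                    class = "synthetic_spec")
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  bad <- function(field, why)
    stop("synthetic spec error in '", field, "': ", why, call. = FALSE)
  for (g in c("gene_a", "gene_b")) {
    gg <- spec[[g]]
    if (any(gg$exon_lengths <= 0)) bad(g, "non-positive exon length")
    if (length(gg$intron_lengths) != length(gg$exon_lengths) - 1L)
      bad(g, "need one intron length per exon gap")
    if (length(gg$intron_lengths) > 0 && any(gg$intron_lengths <= 0))
      bad(g, "non-positive intron length")
  }
  st <- spec$stem
  if (!is.null(st)) {
    la <- spec$gene_a$intron_lengths; lb <- spec$gene_b$intron_lengths
    if (st$intron_a > length(la)) bad("stem", "intron_a index out of range")
    if (st$intron_b > length(lb)) bad("stem", "intron_b index out of range")
    if (st$offset_a + st$length > la[st$intron_a])
      bad("stem", "window does not fit in gene A intron")
    if (st$offset_b + st$length > lb[st$intron_b])
      bad("stem", "window does not fit in gene B intron")
    if (st$mismatches > st$length - 6L)
      bad("stem", "too many mismatches for the stem length")
  }
  for (ev in spec$events) {
    la <- spec$gene_a$intron_lengths; lb <- spec$gene_b$intron_lengths
    if (ev$intron_a > length(la) || ev$offset_a >= la[ev$intron_a])
      bad("events", paste0("event '", ev$id, "' breakpoint_a outside intron"))
    if (ev$intron_b > length(lb) || ev$offset_b >= lb[ev$intron_b])
      bad("events", paste0("event '", ev$id, "' breakpoint_b outside intron"))
    mh <- if (is.null(ev$microhomology)) 0L else ev$microhomology
    if (mh > 0L && ev$offset_b < mh + 1L)
      bad("events", paste0("event '", ev$id,
                           "' microhomology does not fit before breakpoint_b"))
    ins <- if (is.null(ev$insertion)) "" else ev$insertion
    if (nzchar(ins) && mh > 0L)
      bad("events", paste0("event '", ev$id,
                           "' insertion and microhomology are exclusive"))
  }
  invisible(spec)
}

#' JAZF1/SUZ12-like synthetic preset
#'
#' A 5-exon gene A with a very large intron 3 and a 16-exon gene B with
#' a small intron 1, reproducing the ~54 kb vs ~2.7 kb intron-size
#' asymmetry of the emulated locus pair at a configurable scale
#' (`intron 3 of A = round(54000 * scale)`, `intron 1 of B =
#' round(2700 * scale)`; other introns are scaled with a 100 nt floor).
#' Two fusion events are planted in those introns: "x" with a clean
#' junction and "y" carrying an untemplated `"AA"` insertion.
#'
#' @param name preset name; only `"jazf1-suz12-like"` is defined.
#' @param scale intron scale factor in (0, 1].
#' @param seed RNG seed.
#' @return a [synthetic_spec()].
#' @export
fusion_preset <- function(name = "jazf1-suz12-like", scale = 1, seed = 42L) {
  name <- match.arg(name, "jazf1-suz12-like")
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]", call. = FALSE)
  ia <- pmax(round(c(5200, 3800, 54000, 4600) * scale), 100L)
  ia[3] <- round(54000 * scale)
  ib <- pmax(round(c(2700, rep(700, 14)) * scale), 100L)
  ib[1] <- round(2700 * scale)
  la3 <- ia[3]; lb1 <- ib[1]
  synthetic_spec(
    seed = seed,
    gene_a = list(id = "geneA",
                  exon_lengths = c(155, 128, 203, 141, 266),
                  intron_lengths = ia),
    gene_b = list(id = "geneB",
                  exon_lengths = c(170, 96, 134, 120, 158, 101, 149, 127,
                                   133, 112, 140, 118, 126, 109, 131, 204),
                  intron_lengths = ib),
    stem = list(intron_a = 3L, intron_b = 1L, length = 40L, mismatches = 4L,
                offset_a = floor(0.30 * la3), offset_b = max(5L, floor(0.06 * lb1))),
    events = list(
      list(id = "x", intron_a = 3L, offset_a = floor(0.55 * la3),
           intron_b = 1L, offset_b = floor(0.65 * lb1),
           insertion = "", microhomology = 0L),
      list(id = "y", intron_a = 3L, offset_a = floor(0.75 * la3),
           intron_b = 1L, offset_b = floor(0.45 * lb1),
           insertion = "AA", microhomology = 0L)))
}

## assemble one gene contig; returns list(seq, exons data.frame)
assemble_gene_contig <- function(arch, gc, flank) {
  pieces <- character(0)
  exons <- data.frame(start = integer(0), end = integer(0))
  pos <- flank
  pieces <- random_dna(flank, gc)
  n <- length(arch$exon_lengths)
  for (k in seq_len(n)) {
    le <- arch$exon_lengths[k]
    pieces <- c(pieces, random_dna(le, gc))
    exons <- rbind(exons, data.frame(start = pos, end = pos + le))
    pos <- pos + le
    if (k < n) {
      li <- arch$intron_lengths[k]
      pieces <- c(pieces, random_dna(li, gc))
      pos <- pos + li
    }
  }
  pieces <- c(pieces, random_dna(flank, gc))
  list(seq = paste(pieces, collapse = ""), exons = exons)
}

## replace s[start..start+nchar(repl)) (0-based) with repl
splice_in <- function(s, start, repl) {
  paste0(subseq0(s, 0L, start), repl,
         subseq0(s, start + nchar(repl), nchar(s)))
}

set_base <- function(s, pos0, base) splice_in(s, pos0, base)
get_base <- function(s, pos0) substr(s, pos0 + 1L, pos0 + 1L)

#' Generate the synthetic genome, annotation and truth record
#'
#' Builds the two contigs under the spec's seed, plants the stem (the
#' reverse complement of the designated A-intron window copied into the
#' B intron with the requested number of substitutions, end bases kept
#' intact) and the fusion events.  Around each planted junction the few
#' immediately adjacent bases are adjusted so that the stated insertion
#' and microhomology are exactly realised (no accidental extension or
#' extra junction ambiguity).
#'
#' @param spec a [synthetic_spec()].
#' @param dir optional output directory; when given, `genome.fasta`,
#'   `genes.gff3` and `truth.json` are written and listed in the truth
#'   record's manifest with md5 checksums.
#' @return list with `genome` (named character vector), `gene_a`,
#'   `gene_b` ([gene_model()]s), `truth` (planted stem window
#'   intervals, planted [fusion_event()]s, manifest) and `spec`.
#' @export
generate_genome <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  validate_synthetic_spec(spec)
  set.seed(spec$seed)
  ca <- assemble_gene_contig(spec$gene_a, spec$gc_content, spec$flank)
  cb <- assemble_gene_contig(spec$gene_b, spec$gc_content, spec$flank)
  gene_a <- gene_model(spec$gene_a$id, "contigA", "+", ca$exons)
  gene_b <- gene_model(spec$gene_b$id, "contigB", "+", cb$exons)
  seq_a <- ca$seq; seq_b <- cb$seq
  introns_a <- introns_of(gene_a); introns_b <- introns_of(gene_b)

  ## plant the stem
  truth_stem <- NULL
  st <- spec$stem
  if (!is.null(st)) {
    a0 <- introns_a$start[st$intron_a] + st$offset_a
    b0 <- introns_b$start[st$intron_b] + st$offset_b
    win_a <- subseq0(seq_a, a0, a0 + st$length)
    planted <- revcomp(win_a)
    if (st$mismatches > 0L) {
      pos <- sample(seq(4L, st$length - 3L), st$mismatches)
      for (p in pos) {
        old <- get_base(planted, p - 1L)
        planted <- set_base(planted, p - 1L, other_base(old))
      }
    }
    seq_b <- splice_in(seq_b, b0, planted)
    truth_stem <- list(
      window_a = interval("contigA", a0, a0 + st$length, "+"),
      window_b = interval("contigB", b0, b0 + st$length, "+"),
      length = st$length, mismatches = st$mismatches,
      identity = (st$length - st$mismatches) / st$length)
  }

  ## plant the events; adjust junction-adjacent bases so the stated
  ## micro-features hold exactly
  truth_events <- list()
  for (ev in spec$events) {
    ins <- if (is.null(ev$insertion)) "" else ev$insertion
    mh <- if (is.null(ev$microhomology)) 0L else as.integer(ev$microhomology)
    bpA <- introns_a$start[ev$intron_a] + ev$offset_a
    bpB <- introns_b$start[ev$intron_b] + ev$offset_b
    if (mh > 0L) {
      shared <- subseq0(seq_a, bpA - mh + 1L, bpA + 1L)
      seq_b <- splice_in(seq_b, bpB - mh, shared)
      ## stop left extension beyond mh and any right-side ambiguity
      if (get_base(seq_b, bpB - mh - 1L) == get_base(seq_a, bpA - mh))
        seq_b <- set_base(seq_b, bpB - mh - 1L,
                          other_base(get_base(seq_a, bpA - mh)))
      if (get_base(seq_b, bpB) == get_base(seq_a, bpA + 1L))
        seq_b <- set_base(seq_b, bpB, other_base(get_base(seq_a, bpA + 1L)))
    } else if (nzchar(ins)) {
      ## insertion must not be absorbable by either parental flank
      if (get_base(seq_a, bpA + 1L) == substr(ins, 1L, 1L))
        seq_a <- set_base(seq_a, bpA + 1L, other_base(substr(ins, 1L, 1L)))
      if (get_base(seq_b, bpB - 1L) == substr(ins, nchar(ins), nchar(ins)))
        seq_b <- set_base(seq_b, bpB - 1L,
                          other_base(substr(ins, nchar(ins), nchar(ins))))
    } else {
      ## clean junction: no accidental microhomology on either side
      if (get_base(seq_b, bpB) == get_base(seq_a, bpA + 1L))
        seq_b <- set_base(seq_b, bpB, other_base(get_base(seq_a, bpA + 1L)))
      if (get_base(seq_b, bpB - 1L) == get_base(seq_a, bpA))
        seq_b <- set_base(seq_b, bpB - 1L, other_base(get_base(seq_a, bpA)))
    }
    truth_events[[length(truth_events) + 1L]] <-
      fusion_event(ev$id, spec$gene_a$id, spec$gene_b$id, bpA, bpB,
                   insertion = ins, microhomology_length = mh)
  }

  genome <- c(contigA = seq_a, contigB = seq_b)
  truth <- list(stem = truth_stem, events = truth_events, manifest = NULL)
  out <- list(genome = genome, gene_a = gene_a, gene_b = gene_b,
              truth = truth, spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(dir, "genome.fasta")
    gff <- file.path(dir, "genes.gff3")
    tj <- file.path(dir, "truth.json")
    write_fasta(genome, fa)
    write_gene_models(list(gene_a, gene_b), gff)
    truth_json <- list(
      stem = if (is.null(truth_stem)) NULL else list(
        window_a = unclass(truth_stem$window_a),
        window_b = unclass(truth_stem$window_b),
        length = truth_stem$length, mismatches = truth_stem$mismatches),
      events = lapply(truth_events, unclass))
    writeLines(jsonlite::toJSON(truth_json, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), tj)
    files <- c(fa, gff, tj)
    out$truth$manifest <- data.frame(file = basename(files),
                                     md5 = unname(tools::md5sum(files)))
  }
  out
}

#' Generate fused alleles and junction-spanning reads
#'
#' Builds one rearranged allele per planted event via
#' [make_fusion_allele()] and samples `n_reads` reads spanning each
#' junction with at least `read_length / 3` bases on each side;
#' substitution errors are injected at `read_error` under the spec's
#' seed.
#'
#' @param gen result of [generate_genome()].
#' @param dir optional output directory for `allele_<id>.fasta` and
#'   `reads.fasta`.
#' @return list with `alleles` (named list of `fusion_allele`),
#'   `reads` (named character vector, names
#'   `read_<event>_<k>`), and `events`.
#' @export
generate_fusion_materials <- function(gen, dir = NULL) {
  spec <- gen$spec
  if (length(gen$truth$events) == 0L)
    stop("no planted events in this spec", call. = FALSE)
  set.seed(spec$seed + 1L)
  rl <- spec$read_length
  minflank <- rl %/% 3L
  alleles <- list(); reads <- character(0)
  for (ev in gen$truth$events) {
    al <- make_fusion_allele(gen$genome, gen$gene_a, gen$gene_b, ev)
    alleles[[ev$event_id]] <- al
    bpA <- ev$breakpoint_a
    jend <- bpA + 1L + nchar(ev$insertion)      # allele pos where B starts
    lo <- max(0L, jend + minflank - rl)
    hi <- min(bpA + 1L - minflank, nchar(al$sequence) - rl)
    if (hi < lo)
      stop("read_length ", rl, " cannot span the junction of event '",
           ev$event_id, "' with the required flanks", call. = FALSE)
    for (k in seq_len(spec$n_reads)) {
      s <- if (hi > lo) lo + sample.int(hi - lo + 1L, 1L) - 1L else lo
      rd <- subseq0(al$sequence, s, s + rl)
      if (spec$read_error > 0) {
        hitpos <- which(runif(rl) < spec$read_error)
        for (p in hitpos)
          rd <- set_base(rd, p - 1L, other_base(get_base(rd, p - 1L)))
      }
      reads[sprintf("read_%s_%d", ev$event_id, k)] <- rd
    }
  }
  out <- list(alleles = alleles, reads = reads, events = gen$truth$events)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(alleles)) {
      write_fasta(stats::setNames(alleles[[id]]$sequence,
                                  paste0("allele_", id)),
                  file.path(dir, paste0("allele_", id, ".fasta")))
    }
    write_fasta(reads, file.path(dir, "reads.fasta"))
  }
  out
}
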