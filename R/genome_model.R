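## genome_model: sequence and annotation I/O, coordinate conventions,
## strand-aware extraction, intron derivation.
##
## Conventions: coordinates are 0-based half-open internally; strand is
## "+" or "-"; a gene's exons are kept sorted 5'->3' in gene orientation
## (for minus-strand genes exon 1 has the highest genomic coordinate).

#' Construct a genomic interval
#'
#' @param contig_id contig name.
#' @param start,end 0-based half-open bounds, `0 <= start < end`.
#' @param strand `"+"` or `"-"`.
#' @return an object of class `interval`.
#' @export
interval <- function(contig_id, start, end, strand = "+") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop("invalid interval: need 0 <= start < end", call. = FALSE)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  structure(list(contig_id = contig_id, start = start, end = end,
                 strand = strand),
            class = "interval")
}

iv_width <- function(x) x$end - x$start

#' @export
print.interval <- function(x, ...) {
  cat(sprintf("<interval> %s:%d-%d (%s)  [1-based %d-%d]\n",
              x$contig_id, x$start, x$end, x$strand,
              pos1(x$start), x$end))
  invisible(x)
}

#' Construct a gene model
#'
#' Exons are reordered 5'->3' in gene orientation and validated for
#' pairwise non-overlap.
#'
#' @param gene_id gene identifier.
#' @param contig_id contig the gene lives on.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (0-based
#'   half-open, genomic).
#' @return an object of class `gene_model` with exons carrying 1-based
#'   `exon_number` labels.
#' @export
gene_model <- function(gene_id, contig_id, strand, exons) {
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  if (nrow(exons) < 1L) stop("gene model needs >= 1 exon", call. = FALSE)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  if (any(exons$start >= exons$end)) stop("exon with start >= end", call. = FALSE)
  if (nrow(exons) > 1L && any(exons$start[-1L] < exons$end[-nrow(exons)]))
    stop("overlapping exons in gene ", gene_id, call. = FALSE)
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  exons$exon_number <- seq_len(nrow(exons))
  rownames(exons) <- NULL
  structure(list(gene_id = gene_id, contig_id = contig_id, strand = strand,
                 exons = exons),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  %s(%s)  %d exon(s), span %d-%d\n",
              x$gene_id, x$contig_id, x$strand, nrow(x$exons),
              pos1(min(x$exons$start)), max(x$exons$end)))
  invisible(x)
}

gene_span <- function(gene) {
  interval(gene$contig_id, min(gene$exons$start), max(gene$exons$end),
           gene$strand)
}

#' Read a FASTA file into a genome map
#'
#' Input is validated line by line (headers start with `>`, sequence
#' lines restricted to A,C,G,T,N case-insensitively) so parse errors
#' name the offending line, then loaded with Biostrings.  Lowercase is
#' normalised to uppercase.
#'
#' @param path FASTA file.
#' @return named character vector, one uppercase sequence per contig.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  seen_header <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, ">")) { seen_header <- TRUE; next }
    if (!seen_header)
      stop("FASTA parse error at line ", i, ": sequence before any header",
           call. = FALSE)
    if (grepl("[^ACGTNacgtn]", ln))
      stop("FASTA parse error at line ", i, ": invalid sequence character",
           call. = FALSE)
  }
  if (!seen_header) return(stats::setNames(character(0), character(0)))
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write a genome map to FASTA
#'
#' @param genome named character vector of contig sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read gene models from GFF3 or GTF
#'
#' GFF3 is the canonical dialect; `.gtf` files are read through the same
#' importer with attribute-key mapping (`gene_id` instead of
#' `ID`/`Parent`).  Exons are grouped per gene and sorted in gene
#' orientation.
#'
#' @param path annotation file (`.gff3`/`.gff` or `.gtf`).
#' @return list of [gene_model()] objects.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  is_gtf <- grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)
  gr <- rtracklayer::import(path, format = if (is_gtf) "gtf" else "gff3")
  typ <- as.character(gr$type)
  ex <- gr[typ == "exon"]
  if (length(ex) == 0L) stop("annotation error: no exon features in ", path,
                             call. = FALSE)
  if (is_gtf) {
    gid <- as.character(ex$gene_id)
    if (anyNA(gid)) stop("annotation error: exon without gene_id", call. = FALSE)
  } else {
    genes <- gr[typ == "gene"]
    ids <- as.character(gr$ID)
    parent_of <- function(p) {
      hit <- which(ids == p)
      if (length(hit) == 0L) return(NA_character_)
      if (as.character(gr$type[hit[1]]) == "gene") return(p)
      pp <- gr$Parent[[hit[1]]]
      if (length(pp) == 0L) return(NA_character_)
      parent_of(as.character(pp[1]))
    }
    par <- vapply(seq_along(ex), function(k) {
      pp <- ex$Parent[[k]]
      if (length(pp) == 0L) return(NA_character_)
      parent_of(as.character(pp[1]))
    }, character(1))
    if (anyNA(par))
      stop("annotation error: exon without parent gene", call. = FALSE)
    ## map gene feature ID -> printable gene id (Name or ID)
    gname <- as.character(genes$ID)
    if (!is.null(genes$Name)) {
      nm <- as.character(genes$Name)
      gname <- ifelse(is.na(nm), gname, nm)
    }
    gname <- stats::setNames(gname, as.character(genes$ID))
    gid <- ifelse(par %in% names(gname), unname(gname[par]), par)
  }
  out <- lapply(split(seq_along(ex), gid), function(idx) {
    e <- ex[idx]
    gene_model(
      gene_id = gid[idx[1]],
      contig_id = as.character(GenomicRanges::seqnames(e))[1],
      strand = as.character(GenomicRanges::strand(e))[1],
      exons = data.frame(start = GenomicRanges::start(e) - 1L,
                         end = GenomicRanges::end(e)))
  })
  out[order(names(out))]
}

#' Write gene models to GFF3
#'
#' @param genes list of [gene_model()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  rows <- list()
  for (g in genes) {
    sp <- gene_span(g)
    rows[[length(rows) + 1L]] <- data.frame(
      contig = g$contig_id, start = sp$start + 1L, end = sp$end,
      strand = g$strand, type = "gene", id = g$gene_id,
      parent = NA_character_)
    for (k in seq_len(nrow(g$exons))) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = g$contig_id, start = g$exons$start[k] + 1L,
        end = g$exons$end[k], strand = g$strand, type = "exon",
        id = sprintf("%s.exon%d", g$gene_id, g$exons$exon_number[k]),
        parent = g$gene_id)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  gr$type <- df$type
  gr$ID <- df$id
  gr$Parent <- ifelse(is.na(df$parent), NA_character_, df$parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Derive introns of a gene
#'
#' Intron `k` spans the gap between exon `k` and exon `k+1` in gene
#' orientation; a single-exon gene has none.
#'
#' @param gene a [gene_model()].
#' @return data.frame with columns `contig_id`, `start`, `end` (0-based
#'   half-open, genomic), `strand`, `intron_number`; zero rows for a
#'   single-exon gene.
#' @export
introns_of <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  n <- nrow(gene$exons)
  empty <- data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      intron_number = integer(0))
  if (n < 2L) return(empty)
  e <- gene$exons
  if (gene$strand == "+") {
    start <- e$end[-n]; end <- e$start[-1L]
  } else {
    start <- e$start[-n]; end <- e$end[-1L]
    tmp <- start; start <- end; end <- tmp
  }
  data.frame(contig_id = gene$contig_id, start = as.integer(start),
             end = as.integer(end), strand = gene$strand,
             intron_number = seq_len(n - 1L))
}

intron_interval <- function(gene, k) {
  ii <- introns_of(gene)
  if (k < 1L || k > nrow(ii))
    stop("gene ", gene$gene_id, " has no intron ", k, call. = FALSE)
  interval(ii$contig_id[k], ii$start[k], ii$end[k], ii$strand[k])
}

#' Extract the sense-strand sequence of a region
#'
#' Plus-strand regions return the stored string; minus-strand regions
#' return its reverse complement (the gene's sense strand).
#'
#' @param region an [interval()] (or a one-row data.frame from
#'   [introns_of()]).
#' @param genome named character vector from [read_fasta()].
#' @return nucleotide string, 5'->3' on the region's sense strand.
#' @export
sense_sequence <- function(region, genome) {
  if (is.data.frame(region)) {
    stopifnot(nrow(region) == 1L)
    region <- interval(region$contig_id, region$start, region$end,
                       region$strand)
  }
  s <- genome[[region$contig_id]]
  if (is.null(s)) stop("unknown contig: ", region$contig_id, call. = FALSE)
  if (region$end > nchar(s))
    stop("range error: ", region$contig_id, ":", region$start, "-",
         region$end, " exceeds contig length ", nchar(s), call. = FALSE)
  out <- subseq0(s, region$start, region$end)
  if (region$strand == "-") out <- revcomp(out)
  out
}

## Orient a gene into "sense space": the whole contig read 5'->3' on the
## gene's sense strand, with exon/intron coordinates transformed to
## match.  For plus-strand genes this is the identity.
gene_sense_space <- function(gene, genome) {
  s <- genome[[gene$contig_id]]
  if (is.null(s)) stop("unknown contig: ", gene$contig_id, call. = FALSE)
  L <- nchar(s)
  ex <- gene$exons
  if (gene$strand == "+") {
    list(seq = s, length = L, exons = ex)
  } else {
    ex2 <- data.frame(start = L - ex$end, end = L - ex$start,
                      exon_number = ex$exon_number)
    list(seq = revcomp(s), length = L, exons = ex2)
  }
}

#' Write intervals to a BED file
#'
#' BED is 0-based half-open, matching the internal convention.
#'
#' @param df data.frame with `contig_id`, `start`, `end`, optional
#'   `name` and `strand` columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  name <- if ("name" %in% names(df)) df$name else "."
  strand <- if ("strand" %in% names(df)) df$strand else "."
  out <- data.frame(df$contig_id, df$start, df$end, name, 0L, strand)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
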